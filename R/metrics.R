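#' Convergence time of the recurrent dynamics
#'
#' The number of solver steps until every neuron's activity changes by less
#' than `tol` between consecutive steps. Near the critical point this count
#' grows sharply -- critical slowing down -- so it serves as a dynamical
#' probe of proximity to the phase transition. One solver step corresponds to
#' `alpha * tau` units of model time.
#'
#' @inheritParams solve_fixed_point
#' @return Integer step count, with attribute `"converged"`; `max_iter` is
#'   returned (flagged `converged = FALSE`) when the criterion is never met.
#' @export
convergence_time <- function(params, x, tol = 1e-9, max_iter = 1e6,
                             init = NULL, noise_scale = 0, seed = NULL,
                             alpha = 0.5) {
  fp <- solve_fixed_point(params, x, tol = tol, max_iter = max_iter,
                          init = init, noise_scale = noise_scale,
                          seed = seed, alpha = alpha)
  structure(fp$iterations, converged = fp$converged)
}

#' Population vector of a network response
#'
#' Each neuron contributes a phasor of magnitude equal to its activity and
#' phase equal to its preferred angle; the resultant summarizes the tuning of
#' the population response. A uniform response gives magnitude 0; a bump
#' gives a finite magnitude pointing at the bump. For orientation (rather
#' than direction) preferences the angle is doubled before summing, so that
#' the 180-degree periodic variable spans the full circle, and the resultant
#' phase is halved back.
#'
#' @param s Activity vector (non-negative).
#' @param angles Preferred angles in radians (same length as `s`).
#' @param doubling Apply the orientation angle-doubling convention.
#' @return A `"population_vector"` list: `magnitude`, `phase` (radians),
#'   `doubling`.
#' @export
population_vector <- function(s, angles, doubling = FALSE) {
  stopifnot(length(s) == length(angles), all(s >= 0))
  mult <- if (doubling) 2 else 1
  z <- sum(s * exp(1i * mult * angles))
  phase <- Arg(z) / mult
  structure(list(magnitude = Mod(z), phase = phase, doubling = doubling),
            class = "population_vector")
}

#' @export
print.population_vector <- function(x, ...) {
  cat("<population_vector> magnitude", format(x$magnitude, digits = 4),
      "phase", format(x$phase, digits = 4), "rad",
      if (x$doubling) "(orientation doubling)" else "", "\n")
  invisible(x)
}

#' Sweep a multiplicative scale on the recurrent interactions
#'
#' Replaces K by c*K over a grid of scale factors and records, for each
#' scale: the infomax objective on a fixed input batch, the mean convergence
#' step count over that batch, and the magnitude of the population vector of
#' the zero-input response (with small seeded symmetry-breaking noise, so the
#' supercritical "hill" attractor is detectable). The objective minimum at
#' scale 1 of a trained network indicates that learning converged; the jump
#' of the zero-input population vector and the peak in convergence time near
#' that scale are the criticality signatures.
#'
#' @param params Network whose K is swept.
#' @param scales Sorted grid of multiplicative factors.
#' @param inputs Fixed N x n input batch, shared across scales (paired
#'   comparison).
#' @param tol Solver tolerance.
#' @param max_iter Solver cap per fixed point (default 1e5 so supercritical
#'   or near-critical scales record the cap rather than stalling).
#' @param popvec_seed Seed for the zero-input symmetry-breaking noise.
#' @param noise_scale Scale of that noise (default 1e-6).
#' @param doubling Angle doubling for the population vector.
#' @param angles Preferred angles for the population vector; default ring
#'   angles of M neurons.
#' @return A `"scaling_sweep"` data.frame with columns `scale`, `epsilon`,
#'   `steps`, `popvec`; supercritical scales where the objective is undefined
#'   carry `NA` epsilon. Attribute `"argmin_scale"` is the scale of minimum
#'   epsilon among defined values.
#' @export
scaling_sweep <- function(params, scales, inputs, tol = 1e-9, max_iter = 1e5,
                          popvec_seed = 1L, noise_scale = 1e-6,
                          doubling = FALSE, angles = NULL) {
  stopifnot(inherits(params, "network_params"), !is.unsorted(scales))
  X <- as.matrix(inputs)
  if (is.null(angles)) angles <- ring_angles(params$M)
  rows <- lapply(scales, function(sc) {
    p <- network_params(params$W, sc * params$K, params$tau, params$nl)
    # beyond the zero-input critical point the homogeneous state is unstable
    # and the log-determinant objective loses its information meaning:
    # record epsilon as missing there (dynamical metrics remain defined)
    supercritical <-
      params$nl$gamma0 * sc * spectral_radius(params$K) >= 1
    eps <- if (supercritical) NA_real_ else tryCatch(
      infomax_objective(p, X, tol = tol, max_iter = max_iter)$epsilon,
      error = function(e) NA_real_)
    bat <- tryCatch(
      solve_fixed_points_batch(p, X, tol = tol, max_iter = max_iter),
      error = function(e) NULL)
    steps <- if (is.null(bat)) NA_real_ else mean(bat$iterations)
    pv <- tryCatch({
      fp0 <- solve_fixed_point(p, rep(0, params$N), tol = tol,
                               max_iter = max_iter,
                               noise_scale = noise_scale, seed = popvec_seed)
      population_vector(fp0$s, angles, doubling = doubling)$magnitude
    }, error = function(e) NA_real_)
    data.frame(scale = sc, epsilon = eps, steps = steps, popvec = pv)
  })
  out <- do.call(rbind, rows)
  ok <- is.finite(out$epsilon)
  attr(out, "argmin_scale") <-
    if (any(ok)) out$scale[ok][which.min(out$epsilon[ok])] else NA_real_
  class(out) <- c("scaling_sweep", "data.frame")
  out
}

#' Steady-state response curves with and without recurrent interactions
#'
#' Drives the network with a fixed stimulus direction at each contrast in
#' `contrasts`, once with the recurrent matrix and once with K = 0, and
#' returns the steady-state activity of every neuron plus the tuning width
#' (half-width at half of the peak height above baseline) per condition and
#' contrast. Used to show recurrent amplification and (for the ecological
#' model) approximate contrast invariance of the tuning width.
#'
#' @param params A [network_params()] object.
#' @param stimulus Unit stimulus vector of length N (e.g. `c(cos(a), sin(a))`
#'   for the ring, or a whitened Gabor-probe code for the ecological model).
#' @param contrasts Multiplicative contrast levels applied to `stimulus`.
#' @param angles Preferred angles used to report widths (radians; default
#'   ring angles). Widths are reported in the same angular units.
#' @param tol,max_iter Solver controls.
#' @return A `"response_curves"` list: `curves` -- data.frame (neuron, angle,
#'   response, condition = "recurrent"/"feedforward", contrast) -- and
#'   `widths` -- data.frame (condition, contrast, width, peak).
#' @export
response_curves <- function(params, stimulus, contrasts = c(0.5, 1, 2),
                            angles = NULL, tol = 1e-9, max_iter = 1e5) {
  stopifnot(inherits(params, "network_params"),
            length(stimulus) == params$N)
  if (is.null(angles)) angles <- ring_angles(params$M)
  p0 <- network_params(params$W, NULL, params$tau, params$nl)
  curves <- list(); widths <- list()
  for (cond in c("recurrent", "feedforward")) {
    p <- if (cond == "recurrent") params else p0
    for (ct in contrasts) {
      fp <- solve_fixed_point(p, ct * stimulus, tol = tol,
                              max_iter = max_iter)
      if (!fp$converged)
        stop("response solver did not converge at contrast ", ct)
      curves[[length(curves) + 1L]] <-
        data.frame(neuron = seq_along(fp$s), angle = angles,
                   response = fp$s, condition = cond, contrast = ct)
      widths[[length(widths) + 1L]] <-
        data.frame(condition = cond, contrast = ct,
                   width = tuning_width(fp$s, angles), peak = max(fp$s))
    }
  }
  structure(list(curves = do.call(rbind, curves),
                 widths = do.call(rbind, widths)),
            class = "response_curves")
}

# Half-width at half height above baseline of a tuning profile on a circle.
# Baseline = minimum response; width = angular extent where the response
# exceeds baseline + (peak - baseline)/2, measured by counting neurons
# (profiles here are unimodal bumps).
tuning_width <- function(s, angles) {
  base <- min(s); peak <- max(s)
  if (peak - base < .Machine$double.eps) return(NA_real_)
  above <- s > base + (peak - base) / 2
  sum(above) * (2 * pi / length(s)) / 2
}
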