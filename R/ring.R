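#' Ring hypercolumn specification
#'
#' The toy hypercolumn: M output neurons with preferred angles equally spaced
#' on the full circle, driven by 2-dimensional inputs whose angle encodes
#' stimulus orientation (with 360-degree periodicity) and whose radius encodes
#' contrast. Input radii are Gaussian around `mean_contrast` with standard
#' deviation `contrast_sd_fraction * mean_contrast`.
#'
#' @param M Number of output neurons (>= 3; the full-size model uses 141).
#' @param mean_contrast Mean input radius `<r>`.
#' @param contrast_sd_fraction Radius standard deviation as a fraction of the
#'   mean (default 0.1).
#' @return A `"ring_spec"` with fields `M`, `angles` (2*pi*(0:(M-1))/M),
#'   `mean_contrast`, `contrast_sd_fraction`.
#' @export
ring_spec <- function(M = 141, mean_contrast = 0.1,
                      contrast_sd_fraction = 0.1) {
  stopifnot(M >= 3, mean_contrast >= 0, contrast_sd_fraction >= 0)
  structure(list(M = as.integer(M),
                 angles = 2 * pi * (seq_len(M) - 1) / M,
                 mean_contrast = mean_contrast,
                 contrast_sd_fraction = contrast_sd_fraction),
            class = "ring_spec")
}

#' Ring preferred angles
#' @param M Number of neurons.
#' @return Angles in radians, equally spaced over [0, 2*pi).
#' @export
ring_angles <- function(M) 2 * pi * (seq_len(M) - 1) / M

#' Build the ring network
#'
#' Feedforward rows are unit vectors at the preferred angles,
#' \eqn{W_i = (\cos\theta_i, \sin\theta_i)}, so the drive to neuron i has a
#' cosine tuning curve peaked at its preferred angle. K starts at zero; the
#' nonlinearity is the logistic; tau = 1.
#'
#' @param M Number of output neurons (>= 3).
#' @return A [network_params()] object (M x 2 feedforward matrix).
#' @export
build_ring <- function(M) {
  stopifnot(M >= 3)
  th <- ring_angles(M)
  network_params(W = cbind(cos(th), sin(th)))
}

#' Sample ring-model inputs
#'
#' Input angle uniform on [0, 2*pi); radius Gaussian with mean
#' `spec$mean_contrast` and sd `contrast_sd_fraction` times the mean.
#'
#' @param spec A [ring_spec()].
#' @param n Number of samples.
#' @param seed Optional seed; when given, the global RNG state is untouched
#'   and repeated calls reproduce the same batch.
#' @return 2 x n matrix, one input vector r*(cos, sin) per column.
#' @export
sample_ring_inputs <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "ring_spec"), n >= 1)
  with_seed(seed, {
    th0 <- stats::runif(n, 0, 2 * pi)
    r <- stats::rnorm(n, mean = spec$mean_contrast,
                      sd = spec$contrast_sd_fraction * spec$mean_contrast)
    rbind(r * cos(th0), r * sin(th0))
  })
}

#' Input sampler closure for training
#'
#' Returns a function `f(n)` drawing n ring inputs from the RNG stream of the
#' caller (the training loop seeds its own stream), for use as the `sampler`
#' argument of [train_network()].
#'
#' @param spec A [ring_spec()].
#' @return Function of one argument n returning a 2 x n matrix.
#' @export
ring_input_sampler <- function(spec) {
  force(spec)
  function(n) sample_ring_inputs(spec, n, seed = NULL)
}

#' Cosine-harmonic decomposition of an interaction matrix
#'
#' Extracts the interaction profile K(theta) and its cosine harmonics in the
#' normalization \eqn{K(\theta) = (1/M)\sum_n k_n \cos(n\theta)}, so a pure
#' profile \eqn{(c/M)\cos\Delta\theta} yields k1 = c. A non-circulant K is
#' first circularly averaged over its diagonals; the root-mean-square residual
#' of that averaging (relative to the mean absolute entry) is reported, not
#' fatal, as a measure of departure from translation invariance.
#'
#' @param K M x M interaction matrix.
#' @param angles Preferred angles (default equally spaced, as in the ring).
#' @param n_max Highest harmonic to return (default `floor((M-1)/2)`).
#' @return A `"fourier_profile"`: `k` (named numeric, harmonics 0..n_max;
#'   k0 is the profile mean term), `profile` (circularly averaged profile over
#'   offsets), `offsets` (angles of the profile), `circulant_residual`.
#' @export
fourier_profile <- function(K, angles = NULL, n_max = NULL) {
  K <- as.matrix(K)
  M <- nrow(K)
  stopifnot(ncol(K) == M, M >= 3)
  if (is.null(angles)) angles <- ring_angles(M)
  if (is.null(n_max)) n_max <- (M - 1L) %/% 2L
  idx <- seq_len(M)
  # profile over offset d: average of K[i, i + d (mod M)]
  profile <- vapply(0:(M - 1L), function(d) {
    mean(K[cbind(idx, ((idx - 1L + d) %% M) + 1L)])
  }, numeric(1))
  resid2 <- vapply(0:(M - 1L), function(d) {
    v <- K[cbind(idx, ((idx - 1L + d) %% M) + 1L)]
    mean((v - mean(v))^2)
  }, numeric(1))
  denom <- mean(abs(K))
  circ_res <- if (denom > 0) sqrt(mean(resid2)) / denom else 0
  offs <- 2 * pi * (0:(M - 1L)) / M
  k <- c(sum(profile),
         vapply(seq_len(n_max), function(n) 2 * sum(profile * cos(n * offs)),
                numeric(1)))
  names(k) <- paste0("k", 0:n_max)
  structure(list(k = k, profile = profile, offsets = offs,
                 circulant_residual = circ_res),
            class = "fourier_profile")
}

#' @export
print.fourier_profile <- function(x, ...) {
  cat("<fourier_profile> k0 =", format(x$k[1], digits = 4),
      " k1 =", format(x$k[2], digits = 4),
      " circulant residual =", format(x$circulant_residual, digits = 3), "\n")
  invisible(x)
}

#' Amplitude of an interaction profile
#'
#' M times the peak of the circularly averaged interaction profile -- the
#' scale on which the learned ring profile is reported (a pure cosine of
#' first harmonic k1 has amplitude k1 on this scale).
#'
#' @inheritParams fourier_profile
#' @return Scalar amplitude.
#' @export
profile_amplitude <- function(K, angles = NULL) {
  fp <- fourier_profile(K, angles)
  nrow(as.matrix(K)) * max(fp$profile)
}

#' Analytically optimal ring interactions
#'
#' In the low-contrast limit the infomax-optimal recurrent interactions are
#' the pure cosine profile at the critical amplitude,
#' \eqn{K_{ij} = (2/(M\gamma_0)) \cos(\theta_i - \theta_j)}; for the logistic
#' (gamma0 = 1/4) the amplitude M * max K equals 8.
#'
#' @param M Number of neurons (>= 3).
#' @param gamma0 Gain of the nonlinearity at zero input (> 0).
#' @return M x M symmetric circulant matrix.
#' @export
optimal_ring_K <- function(M, gamma0 = 0.25) {
  stopifnot(M >= 3, gamma0 > 0)
  th <- ring_angles(M)
  (2 / (M * gamma0)) * cos(outer(th, th, "-"))
}

#' Closed-form objective shift for the zero-contrast ring
#'
#' For the ring at vanishing contrast with a pure-cosine interaction profile
#' of first harmonic k1, the objective depends on k1 only through
#' \deqn{\varepsilon(k_1) - \varepsilon(0) = 2\ln(1 - \tfrac12\gamma_0 k_1),}
#' which diverges to -Inf as k1 approaches the critical value 2/gamma0.
#'
#' @param k1 First cosine harmonic of the interaction profile (must be below
#'   the critical value 2/gamma0).
#' @param gamma0 Zero-input gain.
#' @return The objective shift in nats.
#' @export
analytic_objective_shift <- function(k1, gamma0 = 0.25) {
  stopifnot(gamma0 > 0)
  if (any(k1 >= 2 / gamma0))
    stop("supercritical k1 >= 2/gamma0: objective undefined (diverges)")
  2 * log(1 - 0.5 * gamma0 * k1)
}

#' Closed-form ring susceptibility at zero contrast
#'
#' \eqn{\chi_{i1} = \gamma_0\cos\theta_i/(1 - \tfrac12\gamma_0 k_1)} and the
#' analogous sine column: the cosine input mode is amplified by the factor
#' \eqn{1/(1-\gamma_0 k_1/2)}, which diverges at the critical point.
#'
#' @param k1 First cosine harmonic of the interaction profile (subcritical).
#' @param angles Preferred angles.
#' @param gamma0 Zero-input gain.
#' @return M x 2 matrix.
#' @export
analytic_susceptibility <- function(k1, angles, gamma0 = 0.25) {
  stopifnot(gamma0 > 0)
  if (k1 >= 2 / gamma0)
    stop("supercritical k1 >= 2/gamma0: susceptibility diverges")
  d <- 1 - 0.5 * gamma0 * k1
  cbind(gamma0 * cos(angles) / d, gamma0 * sin(angles) / d)
}
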