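#' Network parameters
#'
#' Container for a two-layer recurrent sensory network: N input units feed an
#' overcomplete layer of M output units (M >= N) through the feedforward
#' matrix `W` (M x N); the output units interact through the recurrent matrix
#' `K` (M x M). Output activities follow
#' \deqn{\tau \dot s = -s + g(Wx + Ks)}
#' with squashing function `g`.
#'
#' @param W Feedforward weight matrix, M x N.
#' @param K Recurrent weight matrix, M x M (defaults to zeros).
#' @param tau Relaxation time constant of the rate dynamics (arbitrary time
#'   unit, default 1).
#' @param nl A [nonlinearity()] object; defaults to the logistic.
#' @return An object of class `"network_params"` with fields `W`, `K`, `tau`,
#'   `nl`, `M`, `N`.
#' @export
network_params <- function(W, K = NULL, tau = 1,
                           nl = logistic_nonlinearity()) {
  W <- as.matrix(W)
  M <- nrow(W)
  N <- ncol(W)
  if (is.null(K)) K <- matrix(0, M, M)
  K <- as.matrix(K)
  if (!all(dim(K) == c(M, M)))
    stop("K must be square with side equal to nrow(W)")
  if (M < N)
    stop("overcomplete representation requires M >= N")
  if (!all(is.finite(W)) || !all(is.finite(K)) || !is.finite(tau) || tau <= 0)
    stop("W, K must be finite and tau > 0")
  if (!inherits(nl, "nonlinearity")) stop("nl must be a nonlinearity object")
  structure(list(W = W, K = K, tau = tau, nl = nl, M = M, N = N),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params> M =", x$M, "outputs, N =", x$N, "inputs,",
      "tau =", format(x$tau), ", nonlinearity:", x$nl$name, "\n")
  cat("  ||K||_max =", format(max(abs(x$K))), "\n")
  invisible(x)
}

# Run the RNG-dependent expression under a temporary seed, restoring the
# caller's RNG state afterwards. seed = NULL leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Solve for the steady state of the recurrent dynamics
#'
#' Finds a self-consistent solution of \eqn{s = g(Wx + Ks)} by damped
#' fixed-point iteration \eqn{s \leftarrow (1-\alpha)s + \alpha g(Wx + Ks)},
#' equivalent to forward-Euler integration of the rate dynamics with step
#' \eqn{\alpha\tau}. Iteration stops when every neuron's activity changes by
#' less than `tol` between consecutive steps (the stability criterion used by
#' [convergence_time()]).
#'
#' @param params A [network_params()] object.
#' @param x Input vector of length N.
#' @param tol Per-neuron convergence tolerance (> 0).
#' @param max_iter Iteration cap; on hitting it the result is returned with
#'   `converged = FALSE` rather than an error, so sweeps near criticality can
#'   record non-convergence.
#' @param init Optional initial activity vector; defaults to the homogeneous
#'   baseline `g(0)`.
#' @param noise_scale If > 0, adds seeded Gaussian noise of this scale to the
#'   initial state. Needed to break the symmetry of the homogeneous state in
#'   the supercritical regime, where the network falls into a "hill" attractor
#'   whose location depends on the noise realization.
#' @param seed Seed for the initial noise (ignored when `noise_scale == 0`).
#' @param alpha Damping factor in (0, 1]; default 0.5.
#' @return An object of class `"fixed_point"`: `s` (steady-state activities,
#'   each in (0,1) for the logistic), `net_input` (Wx + Ks at the solution),
#'   `iterations`, `converged`, `per_neuron_delta` (the last step's largest
#'   activity change).
#' @export
solve_fixed_point <- function(params, x, tol = 1e-9, max_iter = 1e6,
                              init = NULL, noise_scale = 0, seed = NULL,
                              alpha = 0.5) {
  stopifnot(inherits(params, "network_params"))
  x <- as.numeric(x)
  if (length(x) != params$N) stop("x must have length N")
  if (!all(is.finite(x))) stop("x must be finite")
  if (tol <= 0) stop("tol must be positive")
  res <- solve_fixed_points_batch(params, matrix(x, ncol = 1), tol = tol,
                                  max_iter = max_iter,
                                  init = if (is.null(init)) NULL
                                         else matrix(init, ncol = 1),
                                  noise_scale = noise_scale, seed = seed,
                                  alpha = alpha)
  structure(list(s = drop(res$S), net_input = drop(res$U),
                 iterations = res$iterations[1L],
                 converged = res$converged[1L],
                 per_neuron_delta = res$per_neuron_delta[1L]),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat("<fixed_point> ", length(x$s), " neurons, ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations (last delta ",
      format(x$per_neuron_delta), ")\n", sep = "")
  invisible(x)
}

# Batched damped fixed-point iteration: X is N x B (one input per column),
# returns S, U = W X + K S (both M x B), per-column iteration counts (first
# step at which that column met the criterion), convergence flags and last
# deltas. All columns are iterated until every one has converged (cheap: the
# update is a single BLAS call), but the recorded count per column is the
# first step at which it satisfied the criterion.
#
# With newton_polish = TRUE the damped iteration is only run to a coarse
# criterion and each unconverged column is finished by Newton's method on
# F(s) = s - g(Wx + Ks). Near the critical point the damped map contracts at
# a rate 1 - O(distance to criticality) -- critical slowing down applies to
# the solver too -- whereas Newton stays quadratic until the Jacobian is
# numerically singular. The damped phase still selects the dynamically
# stable branch (uniform vs hill); Newton only sharpens it. Polished columns
# report iteration counts from the damped phase only, so dynamical timing
# metrics must use newton_polish = FALSE (the default).
solve_fixed_points_batch <- function(params, X, tol = 1e-9, max_iter = 1e6,
                                     init = NULL, noise_scale = 0,
                                     seed = NULL, alpha = 0.5,
                                     newton_polish = FALSE,
                                     switch_tol = 1e-5) {
  W <- params$W; K <- params$K; g <- params$nl$eval
  X <- as.matrix(X)
  B <- ncol(X)
  M <- params$M
  drive <- W %*% X                      # constant over the iteration
  S <- if (is.null(init)) matrix(g(0), M, B) else as.matrix(init)
  if (noise_scale > 0)
    S <- S + with_seed(seed, matrix(stats::rnorm(M * B, sd = noise_scale),
                                    M, B))
  damped_tol <- if (newton_polish) max(tol, switch_tol) else tol
  damped_cap <- if (newton_polish) min(max_iter, 500L) else max_iter
  iters <- rep.int(NA_integer_, B)
  delta_col <- rep.int(Inf, B)
  it <- 0L
  while (it < damped_cap) {
    it <- it + 1L
    S_new <- (1 - alpha) * S + alpha * g(drive + K %*% S)
    if (anyNA(S_new)) stop("divergent dynamics: NaN in fixed-point iteration")
    d <- abs(S_new - S)
    delta_col <- if (M > 1L) {
      td <- t(d)   # max.col is C-level; avoids an R-level loop per iteration
      td[cbind(seq_len(B), max.col(td, ties.method = "first"))]
    } else as.numeric(d)
    S <- S_new
    done_now <- delta_col < damped_tol
    iters[is.na(iters) & done_now] <- it
    if (all(done_now)) break
  }
  if (newton_polish) {
    d1 <- params$nl$deriv1
    for (b in seq_len(B)) {
      if (delta_col[b] < tol) next
      s <- S[, b]
      u <- drive[, b] + drop(K %*% s)
      Fv <- s - g(u)
      res <- max(abs(Fv))
      for (nit in seq_len(100L)) {
        if (res < tol) break
        step <- tryCatch(solve(diag(M) - d1(u) * K, Fv),
                         error = function(e) NULL)
        if (is.null(step)) break        # singular Jacobian: keep damped state
        # guarded step: halve until the residual decreases (the Jacobian is
        # near-singular close to criticality and full steps can overshoot)
        t_ <- 1
        repeat {
          s_try <- s - t_ * step
          u_try <- drive[, b] + drop(K %*% s_try)
          F_try <- s_try - g(u_try)
          if (max(abs(F_try)) < res || t_ < 1e-8) break
          t_ <- t_ / 2
        }
        if (max(abs(F_try)) >= res) break   # no progress possible
        s <- s_try; u <- u_try; Fv <- F_try
        res <- max(abs(Fv))
      }
      # for polished columns the recorded delta is the fixed-point residual
      # max_i |s_i - g((Wx + Ks)_i)|, the quantity the tolerance protects
      delta_col[b] <- res
      S[, b] <- s
    }
  }
  U <- drive + K %*% S
  converged <- delta_col < tol
  iters[is.na(iters)] <- it
  list(S = S, U = U, iterations = iters, converged = converged,
       per_neuron_delta = delta_col)
}

#' Integrate the rate dynamics forward in time
#'
#' Explicit forward-Euler integration of
#' \eqn{\tau \dot s = -s + g(Wx + Ks)} from a given initial state. Provided
#' as an independent route to the steady state: for stable dynamics the final
#' state agrees with [solve_fixed_point()].
#'
#' @inheritParams solve_fixed_point
#' @param duration Total integration time (model time units).
#' @param dt Time step; must satisfy `dt < tau` for stability of the explicit
#'   scheme.
#' @param init Initial activity vector (defaults to `g(0)`).
#' @return A matrix with one row per stored time point (including t = 0) and
#'   M columns; attribute `"time"` holds the time stamps.
#' @export
integrate_dynamics <- function(params, x, duration, dt, init = NULL) {
  stopifnot(inherits(params, "network_params"))
  if (dt >= params$tau) stop("dt must be smaller than tau (unstable discretization)")
  if (dt <= 0 || duration <= 0) stop("dt and duration must be positive")
  x <- as.numeric(x)
  if (length(x) != params$N) stop("x must have length N")
  g <- params$nl$eval
  s <- if (is.null(init)) rep.int(g(0), params$M) else as.numeric(init)
  drive <- drop(params$W %*% x)
  n_steps <- ceiling(duration / dt)
  out <- matrix(NA_real_, n_steps + 1L, params$M)
  out[1L, ] <- s
  lam <- dt / params$tau
  for (t in seq_len(n_steps)) {
    s <- s + lam * (-s + g(drive + drop(params$K %*% s)))
    if (anyNA(s)) stop("divergent dynamics: NaN during integration")
    out[t + 1L, ] <- s
  }
  attr(out, "time") <- seq(0, by = dt, length.out = n_steps + 1L)
  out
}
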