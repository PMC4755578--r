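#' Susceptibility (Jacobian) of the steady state with respect to the input
#'
#' At a converged fixed point, the sensitivity of each output to each input,
#' \eqn{\chi_{ij} = \partial s_i / \partial x_j}, satisfies
#' \eqn{(I - GK)\chi = GW} where G is the diagonal matrix of gains
#' \eqn{g'_i} at the operating point. The bundle also carries the auxiliary
#' matrices the learning rule needs: \eqn{\phi = (G^{-1} - K)^{-1}}
#' (so \eqn{\chi = \phi W}), \eqn{\Gamma = (\chi^T\chi)^{-1}\chi^T\phi}, and
#' the curvature vector \eqn{a_k = [\chi\Gamma]_{kk}\, g''_k / (g'_k)^3}.
#'
#' Everything is computed by linear solves on \eqn{I - GK}; the near-singular
#' factor is never inverted blindly. The reciprocal-condition estimate of
#' \eqn{I - GK} is reported so callers can detect operation at or beyond the
#' critical point, where the susceptibility diverges.
#'
#' @param params A [network_params()] object.
#' @param fp A converged [solve_fixed_point()] result for the same network.
#' @param check_condition If `TRUE` (default), estimate the condition number
#'   of `I - GK` and error when it exceeds `cond_limit`.
#' @param cond_limit Condition-number threshold signalling criticality.
#' @return An object of class `"susceptibility"`: `chi` (M x N), `G` (gain
#'   vector, length M), `phi` (M x M), `Gamma` (N x M), `a` (length M),
#'   `condition_estimate` (NA when `check_condition = FALSE`).
#' @export
susceptibility <- function(params, fp, check_condition = TRUE,
                           cond_limit = 1e12) {
  stopifnot(inherits(params, "network_params"), inherits(fp, "fixed_point"))
  if (!isTRUE(fp$converged))
    stop("susceptibility requires a converged fixed point")
  susceptibility_at(params, fp$s, fp$net_input, check_condition, cond_limit)
}

# Core bundle computation from raw state vectors (used per batch sample).
susceptibility_at <- function(params, s, u, check_condition = TRUE,
                              cond_limit = 1e12) {
  nl <- params$nl
  g1 <- nl$deriv1(u)
  g2 <- nl$deriv2(u)
  M <- params$M
  A <- diag(M) - g1 * params$K          # I - GK (row scaling = diag(G) %*% K)
  cond_est <- NA_real_
  if (check_condition) {
    rc <- rcond(A)
    cond_est <- if (rc > 0) 1 / rc else Inf
    if (cond_est > cond_limit)
      stop("network at or beyond criticality for this input: ",
           "condition estimate ", format(cond_est, digits = 3),
           " exceeds ", format(cond_limit))
  }
  # One factorization, two right-hand sides: chi = A^{-1} G W, phi = A^{-1} G.
  rhs <- cbind(g1 * params$W, diag(g1, M))
  sol <- solve(A, rhs)
  chi <- sol[, seq_len(params$N), drop = FALSE]
  phi <- sol[, params$N + seq_len(M), drop = FALSE]
  CtC <- crossprod(chi)
  Gamma <- solve(CtC, crossprod(chi, phi))  # (chi^T chi)^{-1} chi^T phi
  chiGamma <- chi %*% Gamma
  a <- diag(chiGamma) * g2 / g1^3
  structure(list(chi = chi, G = g1, phi = phi, Gamma = Gamma, a = a,
                 chi_Gamma = chiGamma, s = s, net_input = u,
                 condition_estimate = cond_est),
            class = "susceptibility")
}

#' @export
print.susceptibility <- function(x, ...) {
  cat("<susceptibility> chi ", nrow(x$chi), " x ", ncol(x$chi),
      ", condition estimate ", format(x$condition_estimate, digits = 3),
      "\n", sep = "")
  invisible(x)
}

# Stable log det of chi^T chi via Cholesky (N x N, small).
logdet_ctc <- function(chi) {
  CtC <- crossprod(chi)
  R <- tryCatch(chol(CtC), error = function(e) NULL)
  if (is.null(R))
    stop("chi^T chi is not positive definite")
  2 * sum(log(diag(R)))
}

#' Infomax objective over a batch of inputs
#'
#' The mutual information between input and steady-state output of the
#' deterministic network is maximized by minimizing
#' \deqn{\varepsilon = -\tfrac12 \langle \ln\det(\chi^T\chi)\rangle_x,}
#' the average over input samples of the log volume-expansion of the
#' input-to-output map. The average is an arithmetic mean over the supplied
#' batch; the log-determinant is computed by Cholesky factorization of the
#' small N x N matrix \eqn{\chi^T\chi}.
#'
#' @param params A [network_params()] object.
#' @param inputs Inputs, one per column (N x n matrix), or a single vector.
#' @param tol,max_iter Passed to the fixed-point solver.
#' @param cond_limit Condition threshold for [susceptibility()].
#' @param init Optional M x n matrix of initial activities (warm start).
#' @param newton_polish Finish each fixed point by Newton iterations (default
#'   TRUE); with FALSE the damped iteration alone must meet `tol` within
#'   `max_iter`, which near criticality it may not (critical slowing down).
#' @return An object of class `"objective_value"`: `epsilon` (nats),
#'   `per_sample_terms`, `n_samples`.
#' @export
infomax_objective <- function(params, inputs, tol = 1e-9, max_iter = 1e6,
                              cond_limit = 1e12, init = NULL,
                              newton_polish = TRUE) {
  stopifnot(inherits(params, "network_params"))
  X <- if (is.matrix(inputs)) inputs else matrix(inputs, ncol = 1)
  if (nrow(X) != params$N) stop("inputs must have N rows")
  bat <- solve_fixed_points_batch(params, X, tol = tol, max_iter = max_iter,
                                  init = init, newton_polish = newton_polish)
  if (!all(bat$converged))
    stop("fixed point did not converge for sample(s) ",
         paste(which(!bat$converged), collapse = ", "))
  terms <- vapply(seq_len(ncol(X)), function(b) {
    g1 <- params$nl$deriv1(bat$U[, b])
    A <- diag(params$M) - g1 * params$K
    chi <- solve(A, g1 * params$W)      # chi alone; phi/Gamma not needed here
    -0.5 * logdet_ctc(chi)
  }, numeric(1))
  structure(list(epsilon = mean(terms), per_sample_terms = terms,
                 n_samples = ncol(X), S = bat$S),
            class = "objective_value")
}

#' @export
print.objective_value <- function(x, ...) {
  cat("<objective_value> epsilon =", format(x$epsilon),
      "nats over", x$n_samples, "samples\n")
  invisible(x)
}
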