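#' Gradient-descent direction for the recurrent weights
#'
#' Batch-averaged descent direction for the infomax objective with respect
#' to the recurrent matrix K,
#' \deqn{\Delta K/\eta = \langle (\chi\Gamma)^T + \phi^T a\, s^T \rangle,}
#' so that an update \eqn{K \leftarrow K + \eta\,\Delta K/\eta} performs
#' gradient descent on \eqn{\varepsilon}. The first term is the direct
#' sensitivity of the log-determinant to K; the second accounts for the shift
#' of the operating point (and hence the gains) when K changes.
#'
#' @param params A [network_params()] object.
#' @param batch Input batch, one sample per column (N x B).
#' @param tol,max_iter Fixed-point solver controls.
#' @param zero_diagonal If `TRUE`, project out self-connections from the
#'   returned direction (they are learned by default).
#' @param init Optional warm-start activities (M x B).
#' @param newton_polish Finish fixed points by Newton iterations (default
#'   TRUE).
#' @return List with `direction` (M x M, equal to \eqn{-\partial
#'   \varepsilon/\partial K}), `epsilon` (batch objective), `S` (M x B fixed
#'   points, reusable as a warm start).
#' @export
gradient_K <- function(params, batch, tol = 1e-9, max_iter = 1e6,
                       zero_diagonal = FALSE, init = NULL,
                       newton_polish = TRUE) {
  stopifnot(inherits(params, "network_params"))
  X <- if (is.matrix(batch)) batch else matrix(batch, ncol = 1)
  if (nrow(X) != params$N) stop("batch must have N rows")
  B <- ncol(X)
  bat <- solve_fixed_points_batch(params, X, tol = tol, max_iter = max_iter,
                                  init = init, newton_polish = newton_polish)
  if (!all(bat$converged))
    stop("fixed point did not converge for sample(s) ",
         paste(which(!bat$converged), collapse = ", "))
  acc <- matrix(0, params$M, params$M)
  terms <- numeric(B)
  for (b in seq_len(B)) {
    bun <- susceptibility_at(params, bat$S[, b], bat$U[, b],
                             check_condition = FALSE)
    terms[b] <- -0.5 * logdet_ctc(bun$chi)
    acc <- acc + t(bun$chi_Gamma) + tcrossprod(crossprod(bun$phi, bun$a),
                                               bat$S[, b])
  }
  direction <- acc / B
  if (zero_diagonal) diag(direction) <- 0
  list(direction = direction, epsilon = mean(terms), S = bat$S)
}

#' Training configuration
#'
#' @param eta0 Initial learning rate (> 0).
#' @param batch_size Input samples per gradient step.
#' @param max_steps Maximum number of accepted gradient steps.
#' @param seed Integer seed controlling the input stream.
#' @param lookahead If `TRUE` (default), evaluate the objective on the current
#'   batch after a trial update; if it would increase, reject the step and
#'   halve the learning rate, then retry.
#' @param halving_factor Learning-rate multiplier on rejection, in (0, 1).
#' @param eta_floor Stop when the learning rate falls below this.
#' @param tol,max_iter Fixed-point solver controls used throughout training.
#' @param zero_diagonal Exclude self-connections from learning.
#' @param stability_margin Largest admissible spectral radius of
#'   `gamma0 * K` (default 1). The objective's information interpretation
#'   requires a smooth invertible input-output map; once the zero-input
#'   homogeneous state destabilizes (spectral radius of the zero-input gain
#'   times K reaching 1) the network enters the attractor ("hallucination")
#'   regime where fixed points no longer track the stimulus and the
#'   log-determinant stops measuring information. Trial updates that cross
#'   this boundary are rejected like objective increases, keeping learning
#'   in the subcritical domain where the gradient is meaningful. Set to
#'   `Inf` to disable.
#' @return A `"training_config"` list.
#' @export
training_config <- function(eta0 = 0.01, batch_size = 100, max_steps = 1000,
                            seed = 1L, lookahead = TRUE, halving_factor = 0.5,
                            eta_floor = 1e-7, tol = 1e-9, max_iter = 1e5,
                            zero_diagonal = FALSE, stability_margin = 1) {
  stopifnot(eta0 > 0, halving_factor > 0, halving_factor < 1,
            batch_size >= 1, max_steps >= 1, eta_floor > 0,
            stability_margin > 0)
  structure(list(eta0 = eta0, batch_size = batch_size, max_steps = max_steps,
                 seed = as.integer(seed), lookahead = lookahead,
                 halving_factor = halving_factor, eta_floor = eta_floor,
                 tol = tol, max_iter = max_iter,
                 zero_diagonal = zero_diagonal,
                 stability_margin = stability_margin),
            class = "training_config")
}

#' Train the recurrent weights by infomax gradient descent
#'
#' Iterates the gradient rule of [gradient_K()] from the supplied initial
#' network (conventionally K = 0). With lookahead on, each step first
#' evaluates the objective that the trial update would produce on the current
#' batch; an upcoming increase rejects the step and halves the learning rate
#' before retrying, which keeps the step size matched to the sharpening
#' curvature as the network approaches its critical point.
#'
#' @param initial A [network_params()] object (typically with K = 0).
#' @param sampler Function of one argument n returning an N x n input batch.
#'   Called inside a training-owned RNG stream seeded by `config$seed`.
#' @param config A [training_config()].
#' @param verbose Print progress every `verbose` steps (0 = silent).
#' @return A `"training_state"`: `params` (trained network), `step`, `eta`,
#'   `objective_history` (data.frame: step, epsilon_before, epsilon_after,
#'   eta, rejections), `accepted`, `rejected`, `config`.
#' @export
train_network <- function(initial, sampler, config = training_config(),
                          verbose = 0) {
  stopifnot(inherits(initial, "network_params"),
            inherits(config, "training_config"), is.function(sampler))
  params <- initial
  eta <- config$eta0
  hist <- vector("list", config$max_steps)
  accepted <- 0L; rejected <- 0L
  rng_old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(rng_old)) assign(".Random.seed", rng_old, globalenv()))
  set.seed(config$seed)
  for (step in seq_len(config$max_steps)) {
    X <- sampler(config$batch_size)
    gr <- tryCatch(
      gradient_K(params, X, tol = config$tol, max_iter = config$max_iter,
                 zero_diagonal = config$zero_diagonal),
      error = function(e)
        stop("solver failure at training step ", step, ": ",
             conditionMessage(e)))
    eps_before <- gr$epsilon
    rej_this <- 0L
    repeat {
      K_trial <- params$K + eta * gr$direction
      if (is.finite(config$stability_margin) &&
          spectral_radius(K_trial) * params$nl$gamma0 >=
            config$stability_margin) {
        eps_after <- Inf # supercritical trial: objective invalid there
      } else {
        trial <- network_params(params$W, K_trial, params$tau, params$nl)
        eps_after <- tryCatch(
          infomax_objective(trial, X, tol = config$tol,
                            max_iter = config$max_iter, init = gr$S)$epsilon,
          error = function(e) Inf)
      }
      if (is.finite(eps_after) &&
          (!config$lookahead || eps_after <= eps_before)) {
        params <- trial
        accepted <- accepted + 1L
        break
      }
      eta <- eta * config$halving_factor
      rejected <- rejected + 1L
      rej_this <- rej_this + 1L
      if (eta < config$eta_floor) break
    }
    hist[[step]] <- data.frame(step = step, epsilon_before = eps_before,
                               epsilon_after = eps_after, eta = eta,
                               rejections = rej_this)
    if (verbose > 0 && step %% verbose == 0)
      message(sprintf("step %d  epsilon %.4f  eta %.3g", step, eps_after, eta))
    if (eta < config$eta_floor) break
  }
  structure(list(params = params, step = step, eta = eta,
                 objective_history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
                 accepted = accepted, rejected = rejected, config = config),
            class = "training_state")
}

#' @export
print.training_state <- function(x, ...) {
  cat("<training_state> ", x$step, " steps (", x$accepted, " accepted, ",
      x$rejected, " rejected), final eta ", format(x$eta), "\n", sep = "")
  if (NROW(x$objective_history))
    cat("  final epsilon ",
        format(utils::tail(x$objective_history$epsilon_after, 1)), "\n",
        sep = "")
  invisible(x)
}


spectral_radius <- function(K) {
  max(Mod(eigen(K, only.values = TRUE)$values))
}
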