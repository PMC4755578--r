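#' Logistic transfer function and its derivatives
#'
#' Evaluates the logistic squashing function \eqn{g(u) = 1/(1+e^{-u})}
#' together with its first and second derivatives. These are the quantities
#' the recurrent dynamics and the susceptibility calculations need at every
#' operating point: the activity \eqn{g(u)}, the gain \eqn{g'(u) =
#' g(u)(1-g(u))} and the curvature \eqn{g''(u) = g'(u)(1-2g(u))}.
#'
#' @param u Numeric vector of net inputs (finite).
#' @return A list with components `value`, `deriv1` and `deriv2`, each the
#'   same length as `u`.
#' @examples
#' logistic(0) # value 0.5, gain 0.25, curvature 0
#' @export
logistic <- function(u) {
  v <- stats::plogis(u)
  d1 <- v * (1 - v)
  list(value = v, deriv1 = d1, deriv2 = d1 * (1 - 2 * v))
}

#' Nonlinearity specification
#'
#' Bundles a scalar squashing function with its first two derivatives and its
#' gain at zero input (`gamma0`), the constant that controls the location of
#' the ring model's critical point (`k1c = 2/gamma0`).
#'
#' @param name Identifier for the nonlinearity.
#' @param eval,deriv1,deriv2 Vectorized scalar maps.
#' @param gamma0 Value of `deriv1` at zero input.
#' @return An object of class `"nonlinearity"`.
#' @seealso [logistic_nonlinearity()]
#' @export
nonlinearity <- function(name, eval, deriv1, deriv2, gamma0) {
  stopifnot(is.character(name), is.function(eval), is.function(deriv1),
            is.function(deriv2), is.numeric(gamma0), length(gamma0) == 1L)
  if (abs(deriv1(0) - gamma0) > 1e-12)
    stop("gamma0 must equal deriv1(0)")
  structure(list(name = name, eval = eval, deriv1 = deriv1,
                 deriv2 = deriv2, gamma0 = gamma0),
            class = "nonlinearity")
}

#' The logistic nonlinearity, gamma0 = 1/4
#'
#' @return A `"nonlinearity"` object for \eqn{g(u) = 1/(1+e^{-u})}.
#' @export
logistic_nonlinearity <- function() {
  nonlinearity(
    name = "logistic",
    eval = function(u) stats::plogis(u),
    deriv1 = function(u) { v <- stats::plogis(u); v * (1 - v) },
    deriv2 = function(u) { v <- stats::plogis(u); v * (1 - v) * (1 - 2 * v) },
    gamma0 = 0.25
  )
}

#' @export
print.nonlinearity <- function(x, ...) {
  cat("<nonlinearity> ", x$name, " (gamma0 = ", format(x$gamma0), ")\n",
      sep = "")
  invisible(x)
}
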