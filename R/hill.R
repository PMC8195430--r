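#' Hill-function parameters
#'
#' Bundles the half-maximal concentration `K` and Hill coefficient `n` used by
#' the activating and repressing Hill responses of every gene-regulatory model
#' in the package.
#'
#' @param K Half-maximal concentration (concentration units). Must be `> 0`.
#' @param n Hill coefficient (dimensionless). Must be `> 0`.
#'
#' @return An object of class `hill_params`.
#' @examples
#' hill_params(K = 0.5, n = 2)
#' @export
hill_params <- function(K, n) {
  stopifnot(is.numeric(K), length(K) == 1L, is.numeric(n), length(n) == 1L)
  if (!is.finite(K) || K <= 0) abort("`K` must be a positive finite number.")
  if (!is.finite(n) || n <= 0) abort("`n` must be a positive finite number.")
  structure(list(K = K, n = n), class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("<hill_params> K = %g, n = %g\n", x$K, x$n))
  invisible(x)
}

#' Activating and repressing Hill responses
#'
#' The fractional promoter activity of an activating Hill function,
#' \eqn{(y/K)^n / (1 + (y/K)^n)}, or a repressing one,
#' \eqn{1 / (1 + (y/K)^n)}. Both map a nonnegative concentration to `[0, 1]`
#' and are monotone in `y`.
#'
#' @param y Nonnegative concentration(s).
#' @param p A [hill_params()] object.
#' @param mode `"activate"` or `"repress"`.
#'
#' @return Numeric vector of fractions in `[0, 1]`, same length as `y`.
#' @examples
#' p <- hill_params(K = 1, n = 2)
#' hill_response(1, p, "activate")   # 0.5 at half-max
#' hill_response(2, p, "repress")    # 1 / (1 + 4)
#' @export
hill_response <- function(y, p, mode = c("activate", "repress")) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "hill_params"))
  if (any(!is.finite(y)) || any(y < 0)) {
    abort("`y` must be finite and nonnegative.")
  }
  r <- (y / p$K)^p$n
  if (mode == "activate") r / (1 + r) else 1 / (1 + r)
}

# derivative of the repressing response, used in analytic Jacobians
hill_repress_deriv <- function(y, p) {
  r <- (y / p$K)^p$n
  # d/dy [1/(1+r)] = -(n/y) r / (1+r)^2; finite limit 0 at y = 0 for n > 1
  out <- numeric(length(y))
  pos <- y > 0
  out[pos] <- -(p$n / y[pos]) * r[pos] / (1 + r[pos])^2
  if (any(!pos) && p$n < 1) out[!pos] <- -Inf
  if (any(!pos) && p$n == 1) out[!pos] <- -1 / p$K
  out
}
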