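#' Morphogen gradient families
#'
#' A `gradient_spec` describes a morphogen concentration profile evaluable at
#' any time `t` and position `x`. Five families are supported:
#'
#' * `static_exp`: \eqn{b e^{-x/\lambda}} — a fixed exponential gradient.
#' * `emerging`: \eqn{b e^{-x/\lambda} (1 - e^{-\gamma t})} — grows from 0 at
#'   `t = 0` toward the static profile at rate `gamma`.
#' * `decaying`: \eqn{b e^{-x/\lambda - \gamma t}} — an established gradient
#'   whose amplitude decays exponentially in time.
#' * `bcd`: \eqn{b_m e^{-x/\lambda - \omega_0 (\max(t, t_0) - t_0)}} — a
#'   Bicoid-style gradient whose temporal decay at rate `omega0` begins only
#'   at onset time `t0`.
#' * `tabulated`: linear interpolation through an `(x, value)` table, with
#'   flat extrapolation beyond the table ends.
#'
#' All non-tabulated families are strictly decreasing in `x` at fixed `t`.
#'
#' @param b,bm Gradient amplitude (concentration). Must be `> 0`.
#' @param lam Length constant \eqn{\lambda} (length). Must be `> 0`; `Inf`
#'   gives a spatially uniform profile (useful for frozen-parameter systems).
#' @param gamma Temporal rate \eqn{\gamma} (1/time), `>= 0`.
#' @param omega0 Bcd-style decay rate \eqn{\omega_0} (1/time), `>= 0`.
#' @param t0 Onset time of Bcd-style decay (time), `>= 0`.
#' @param table Two-column data frame or matrix `(x, value)` with strictly
#'   increasing `x`.
#' @param g A `gradient_spec`.
#' @param t Time (scalar, `>= 0`).
#' @param x Position(s) along the axis.
#'
#' @return `gradient_*()` constructors return a `gradient_spec`;
#'   `eval_gradient()` returns concentrations, vectorised over `x`.
#' @examples
#' g <- gradient_emerging(b = 1, lam = 0.3, gamma = 0.5)
#' eval_gradient(g, t = 0, x = c(0, 0.5))     # all zero at t = 0
#' eval_gradient(g, t = 100, x = 0.5)          # ~ the static limit
#' @name gradients
NULL

new_gradient <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "gradient_spec")
}

check_amp_lam <- function(b, lam) {
  if (!is.finite(b) || b <= 0) abort("gradient amplitude must be positive and finite.")
  if (is.na(lam) || lam <= 0) abort("`lam` must be positive.")
}

#' @rdname gradients
#' @export
gradient_static <- function(b, lam) {
  check_amp_lam(b, lam)
  new_gradient("static_exp", b = b, lam = lam)
}

#' @rdname gradients
#' @export
gradient_emerging <- function(b, lam, gamma) {
  check_amp_lam(b, lam)
  if (!is.finite(gamma) || gamma < 0) abort("`gamma` must be >= 0.")
  new_gradient("emerging", b = b, lam = lam, gamma = gamma)
}

#' @rdname gradients
#' @export
gradient_decaying <- function(b, lam, gamma) {
  check_amp_lam(b, lam)
  if (!is.finite(gamma) || gamma < 0) abort("`gamma` must be >= 0.")
  new_gradient("decaying", b = b, lam = lam, gamma = gamma)
}

#' @rdname gradients
#' @export
gradient_bcd <- function(bm, lam, omega0, t0 = 0) {
  check_amp_lam(bm, lam)
  if (!is.finite(omega0) || omega0 < 0) abort("`omega0` must be >= 0.")
  if (!is.finite(t0) || t0 < 0) abort("`t0` must be >= 0.")
  new_gradient("bcd", bm = bm, lam = lam, omega0 = omega0, t0 = t0)
}

#' @rdname gradients
#' @export
gradient_tabulated <- function(table) {
  tab <- as.data.frame(table)
  if (ncol(tab) < 2L) abort("`table` needs columns (x, value).")
  names(tab)[1:2] <- c("x", "value")
  if (any(diff(tab$x) <= 0)) abort("tabulated `x` must be strictly increasing.")
  new_gradient("tabulated", table = tab[1:2])
}

#' @rdname gradients
#' @export
eval_gradient <- function(g, t, x) {
  stopifnot(inherits(g, "gradient_spec"), length(t) == 1L)
  if (!is.finite(t) || t < 0) abort("`t` must be a nonnegative time.")
  switch(g$kind,
    static_zero = rep(0, length(x)),
    static_exp = g$b * exp(-x / g$lam),
    emerging   = g$b * exp(-x / g$lam) * (1 - exp(-g$gamma * t)),
    decaying   = g$b * exp(-x / g$lam - g$gamma * t),
    bcd        = g$bm * exp(-x / g$lam - g$omega0 * (max(t, g$t0) - g$t0)),
    tabulated  = {
      if (any(x < g$table$x[1] - diff(range(g$table$x)) | x < 0)) {
        abort("`x` outside the tabulated range.")
      }
      stats::approx(g$table$x, g$table$value, xout = x, rule = 2)$y
    },
    abort(sprintf("unknown gradient kind '%s'", g$kind))
  )
}

#' The t -> infinity (or reference) static profile of a gradient
#'
#' For an emerging gradient this is its final profile
#' \eqn{b e^{-x/\lambda}}; for a decaying or Bcd-style gradient — whose long-
#' time limit vanishes — it is the established profile at the reference time
#' `t = 0` (respectively `t = t0`), the profile against which network
#' timescales are measured. Static and tabulated gradients are returned
#' unchanged.
#'
#' @param g A `gradient_spec`.
#' @return A static `gradient_spec`.
#' @export
gradient_limit <- function(g) {
  stopifnot(inherits(g, "gradient_spec"))
  switch(g$kind,
    static_exp = g,
    tabulated  = g,
    emerging   = gradient_static(g$b, g$lam),
    decaying   = gradient_static(g$b, g$lam),
    bcd        = gradient_static(g$bm, g$lam)
  )
}

#' Freeze a gradient at a time point
#'
#' Returns a static gradient equal to `g` evaluated at time `t` (the profile
#' used by instantaneous phase portraits).
#'
#' @param g A `gradient_spec`.
#' @param t Freeze time.
#' @return A static or tabulated `gradient_spec`.
#' @export
gradient_freeze <- function(g, t) {
  stopifnot(inherits(g, "gradient_spec"))
  switch(g$kind,
    static_exp = g,
    tabulated  = g,
    emerging   = {
      amp <- g$b * (1 - exp(-g$gamma * t))
      if (amp <= 0) new_gradient("static_zero") else gradient_static(amp, g$lam)
    },
    decaying   = gradient_static(g$b * exp(-g$gamma * t), g$lam),
    bcd        = gradient_static(g$bm * exp(-g$omega0 * (max(t, g$t0) - g$t0)), g$lam)
  )
}

#' @export
print.gradient_spec <- function(x, ...) {
  flds <- x[setdiff(names(x), c("kind", "table"))]
  cat(sprintf("<gradient_spec: %s> %s\n", x$kind,
              paste(names(flds), unlist(flds), sep = " = ", collapse = ", ")))
  if (x$kind == "tabulated") cat(sprintf("  table: %d points\n", nrow(x$table)))
  invisible(x)
}
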