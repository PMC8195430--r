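#' Mono/bistable classification along the axis
#'
#' Classifies the instantaneous local dynamics at every grid position and
#' locates the endpoints of the bistable interval (`x_a` anterior, `x_p`
#' posterior) and the anterior monostable-to-bistable transition (`x_crit`)
#' by bisection between adjacent grid cells of differing class.
#'
#' With several disjoint bistable runs (possible for non-monotone threshold
#' fields), `x_a`/`x_p` delimit the first run; the full per-position
#' classification is always returned.
#'
#' @param m A `bf_model`.
#' @param t Frozen time at which the portraits are taken.
#' @param xs Ascending grid of positions (default 101 points over `[0, L]`).
#' @param tol Position tolerance of the bisection (default `1e-4 * L`).
#'
#' @return A `bifurcation_scan`: list with `xs`, `classes`, `portraits`
#'   (fixed-point lists per position), `x_a`, `x_p`, `x_crit` (each `NA` if
#'   absent), `t`, and the generating model. Use [tidy()] for a per-position
#'   table and [glance()] for the interval summary.
#' @export
scan_axis <- function(m, t = 0, xs = NULL, tol = NULL) {
  stopifnot(inherits(m, "bf_model"))
  xs <- xs %||% seq(0, m$L, length.out = 101L)
  if (is.unsorted(xs, strictly = TRUE)) abort("`xs` must be strictly ascending.")
  tol <- tol %||% (1e-4 * m$L)

  portraits <- lapply(xs, function(x) find_fixed_points(m, x, t))
  classes <- vapply(portraits, classify_portrait, character(1), m = m)

  class_at <- function(x) classify_portrait(find_fixed_points(m, x, t), m)
  refine <- function(lo, hi, cl_lo) {
    # position where the class first differs from cl_lo, to within tol
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (identical(class_at(mid), cl_lo)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  bi <- classes == "bistable"
  x_a <- x_p <- x_crit <- NA_real_
  if (any(bi)) {
    i1 <- which(bi)[1]
    run_end <- i1
    while (run_end < length(xs) && bi[run_end + 1L]) run_end <- run_end + 1L
    x_a <- if (i1 == 1L) xs[1] else refine(xs[i1 - 1L], xs[i1], classes[i1 - 1L])
    x_p <- if (run_end == length(xs)) {
      xs[length(xs)]
    } else {
      refine(xs[run_end], xs[run_end + 1L], "bistable")
    }
    if (i1 > 1L && startsWith(classes[i1 - 1L], "mono")) x_crit <- x_a
  }

  structure(
    list(xs = xs, classes = classes, portraits = portraits,
         x_a = x_a, x_p = x_p, x_crit = x_crit, t = t, model = m, tol = tol),
    class = "bifurcation_scan")
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat(sprintf("<bifurcation_scan> t = %g, %d positions on [%g, %g]\n",
              x$t, length(x$xs), min(x$xs), max(x$xs)))
  cat(sprintf("  classes: %s\n",
              paste(rle(x$classes)$values, collapse = " -> ")))
  cat(sprintf("  x_a = %s, x_p = %s, x_crit = %s\n",
              format(x$x_a), format(x$x_p), format(x$x_crit)))
  invisible(x)
}

#' Critical parameter value of a mono/bistable transition
#'
#' Bisects a scalar parameter of the frozen no-diffusion system until the
#' classification changes, locating the bifurcation value to a stated
#' tolerance. Used, e.g., for the critical morphogen concentration separating
#' monostable from bistable local dynamics.
#'
#' @param make_model Function taking the scalar parameter and returning a
#'   `bf_model` (classification is evaluated at `(x, t)` of that model).
#' @param interval Length-2 numeric bracket; classification must differ at
#'   its endpoints.
#' @param x,t Position and frozen time at which portraits are evaluated.
#' @param tol Absolute tolerance on the parameter (default `1e-6`).
#'
#' @return The critical parameter value.
#' @examples
#' # the cubic model loses bistability at alpha = 0 and 1
#' f <- function(a) build_model("scalar", scalar_params(0, a))
#' critical_parameter(f, c(0.5, 1.5))  # ~1
#' @export
critical_parameter <- function(make_model, interval, x = 0, t = 0, tol = 1e-6) {
  stopifnot(is.function(make_model), length(interval) == 2L)
  cls <- function(theta) {
    classify_portrait(find_fixed_points(make_model(theta), x, t),
                      make_model(theta))
  }
  lo <- min(interval); hi <- max(interval)
  c_lo <- cls(lo); c_hi <- cls(hi)
  if (identical(c_lo, c_hi)) {
    abort("classification is the same at both interval endpoints (no bracket).")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (identical(cls(mid), c_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
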