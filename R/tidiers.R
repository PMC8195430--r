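# broom-style tidiers for the package's result objects.

#' Tidy a bifurcation scan
#'
#' One row per grid position with the classification and the fixed-point
#' branches (`u<j>_low`, `u<j>_high`, `u<j>_unstable` per species `j`,
#' `NA` where a branch does not exist).
#'
#' @param x A `bifurcation_scan`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.bifurcation_scan <- function(x, ...) {
  ns <- x$model$n_species
  rows <- purrr::map2(x$xs, x$portraits, function(xi, fps) {
    hl <- high_low_states(fps)
    up <- unstable_points(fps)
    vals <- c(
      setNames(as.list(if (is.null(hl$low)) rep(NA_real_, ns) else hl$low$state),
               paste0("u", seq_len(ns), "_low")),
      setNames(as.list(if (is.null(hl$high)) rep(NA_real_, ns) else hl$high$state),
               paste0("u", seq_len(ns), "_high")),
      setNames(as.list(if (length(up) == 0L) rep(NA_real_, ns) else up[[1]]$state),
               paste0("u", seq_len(ns), "_unstable")))
    # a single stable point is reported on its own side only
    if (!is.null(hl$low) && !is.null(hl$high) &&
        identical(hl$low, hl$high)) {
      side <- if (hl$low$state[1] > x$model$umax[1] / 2) "low" else "high"
      vals[paste0("u", seq_len(ns), "_", side)] <- NA_real_
    }
    as_tibble(c(list(x = xi), vals))
  })
  out <- dplyr::bind_rows(rows)
  out$class <- x$classes
  dplyr::relocate(out, "class", .after = "x")
}

#' @rdname tidy.bifurcation_scan
#' @exportS3Method generics::glance
glance.bifurcation_scan <- function(x, ...) {
  tibble(t = x$t, x_a = x$x_a, x_p = x$x_p, x_crit = x$x_crit,
         n_positions = length(x$xs),
         n_bistable = sum(x$classes == "bistable"))
}

#' Tidy a PDE solution into a long table
#'
#' @param x A `pde_solution`.
#' @param ... Unused.
#' @return A tibble `(t, x, species, value)`.
#' @exportS3Method generics::tidy
tidy.pde_solution <- function(x, ...) {
  d <- dim(x$fields)
  vals <- as.vector(x$fields)  # before tibble(): its `x` column masks `x`
  tibble(
    t = rep(x$ts, times = d[2] * d[3]),
    x = rep(rep(x$grid$xs, each = d[1]), times = d[3]),
    species = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = vals)
}

#' @rdname tidy.pde_solution
#' @exportS3Method generics::glance
glance.pde_solution <- function(x, ...) {
  tibble(t0 = min(x$ts), t1 = max(x$ts), n_times = length(x$ts),
         N = x$grid$N, L = x$grid$L, n_species = dim(x$fields)[3],
         min_value = min(x$fields), max_value = max(x$fields))
}

#' Summaries of experiment results
#'
#' @param x An `emergence_result` or `sweep_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.emergence_result <- function(x, ...) {
  tibble(n_kappa = nrow(x), sigma = x$sigma[1],
         R_min = min(x$R), R_max = max(x$R))
}

#' @rdname glance.emergence_result
#' @exportS3Method generics::glance
glance.sweep_result <- function(x, ...) {
  tibble(t_f = x$t_f[1], R = x$R[1], swept = x$swept[1])
}
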