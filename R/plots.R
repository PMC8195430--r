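# ggplot2 quick-look figures for the package's result types.

#' Plot a bifurcation scan
#'
#' Species-1 steady-state branches along the axis: stable branches solid,
#' the unstable branch dashed; the bistable interval shaded.
#'
#' @param object A `bifurcation_scan`.
#' @param species Species to plot (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bifurcation_scan <- function(object, species = 1L, ...) {
  td <- tidy(object)
  cols <- paste0("u", species, c("_low", "_high", "_unstable"))
  long <- tidyr::pivot_longer(td[, c("x", cols)], -"x",
                              names_to = "branch", values_to = "u")
  long$stability <- ifelse(grepl("unstable", long$branch), "unstable", "stable")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$u,
                                          group = .data$branch,
                                          linetype = .data$stability)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dashed")) +
    ggplot2::labs(x = "position x", y = sprintf("u%d steady state", species))
  if (!is.na(object$x_a)) {
    p <- p + ggplot2::annotate("rect", xmin = object$x_a, xmax = object$x_p,
                               ymin = -Inf, ymax = Inf, alpha = 0.12)
  }
  p
}

#' Kymograph of a PDE solution
#'
#' @param object A `pde_solution`.
#' @param species Species to display (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pde_solution <- function(object, species = 1L, ...) {
  td <- dplyr::filter(tidy(object), .data$species == !!species)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$t,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "position x", y = "time",
                  fill = sprintf("u%d", species))
}

#' Plot a boundary trajectory
#'
#' @param object A `boundary_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.boundary_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$w)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time", y = "boundary position w(t)")
}

#' Plot a front-velocity map
#'
#' @param object A `velocity_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.velocity_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$c)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$extrapolated)) +
    ggplot2::labs(x = "position x", y = "local front velocity c(x)")
}

#' Plot precision against kappa
#'
#' @param object An `emergence_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.emergence_result <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      kappa_label = factor(format(.data$kappa)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kappa_label, y = .data$R)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(kappa), y = "irregularity R")
}
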