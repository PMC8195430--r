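# Local (frozen-parameter) front velocities, velocity-vs-position maps, the
# single-variable ODE approximation of boundary position, and front
# localization points.

#' Local front velocity at frozen parameters
#'
#' Builds the spatially homogeneous companion system with every bifurcation
#' parameter fixed at its `(t, x)` value, starts a step profile between the
#' two stable states on an auxiliary domain a prescribed number of front
#' widths long, integrates, and fits a least-squares line through the
#' extracted boundary positions (the initial quarter of the usable window is
#' discarded as transient). Sign convention: `c > 0` means the high-species-1
#' domain expands toward larger `x`.
#'
#' For the scalar cubic family the closed form
#' \eqn{c = (1 - 2\alpha)\sqrt{D/2}} is used unless `method = "simulate"`.
#'
#' @param m A `bf_model`.
#' @param x Position whose parameter values are frozen.
#' @param t Frozen time.
#' @param method `"auto"` (closed form for the scalar family, simulation
#'   otherwise), `"simulate"`, or `"closed_form"` (scalar only).
#' @param n_widths Auxiliary domain length in units of the front width
#'   `sqrt(D_max / beta_eff)` (default 40).
#' @param nodes_per_width Spatial resolution (default 24 nodes per width).
#' @param refine If `TRUE`, double the domain and resolution until the
#'   fitted speed changes by less than 1% (at most two doublings).
#'
#' @return The signed front velocity (length/time).
#' @export
frozen_front_speed <- function(m, x, t = 0,
                               method = c("auto", "simulate", "closed_form"),
                               n_widths = 40, nodes_per_width = 24,
                               refine = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(m, "bf_model"))
  if (method == "closed_form" && m$tag != "scalar") {
    abort("closed-form speed is only available for the scalar family.")
  }
  if (m$tag == "scalar" && method != "simulate") {
    a <- m$params$alpha_field(x)
    if (a <= 0 || a >= 1) abort("monostable parameters: no front exists.")
    return((1 - 2 * a) * sqrt(m$params$D / 2))
  }

  est <- front_speed_sim(m, x, t, n_widths, nodes_per_width)
  if (refine) {
    for (k in 1:2) {
      est2 <- front_speed_sim(m, x, t, n_widths * 2^k, nodes_per_width)
      ref <- max(abs(est2$c), 1e-12)
      done <- abs(est2$c - est$c) < 0.01 * ref
      est <- est2
      if (done) break
    }
  }
  # an R^2 criterion is meaningless for a stationary front: require the
  # fitted displacement to be resolvable on the grid before complaining
  if (est$r2 < 0.999 && abs(est$c) * est$t_window > est$dx) {
    warn(sprintf("front-speed fit R^2 = %.4f < 0.999 (convergence warning).",
                 est$r2))
  }
  est$c
}

front_speed_sim <- function(m, x, t, n_widths, nodes_per_width) {
  mc <- companion_model(m, x, t, L_aux = 1)  # length set below
  fps <- find_fixed_points(mc, 0, 0)
  st <- stable_points(fps)
  if (length(st) != 2L) abort("monostable parameters: no front exists.")
  up <- unstable_points(fps)
  hl <- high_low_states(fps)
  beta_eff <- min(vapply(st, function(p) abs(p$leading_rate), numeric(1)))
  Dmax <- max(mc$diffusivities)
  if (Dmax <= 0) abort("all diffusivities are zero: no travelling front.")
  ell <- sqrt(Dmax / beta_eff)
  L_aux <- n_widths * ell
  mc$L <- L_aux
  N <- as.integer(round(n_widths * nodes_per_width)) + 1L
  grid <- rd_grid(N, L_aux)

  # step initial condition: high state on the left, low on the right
  half <- grid$xs <= L_aux / 2
  U0 <- matrix(rep(hl$low$state, each = N), nrow = N)
  U0[half, ] <- matrix(rep(hl$high$state, each = sum(half)), nrow = sum(half))
  uref <- if (length(up) > 0L) up[[1]]$state[1] else {
    (hl$high$state[1] + hl$low$state[1]) / 2
  }

  Tmax <- 20 / beta_eff
  nt <- 81L
  sol <- integrate_rd(mc, U0, c(0, Tmax), grid = grid, nt = nt,
                      rtol = 1e-8)
  pos <- vapply(seq_len(nt), function(k) {
    cr <- profile_crossings(grid$xs, sol$fields[k, , 1] - uref)
    if (length(cr) == 0L) return(NA_real_)
    cr[which.min(abs(cr - L_aux / 2))]
  }, numeric(1))
  safe <- !is.na(pos) & pos > 5 * ell & pos < L_aux - 5 * ell
  keep <- which(safe)
  first_bad <- which(!safe)
  first_bad <- first_bad[first_bad > 1L]
  if (length(first_bad) > 0L) keep <- keep[keep < min(first_bad)]
  if (length(keep) < 8L) {
    abort("front left the measurement window too quickly; enlarge `n_widths`.")
  }
  keep <- keep[-seq_len(ceiling(length(keep) / 4))]  # drop initial transient
  fit <- lm(pos[keep] ~ sol$ts[keep])
  r2 <- summary(fit)$r.squared
  if (is.na(r2)) r2 <- 1  # zero-variance positions: stationary front
  list(c = unname(coef(fit)[2]), r2 = r2, dx = grid$dx,
       t_window = diff(range(sol$ts[keep])))
}

#' Front-velocity map along the axis
#'
#' Evaluates [frozen_front_speed()] at every bistable grid position,
#' computing the speed once per distinct frozen morphogen value and mapping
#' it back to positions. Positions within `near_frac * L` of the bistable-
#' interval endpoints are linearly extrapolated from their neighbours rather
#' than simulated (front speeds diverge in cost near the bifurcation) and
#' flagged in the output.
#'
#' @param m A `bf_model`.
#' @param xs Candidate positions (default 41 over `[0, L]`).
#' @param t Frozen time.
#' @param scan Optional precomputed `bifurcation_scan` at `t` (reused for
#'   the bistable classification).
#' @param near_frac Fraction of `L` near the interval endpoints to
#'   extrapolate (default 0.01).
#' @param ... Passed to [frozen_front_speed()].
#'
#' @return A `velocity_map` tibble `(x, c, extrapolated)` restricted to the
#'   bistable positions, with the scan attached as an attribute.
#' @export
velocity_map <- function(m, xs = NULL, t = 0, scan = NULL,
                         near_frac = 0.01, ...) {
  stopifnot(inherits(m, "bf_model"))
  xs <- xs %||% seq(0, m$L, length.out = 41L)
  scan <- scan %||% scan_axis(m, t = t, xs = xs)
  if (is.na(scan$x_a)) abort("no bistable region: empty velocity map.")
  keep <- xs >= scan$x_a & xs <= scan$x_p
  xs <- xs[keep]
  near <- (xs - scan$x_a < near_frac * m$L) | (scan$x_p - xs < near_frac * m$L)
  if (all(near)) near[] <- FALSE

  cache <- new.env(parent = emptyenv())
  key_of <- function(x) {
    vals <- if (m$tag == "scalar") m$params$alpha_field(x) else {
      vapply(m$gradients, eval_gradient, numeric(1), t = t, x = x)
    }
    paste(signif(vals, 12), collapse = "|")
  }
  cvals <- rep(NA_real_, length(xs))
  for (i in which(!near)) {
    k <- key_of(xs[i])
    if (is.null(cache[[k]])) {
      cache[[k]] <- frozen_front_speed(m, xs[i], t, ...)
    }
    cvals[i] <- cache[[k]]
  }
  if (any(near)) {
    good <- which(!near)
    # linear extrapolation from the two nearest simulated entries
    lin_ext <- function(xq) {
      if (xq <= xs[good[1]]) {
        i <- good[1:2]
      } else if (xq >= xs[good[length(good)]]) {
        i <- good[c(length(good) - 1L, length(good))]
      } else {
        return(stats::approx(xs[good], cvals[good], xout = xq)$y)
      }
      cvals[i[1]] + (cvals[i[2]] - cvals[i[1]]) *
        (xq - xs[i[1]]) / (xs[i[2]] - xs[i[1]])
    }
    cvals[near] <- vapply(xs[near], lin_ext, numeric(1))
  }
  out <- tibble(x = xs, c = cvals, extrapolated = near)
  attr(out, "scan") <- scan
  attr(out, "t") <- t
  attr(out, "L") <- m$L
  class(out) <- c("velocity_map", class(out))
  out
}

# piecewise-linear interpolant of a velocity map; NA outside its domain
vm_fun <- function(vm) {
  stopifnot(inherits(vm, "velocity_map"))
  approxfun(vm$x, vm$c, rule = 1)
}

#' ODE approximation of boundary position
#'
#' Integrates the single-variable approximation `dw/dt = c(w + eps)` of
#' propagating-boundary position over a front-velocity map, with `eps` a
#' constant correction offset (0 is appropriate for equal diffusivities).
#' Integration halts cleanly when `w + eps` reaches the edge of the map's
#' bistable domain (the trajectory is then flagged truncated).
#'
#' For a time-varying system pass `vm_family`, a list of maps with their
#' times (see [velocity_map_family()]); `c` is then interpolated linearly in
#' time between the scheduled maps.
#'
#' @param vm A `velocity_map`, or a `velocity_map_family`.
#' @param w0 Initial boundary position.
#' @param eps Correction offset (length units; default 0).
#' @param t_span Length-2 time interval.
#' @param nt Number of output times.
#' @param times Explicit output times (overrides `t_span`/`nt`), e.g. the
#'   output times of a PDE solution being compared against.
#'
#' @return A `front_approx` tibble `(t, w)` with attributes `eps`, `w0`,
#'   `truncated`.
#' @export
ode_boundary <- function(vm, w0, eps = 0, t_span, nt = 201L, times = NULL) {
  fam <- inherits(vm, "velocity_map_family")
  if (!fam) stopifnot(inherits(vm, "velocity_map"))
  cfun <- if (fam) vm_family_fun(vm) else {
    f <- vm_fun(vm); function(t, x) f(x)
  }
  dom <- if (fam) vm$domain else range(vm$x)
  if (w0 + eps < dom[1] || w0 + eps > dom[2]) {
    abort("`w0 + eps` lies outside the velocity map's bistable domain.")
  }
  margin <- 1e-9 * (dom[2] - dom[1])
  derivs <- function(t, y, parms) {
    xq <- min(max(y + eps, dom[1]), dom[2])
    list(cfun(t, xq))
  }
  rootfun <- function(t, y, parms) {
    c(y + eps - dom[1] - margin, dom[2] - margin - (y + eps))
  }
  ts <- times %||% seq(t_span[1], t_span[2], length.out = nt)
  nt <- length(ts)
  sol <- deSolve::lsodar(y = w0, times = ts, func = derivs, parms = NULL,
                         rootfunc = rootfun, rtol = 1e-10, atol = 1e-12)
  w <- rep(NA_real_, nt)
  got <- match(round(sol[, 1], 12), round(ts, 12))
  w[got[!is.na(got)]] <- sol[!is.na(got), 2]
  truncated <- nrow(sol) < nt
  out <- tibble(t = ts, w = w)
  attr(out, "eps") <- eps
  attr(out, "w0") <- w0
  attr(out, "truncated") <- truncated
  class(out) <- c("front_approx", class(out))
  out
}

#' Velocity maps on a time schedule
#'
#' Precomputes instantaneous velocity maps of a time-varying model at a
#' fixed schedule of freeze times, for use by [ode_boundary()] with linear
#' interpolation in time.
#'
#' @param m A `bf_model` with time-varying gradients.
#' @param ts Freeze times (e.g. `seq(t0, t1, length.out = 11)`).
#' @param xs Candidate positions per map.
#' @param ... Passed to [velocity_map()].
#' @return A `velocity_map_family`.
#' @export
velocity_map_family <- function(m, ts, xs = NULL, ...) {
  maps <- lapply(ts, function(tt) velocity_map(m, xs = xs, t = tt, ...))
  dom <- c(max(vapply(maps, function(v) min(v$x), numeric(1))),
           min(vapply(maps, function(v) max(v$x), numeric(1))))
  structure(list(ts = ts, maps = maps, domain = dom),
            class = "velocity_map_family")
}

vm_family_fun <- function(fam) {
  funs <- lapply(fam$maps, vm_fun)
  ts <- fam$ts
  function(t, x) {
    if (t <= ts[1]) return(funs[[1]](x))
    if (t >= ts[length(ts)]) return(funs[[length(ts)]](x))
    i <- findInterval(t, ts)
    w <- (t - ts[i]) / (ts[i + 1] - ts[i])
    (1 - w) * funs[[i]](x) + w * funs[[i + 1]](x)
  }
}

#' Front localization points
#'
#' Sign-change roots of the front-velocity map: positions where the local
#' front velocity crosses zero so that fronts forming on either side
#' propagate toward (attracting, `c` passing from + to - with increasing
#' `x`) or away from (repelling) the point.
#'
#' @param vm A `velocity_map`.
#' @return A tibble `(x_l, stability)`; zero rows if `c` never changes sign.
#' @export
localization_points <- function(vm) {
  stopifnot(inherits(vm, "velocity_map"))
  x <- vm$x; cv <- vm$c
  out <- list()
  for (i in seq_len(length(x) - 1L)) {
    if (is.na(cv[i]) || is.na(cv[i + 1])) next
    if (cv[i] == 0) {
      out[[length(out) + 1L]] <- list(x_l = x[i],
        stability = if (cv[i + 1] < 0) "attracting" else "repelling")
    } else if (cv[i] * cv[i + 1] < 0) {
      xr <- x[i] - cv[i] * (x[i + 1] - x[i]) / (cv[i + 1] - cv[i])
      out[[length(out) + 1L]] <- list(x_l = xr,
        stability = if (cv[i] > 0) "attracting" else "repelling")
    }
  }
  dplyr::bind_rows(lapply(out, as_tibble))
}

#' Boundary-width-based correction offset
#'
#' The convention of taking `|eps|` as a quarter of the boundary width, read
#' from a PDE boundary trajectory. Returns a magnitude; the caller chooses
#' the sign.
#'
#' @param traj A `boundary_trajectory`.
#' @param frac Fraction of the width (default 0.25).
#' @return A length (same units as `x`).
#' @export
eps_from_width <- function(traj, frac = 0.25) {
  stopifnot(inherits(traj, "boundary_trajectory"))
  frac * stats::median(traj$width, na.rm = TRUE)
}

#' Compare a PDE boundary trajectory with its ODE approximation
#'
#' Aligns the two trajectories on shared times (from front formation onward)
#' and reports the per-time discrepancy.
#'
#' @param traj A `boundary_trajectory` (PDE extraction).
#' @param appr A `front_approx` ([ode_boundary()] result), computed at the
#'   trajectory's output times.
#' @return A tibble `(t, w_pde, w_ode, error)` with attribute `max_error`.
#' @export
compare_boundary <- function(traj, appr) {
  stopifnot(inherits(traj, "boundary_trajectory"),
            inherits(appr, "front_approx"))
  d <- dplyr::inner_join(
    tibble(t = traj$t, w_pde = traj$w),
    tibble(t = appr$t, w_ode = appr$w), by = "t")
  d <- dplyr::filter(d, !is.na(.data$w_pde), !is.na(.data$w_ode))
  d <- dplyr::mutate(d, error = abs(.data$w_pde - .data$w_ode))
  attr(d, "max_error") <- if (nrow(d) > 0L) max(d$error) else NA_real_
  d
}
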