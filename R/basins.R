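# Basin-of-attraction labelling and network/gradient timescales.

# Integrate a stack of states of the frozen no-diffusion system at position x
# until each is within `radius` (max-norm, relative to the attractor's scale)
# of a stable fixed point, or a time cap is hit. Returns "high"/"low"/
# "indeterminate" per row of `states`.
label_states <- function(mf, x, fps, states,
                         radius = 1e-4, cap_factor = 50) {
  st <- stable_points(fps)
  n <- nrow(states)
  if (length(st) == 0L) return(rep("indeterminate", n))
  hl <- high_low_states(fps)
  if (length(st) == 1L) {
    lab <- if (st[[1]]$state[1] > mf$umax[1] / 2) "high" else "low"
    return(rep(lab, n))
  }

  scales <- lapply(st, function(p) pmax(abs(p$state), 1e-2 * mf$umax))
  near <- function(u) {
    for (k in seq_along(st)) {
      if (max(abs(u - st[[k]]$state) / scales[[k]]) < radius) return(k)
    }
    0L
  }
  sigma_loc <- min(vapply(st, function(p) abs(p$leading_rate), numeric(1)))
  t_cap <- cap_factor / sigma_loc
  dt <- t_cap / 10

  ns <- mf$n_species
  labels <- rep(NA_character_, n)
  active <- seq_len(n)
  U <- states
  derivs <- function(t, y, parms) {
    list(as.vector(mf$rhs_vec(t, rep(x, length(y) / ns),
                              matrix(y, ncol = ns))))
  }
  t_now <- 0
  while (length(active) > 0L && t_now < t_cap) {
    y0 <- as.vector(U[active, , drop = FALSE])
    sol <- deSolve::ode(y = y0, times = c(0, dt), func = derivs, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10 * max(mf$umax))
    yT <- matrix(sol[nrow(sol), -1], ncol = ns)
    U[active, ] <- yT
    reached <- vapply(seq_len(nrow(yT)), function(i) near(yT[i, ]), integer(1))
    done <- reached > 0L
    if (any(done)) {
      idx <- active[done]
      labels[idx] <- vapply(reached[done], function(k) {
        if (identical(st[[k]], hl$high)) "high" else "low"
      }, character(1))
      active <- active[!done]
    }
    t_now <- t_now + dt
  }
  labels[is.na(labels)] <- "indeterminate"
  labels
}

#' Basin membership of an initial condition
#'
#' Integrates the frozen no-diffusion system at `(x, t)` from `ic` until the
#' trajectory settles within a convergence radius of a stable fixed point
#' (max-norm, relative to the attractor's scale) and labels it by the reached
#' attractor: `"high"` (high species-1 state) or `"low"`. If the time cap
#' (`cap_factor` over the slowest local convergence rate) is hit first, the
#' label is `"indeterminate"`; callers treat that conservatively.
#'
#' @param m A `bf_model`.
#' @param x Position.
#' @param t Frozen time.
#' @param ic Initial state vector (length `n_species`), or a matrix with one
#'   state per row.
#' @param radius Convergence radius (relative max-norm, default `1e-4`).
#' @param cap_factor Time cap in units of the slowest local timescale.
#'
#' @return Character vector of labels, one per initial condition.
#' @export
basin_label <- function(m, x, t, ic, radius = 1e-4, cap_factor = 50) {
  stopifnot(inherits(m, "bf_model"))
  states <- if (is.matrix(ic)) ic else matrix(ic, nrow = 1L)
  if (ncol(states) != m$n_species) abort("`ic` has the wrong number of species.")
  if (any(states < 0)) abort("initial conditions must be nonnegative.")
  mf <- freeze_model(m, t)
  fps <- find_fixed_points(mf, x, t)
  label_states(mf, x, fps, states, radius = radius, cap_factor = cap_factor)
}

#' Network and gradient timescales: sigma and kappa
#'
#' `sigma` is the minimum rate of convergence to a stable steady state over
#' all bistable positions of the gradient's reference static profile (the
#' final profile of an emerging gradient; the established `t = 0` profile of
#' a decaying or Bcd-style one), measured as the magnitude of the leading
#' Jacobian eigenvalue at each stable fixed point. `kappa = gamma / sigma`
#' compares the gradient's temporal rate to the slowest network timescale:
#' `kappa << 1` means the network tracks the gradient quasi-statically.
#'
#' @param m A `bf_model` with an emerging, decaying or Bcd-style gradient.
#' @param gamma Gradient temporal rate (defaults to the rate stored in the
#'   model's first gradient).
#' @param xs Scan grid (default 101 positions).
#' @param scan Optionally a precomputed `bifurcation_scan` of the reference
#'   profile (its portraits are reused).
#'
#' @return A list with `sigma`, `kappa` and the reference `scan`.
#' @export
sigma_and_kappa <- function(m, gamma = NULL, xs = NULL, scan = NULL) {
  stopifnot(inherits(m, "bf_model"))
  g1 <- m$gradients[[1]]
  gamma <- gamma %||% g1$gamma %||% g1$omega0
  if (is.null(gamma)) abort("no temporal rate `gamma` available.")
  if (is.null(scan)) {
    m_inf <- build_model(m$tag, m$params, lapply(m$gradients, gradient_limit), m$L)
    m_inf$diffusivities <- m$diffusivities
    scan <- scan_axis(m_inf, t = 0, xs = xs)
  }
  bi <- which(scan$classes == "bistable")
  if (length(bi) == 0L) {
    abort("no bistable position at the reference profile; sigma undefined.")
  }
  rates <- unlist(lapply(scan$portraits[bi], function(fps) {
    vapply(stable_points(fps), function(p) abs(p$leading_rate), numeric(1))
  }))
  sigma <- min(rates)
  list(sigma = sigma, kappa = gamma / sigma, scan = scan)
}
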