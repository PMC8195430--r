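# Method-of-lines reaction-diffusion integration with no-flux boundaries,
# and extraction of boundary trajectories from solutions.

#' Spatial grid
#'
#' Node-centred uniform grid on `[0, L]` with both endpoints included.
#'
#' @param N Node count (`>= 16`).
#' @param L Domain length.
#' @return A `bf_grid`: list with `N`, `L`, `dx`, `xs`.
#' @export
rd_grid <- function(N = 401L, L = 1) {
  N <- as.integer(N)
  if (N < 16L) abort("`N` must be at least 16.")
  if (!is.finite(L) || L <= 0) abort("`L` must be positive.")
  structure(list(N = N, L = L, dx = L / (N - 1L),
                 xs = seq(0, L, length.out = N)),
            class = "bf_grid")
}

# second-order Laplacian with mirrored ghost nodes (no-flux)
laplacian_noflux <- function(u, dx) {
  n <- length(u)
  out <- numeric(n)
  out[2:(n - 1L)] <- (u[1:(n - 2L)] - 2 * u[2:(n - 1L)] + u[3:n]) / dx^2
  out[1L] <- 2 * (u[2L] - u[1L]) / dx^2
  out[n] <- 2 * (u[n - 1L] - u[n]) / dx^2
  out
}

#' Integrate a reaction-diffusion model
#'
#' Solves \eqn{\partial_t u = f(t, x, u) + D \partial_x^2 u} on `[0, L]` with
#' no-flux (mirrored-ghost) boundaries by the method of lines: second-order
#' central Laplacian in space, stiff-capable adaptive integration (lsoda,
#' banded Jacobian) in time. Species with `D = 0` reduce exactly to per-node
#' reaction ODEs. Time-varying gradients are evaluated inside the right-hand
#' side at solver time. Nonnegativity is checked diagnostically (warning
#' below `-1e-9`), never enforced by clipping.
#'
#' @param m A `bf_model`.
#' @param ic_profile Initial condition: `N x n_species` matrix, a length-
#'   `n_species` vector recycled across nodes, or a function of `x` returning
#'   a state per position.
#' @param t_span Length-2 time interval `c(t0, t1)`.
#' @param grid A [rd_grid()] (default 401 nodes on `[0, m$L]`).
#' @param nt Number of output times (default 201, i.e. every
#'   `diff(t_span)/200`).
#' @param rtol,atol Solver tolerances.
#'
#' @return A `pde_solution`: list with `ts`, `grid`, `fields` (array `time x
#'   node x species`) and the model. [tidy()] gives a long `(t, x, species,
#'   value)` tibble.
#' @export
integrate_rd <- function(m, ic_profile, t_span, grid = NULL, nt = 201L,
                         rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(m, "bf_model"), length(t_span) == 2L)
  grid <- grid %||% rd_grid(401L, m$L)
  ns <- m$n_species
  N <- grid$N
  atol <- atol %||% (1e-10 * max(m$umax))

  U0 <- if (is.function(ic_profile)) {
    prof <- t(vapply(grid$xs, function(x) {
      v <- ic_profile(x); stopifnot(length(v) == ns); as.numeric(v)
    }, numeric(ns)))
    prof
  } else if (is.matrix(ic_profile)) {
    stopifnot(nrow(ic_profile) == N, ncol(ic_profile) == ns)
    ic_profile
  } else {
    stopifnot(length(ic_profile) == ns)
    matrix(rep(ic_profile, each = N), nrow = N)
  }
  if (any(U0 < 0)) abort("initial profile must be nonnegative.")

  D <- m$diffusivities
  xs <- grid$xs
  dx <- grid$dx
  derivs <- function(t, y, parms) {
    U <- matrix(y, ncol = ns, byrow = TRUE)  # interleaved: node-major
    dU <- m$rhs_vec(t, xs, U)
    for (s in which(D > 0)) {
      dU[, s] <- dU[, s] + D[s] * laplacian_noflux(U[, s], dx)
    }
    list(as.vector(t(dU)))
  }

  ts <- seq(t_span[1], t_span[2], length.out = nt)
  sol <- deSolve::ode(y = as.vector(t(U0)), times = ts, func = derivs,
                      parms = NULL, method = "lsoda",
                      jactype = "bandint", bandup = ns, banddown = ns,
                      rtol = rtol, atol = atol)
  ok <- stats::complete.cases(sol)
  if (!all(ok)) {
    abort(sprintf("integrator failed; last good time %.6g.",
                  sol[max(which(ok)), 1]))
  }
  fields <- array(NA_real_, dim = c(nt, N, ns))
  for (k in seq_len(nt)) {
    fields[k, , ] <- matrix(sol[k, -1], ncol = ns, byrow = TRUE)
  }
  if (min(fields) < -1e-9) {
    warn(sprintf("solution dips to %.3g < -1e-9 (solver error not masked).",
                 min(fields)))
  }
  structure(list(ts = ts, grid = grid, fields = fields, model = m),
            class = "pde_solution")
}

#' @export
print.pde_solution <- function(x, ...) {
  cat(sprintf("<pde_solution> %d times on [%g, %g], %d nodes, %d species\n",
              length(x$ts), min(x$ts), max(x$ts), x$grid$N,
              dim(x$fields)[3]))
  invisible(x)
}

# reference curve for boundary extraction: the local unstable steady state
# inside the bistable interval, the midpoint of the bistable-region stable
# branches (clamped interpolation) outside it. Also returns the local high/
# low branch values used for width levels.
reference_curves <- function(scan, species = 1L) {
  bi <- which(scan$classes == "bistable")
  if (length(bi) == 0L) abort("scan has no bistable region.")
  xb <- scan$xs[bi]
  uu <- vapply(scan$portraits[bi], function(fps) {
    up <- unstable_points(fps)
    if (length(up) == 0L) NA_real_ else up[[1]]$state[species]
  }, numeric(1))
  hi <- vapply(scan$portraits[bi], function(fps) {
    high_low_states(fps)$high$state[species]
  }, numeric(1))
  lo <- vapply(scan$portraits[bi], function(fps) {
    high_low_states(fps)$low$state[species]
  }, numeric(1))
  clamp <- function(x) pmin(pmax(x, min(xb)), max(xb))
  fu <- if (length(xb) > 1L) approxfun(xb, uu, rule = 2) else function(x) rep(uu, length(x))
  fh <- if (length(xb) > 1L) approxfun(xb, hi, rule = 2) else function(x) rep(hi, length(x))
  fl <- if (length(xb) > 1L) approxfun(xb, lo, rule = 2) else function(x) rep(lo, length(x))
  list(
    ref = function(x) {
      inside <- x >= scan$x_a & x <= scan$x_p & !is.na(fu(clamp(x)))
      out <- (fh(clamp(x)) + fl(clamp(x))) / 2
      out[inside] <- fu(clamp(x[inside]))
      out
    },
    high = function(x) fh(clamp(x)), low = function(x) fl(clamp(x)))
}

# all sign-change crossings of profile - ref, linearly interpolated
profile_crossings <- function(xs, d) {
  s <- sign(d)
  idx <- which(s[-length(s)] * s[-1] < 0)
  cross <- xs[idx] - d[idx] * (xs[idx + 1L] - xs[idx]) / (d[idx + 1L] - d[idx])
  exact <- which(d == 0)
  sort(unique(c(cross, xs[exact])))
}

#' Extract a boundary trajectory from a PDE solution
#'
#' The boundary position at each output time is the point where the chosen
#' species' profile crosses the local value of the unstable steady state
#' (linearly interpolated between nodes); in monostable regions the reference
#' falls back to the midpoint of the bistable-region stable branches. With
#' multiple crossings the one nearest the previous position is kept
#' (continuity). `t_form` is the first time a crossing exists inside the
#' bistable interval. The width column is the distance between the 10% and
#' 90% levels of the local high-low span around the boundary.
#'
#' @param sol A `pde_solution`.
#' @param scan A `bifurcation_scan` of the same model (frozen at a reference
#'   time) supplying the unstable/stable branch curves.
#' @param species Species index the boundary is read from (default 1).
#'
#' @return A `boundary_trajectory` tibble `(t, w, width)` with attribute
#'   `t_form`. `w` is `NA` before the front exists.
#' @export
extract_boundary <- function(sol, scan, species = 1L) {
  stopifnot(inherits(sol, "pde_solution"), inherits(scan, "bifurcation_scan"))
  rc <- reference_curves(scan, species)
  xs <- sol$grid$xs
  nt <- length(sol$ts)
  w <- width <- rep(NA_real_, nt)
  t_form <- NA_real_
  prev <- NA_real_
  for (k in seq_len(nt)) {
    prof <- sol$fields[k, , species]
    d <- prof - rc$ref(xs)
    cr <- profile_crossings(xs, d)
    if (length(cr) == 0L) next
    wk <- if (!is.na(prev)) cr[which.min(abs(cr - prev))] else {
      inb <- cr[cr >= scan$x_a & cr <= scan$x_p]
      if (length(inb) > 0L) inb[1] else cr[1]
    }
    if (is.na(t_form) && wk >= scan$x_a && wk <= scan$x_p) t_form <- sol$ts[k]
    w[k] <- prev <- wk
    hi <- rc$high(wk); lo <- rc$low(wk)
    x10 <- profile_crossings(xs, prof - (lo + 0.9 * (hi - lo)))
    x90 <- profile_crossings(xs, prof - (lo + 0.1 * (hi - lo)))
    if (length(x10) > 0L && length(x90) > 0L) {
      width[k] <- abs(x90[which.min(abs(x90 - wk))] - x10[which.min(abs(x10 - wk))])
    }
  }
  out <- tibble(t = sol$ts, w = w, width = width)
  attr(out, "t_form") <- t_form
  attr(out, "species") <- species
  class(out) <- c("boundary_trajectory", class(out))
  out
}
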