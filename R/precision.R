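# Irregularity metric R, tight basin-of-attraction bounds, and the two
# experiment protocols (gradient emergence; decay sweep).

#' Tight basin-of-attraction bounds over an initial-condition ensemble
#'
#' Within the bistable interval `[x_a, x_p]` of `scan`, computes the tight
#' bounds of the possibly-irregular region: `x_tilde_a` is the supremum of
#' positions at which *every* ensemble member is labelled high, `x_tilde_p`
#' the infimum of positions at which *no* member is labelled high. Because
#' basins are nested along a monotone gradient (`B_x2` a subset of `B_x1` for
#' `x1 < x2`), both predicates are monotone in `x` and are located by
#' bisection with the full ensemble. Indeterminate labels widen the bounds
#' conservatively (they count as not-high for `x_tilde_a` and as high for
#' `x_tilde_p`).
#'
#' If every probed position is unanimous, the boundary is precise and the two
#' bounds are collapsed to a common value (`R = 0` exactly).
#'
#' @param m A `bf_model`.
#' @param scan A `bifurcation_scan` with a bistable interval.
#' @param ens An [make_ic_ensemble()] ensemble (or plain matrix of states).
#' @param t Frozen time of the labelling (default the scan's time).
#' @param labeller Optional function `f(x, states) -> labels` replacing the
#'   default frozen-basin labelling (used by the experiment protocols, whose
#'   labels come from full non-autonomous integration).
#' @param tol Position tolerance (defaults to the scan's).
#'
#' @return A list with `x_tilde_a`, `x_tilde_p`, `mixed_seen`,
#'   `n_indeterminate`.
#' @export
tight_bounds <- function(m, scan, ens, t = scan$t, labeller = NULL, tol = NULL) {
  stopifnot(inherits(scan, "bifurcation_scan"))
  if (is.na(scan$x_a) || is.na(scan$x_p)) abort("scan has no bistable interval.")
  states <- ensemble_states(ens)
  tol <- tol %||% scan$tol
  labeller <- labeller %||% function(x, states) basin_label(m, x, t, states)

  mixed_seen <- FALSE
  n_ind <- 0L
  probe <- function(x) {
    lab <- labeller(x, states)
    n_ind <<- n_ind + sum(lab == "indeterminate")
    if (any(lab == "high") && any(lab != "high")) mixed_seen <<- TRUE
    lab
  }
  all_high <- function(lab) all(lab == "high")
  none_high <- function(lab) all(lab == "low")

  la <- probe(scan$x_a)
  lp <- probe(scan$x_p)

  xa_t <- if (!all_high(la)) {
    scan$x_a
  } else if (all_high(lp)) {
    scan$x_p
  } else {
    bisect_pred(function(x) all_high(probe(x)), scan$x_a, scan$x_p, tol)
  }
  xp_t <- if (none_high(la)) {
    scan$x_a
  } else if (!none_high(lp)) {
    scan$x_p
  } else {
    bisect_pred(function(x) !none_high(probe(x)), scan$x_a, scan$x_p, tol)
  }
  if (!mixed_seen && n_ind == 0L) xa_t <- xp_t <- (xa_t + xp_t) / 2
  list(x_tilde_a = xa_t, x_tilde_p = xp_t,
       mixed_seen = mixed_seen, n_indeterminate = n_ind)
}

# largest x in [lo, hi] with pred(x) TRUE, assuming pred monotone decreasing;
# pred(lo) TRUE and pred(hi) FALSE on entry
bisect_pred <- function(pred, lo, hi, tol) {
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pred(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Irregularity ratio R
#'
#' `R = (x_tilde_p - x_tilde_a) / (x_p - x_a)`: the fraction of the final
#' bistable region over which cell fate is not guaranteed by the
#' initial-condition ensemble. `R = 0` means a precise boundary (or, reading
#' the ensemble as embryo-to-embryo variation, perfectly reproducible
#' placement); `R = 1` means the whole bistable region may be irregular.
#'
#' @param bounds Result of [tight_bounds()] (or any list with `x_tilde_a`,
#'   `x_tilde_p`).
#' @param scan The `bifurcation_scan` supplying `x_a`, `x_p`.
#'
#' @return A number in `[0, 1]`.
#' @export
irregularity_R <- function(bounds, scan) {
  if (is.na(scan$x_a) || is.na(scan$x_p) || scan$x_p <= scan$x_a) {
    abort("degenerate bistable interval: R undefined.")
  }
  R <- (bounds$x_tilde_p - bounds$x_tilde_a) / (scan$x_p - scan$x_a)
  min(max(R, 0), 1)
}

#' Irregularity ratio at an earlier time
#'
#' Rescales `R` (defined against the bistable width at readout time `t_f`) to
#' the relative width of the irregular region at another time `t`:
#' `R_t = [(x_p(t_f) - x_a(t_f)) / (x_p(t) - x_a(t))] * R`.
#'
#' @param R Irregularity ratio at readout time.
#' @param scan_t `bifurcation_scan` at time `t`.
#' @param scan_tf `bifurcation_scan` at readout time `t_f`.
#'
#' @return The rescaled ratio `R_t`.
#' @export
irregularity_at_time <- function(R, scan_t, scan_tf) {
  w_t <- scan_t$x_p - scan_t$x_a
  w_f <- scan_tf$x_p - scan_tf$x_a
  if (!is.finite(w_t) || w_t <= 0) abort("zero-width bistable interval at t.")
  if (!is.finite(w_f)) abort("no bistable interval at t_f.")
  (w_f / w_t) * R
}

# labels for an ensemble at one position after non-autonomous integration of
# the time-varying system from t = 0 to t_settle, followed by frozen-profile
# relaxation and attractor matching
nonautonomous_labeller <- function(m, m_ref, t_settle, fps_at = NULL) {
  force(m); force(m_ref); force(t_settle)
  ns <- m$n_species
  function(x, states) {
    n <- nrow(states)
    if (t_settle > 0) {
      derivs <- function(t, y, parms) {
        list(as.vector(m$rhs_vec(t, rep(x, n), matrix(y, ncol = ns))))
      }
      sol <- deSolve::ode(y = as.vector(states), times = c(0, t_settle),
                          func = derivs, parms = NULL, method = "lsoda",
                          rtol = 1e-8, atol = 1e-10 * max(m$umax))
      states <- matrix(sol[nrow(sol), -1], ncol = ns)
    }
    fps <- if (!is.null(fps_at)) fps_at(x) else find_fixed_points(m_ref, x, 0)
    label_states(m_ref, x, fps, pmax(states, 0), cap_factor = 100)
  }
}

# dense-grid tight bounds from per-position ensemble labels, with bisection
# refinement between the grid cells that bracket each bound
dense_bounds <- function(scan, labels_by_x, bi_idx, labeller, states, tol) {
  stopifnot(length(bi_idx) > 0L)
  xs <- scan$xs
  A <- vapply(labels_by_x[bi_idx], function(l) all(l == "high"), logical(1))
  N <- vapply(labels_by_x[bi_idx], function(l) all(l == "low"), logical(1))
  mixed <- any(!A & !N)
  n_ind <- as.integer(sum(vapply(labels_by_x[bi_idx],
                                 function(l) sum(l == "indeterminate"),
                                 numeric(1))))

  refine <- function(pred_true_at_lo, lo, hi) {
    bisect_pred(function(x) pred_true_at_lo(labeller(x, states)), lo, hi, tol)
  }
  xg <- xs[bi_idx]
  xa_t <- if (!A[1]) {
    scan$x_a
  } else if (A[length(A)]) {
    scan$x_p
  } else {
    i <- max(which(A))
    refine(function(l) all(l == "high"), xg[i], xg[i + 1L])
  }
  xp_t <- if (N[1]) {
    scan$x_a
  } else if (!N[length(N)]) {
    scan$x_p
  } else {
    i <- min(which(N))
    refine(function(l) any(l == "high") || any(l == "indeterminate"),
           xg[i - 1L], xg[i])
  }
  if (!mixed && n_ind == 0L) xa_t <- xp_t <- (xa_t + xp_t) / 2
  list(x_tilde_a = xa_t, x_tilde_p = xp_t,
       mixed_seen = mixed, n_indeterminate = n_ind)
}

#' Boundary precision under an emerging gradient
#'
#' For each target `kappa`, sets the gradient emergence rate `gamma = kappa *
#' sigma` (with `sigma` the slowest network convergence rate at the final
#' profile), integrates every ensemble member at every grid position under
#' the time-varying dynamics until the gradient has settled, relaxes at the
#' final profile, and computes the irregularity ratio `R` against the final-
#' profile bifurcation scan. `kappa = Inf` is the static-gradient control.
#'
#' @param m A `"toggle1"` `bf_model` whose gradient is `emerging`.
#' @param ens Initial-condition ensemble ([make_ic_ensemble()]).
#' @param kappa_targets Numeric vector of `kappa` values (may include `Inf`).
#' @param xs Grid of positions (default 100 over `[0, L]`).
#' @param keep_fields Keep the final concentration fields (list-column of
#'   `n_ic x n_x` species-1 matrices)?
#' @param settle_tol Relative amplitude shortfall at which the emerging
#'   gradient is considered settled (default `1e-8`).
#'
#' @return A tibble with one row per `kappa`: `kappa`, `gamma`, `sigma`,
#'   `x_a`, `x_p`, `x_tilde_a`, `x_tilde_p`, `R`, `n_indeterminate`, and
#'   optionally `fields`.
#' @export
emergence_experiment <- function(m, ens, kappa_targets,
                                 xs = NULL, keep_fields = FALSE,
                                 settle_tol = 1e-8) {
  stopifnot(inherits(m, "bf_model"))
  if (m$gradients[[1]]$kind != "emerging") {
    abort("`m` must carry an emerging gradient.")
  }
  xs <- xs %||% seq(0, m$L, length.out = 100L)
  states <- ensemble_states(ens)
  n <- nrow(states)

  sk <- sigma_and_kappa(m, gamma = 1, xs = xs)  # gamma placeholder; sigma only
  sigma <- sk$sigma
  scan_inf <- sk$scan
  bi_idx <- which(scan_inf$classes == "bistable")
  m_inf <- scan_inf$model
  fps_at_grid <- function(x) {
    i <- match(TRUE, abs(scan_inf$xs - x) < 1e-12)
    if (!is.na(i)) scan_inf$portraits[[i]] else find_fixed_points(m_inf, x, 0)
  }

  rows <- lapply(kappa_targets, function(kap) {
    if (is.infinite(kap)) {
      mk <- m_inf
      t_settle <- 0
      gam <- Inf
    } else {
      gam <- kap * sigma
      g <- m$gradients[[1]]
      mk <- build_model("toggle1", m$params,
                        gradient_emerging(g$b, g$lam, gam), m$L)
      t_settle <- -log(settle_tol) / gam
    }
    lab_fun <- nonautonomous_labeller(mk, m_inf, t_settle, fps_at = NULL)
    lab_grid <- nonautonomous_labeller(mk, m_inf, t_settle, fps_at = fps_at_grid)

    labels_by_x <- lapply(scan_inf$xs, function(x) lab_grid(x, states))
    b <- dense_bounds(scan_inf, labels_by_x, bi_idx, lab_fun, states, scan_inf$tol)
    R <- irregularity_R(b, scan_inf)
    out <- tibble(kappa = kap, gamma = gam, sigma = sigma,
                  x_a = scan_inf$x_a, x_p = scan_inf$x_p,
                  x_tilde_a = b$x_tilde_a, x_tilde_p = b$x_tilde_p, R = R,
                  n_indeterminate = b$n_indeterminate)
    if (keep_fields) {
      flds <- final_fields(mk, m_inf, scan_inf$xs, states, t_settle)
      out$fields <- list(flds)
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  attr(res, "scan_inf") <- scan_inf
  class(res) <- c("emergence_result", class(res))
  res
}

# final species-1 field: integrate the ensemble at every position through
# emergence plus a relaxation tail at the settled profile
final_fields <- function(mk, m_inf, xs, states, t_settle) {
  ns <- mk$n_species
  n <- nrow(states)
  sapply(xs, function(x) {
    derivs <- function(t, y, parms) {
      list(as.vector(mk$rhs_vec(t, rep(x, n), matrix(y, ncol = ns))))
    }
    t1 <- max(t_settle, 1e-6)
    sol <- deSolve::ode(y = as.vector(states), times = c(0, t1),
                        func = derivs, parms = NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10 * max(mk$umax))
    y1 <- matrix(sol[nrow(sol), -1], ncol = ns)
    derivs2 <- function(t, y, parms) {
      list(as.vector(m_inf$rhs_vec(t, rep(x, n), matrix(y, ncol = ns))))
    }
    sol2 <- deSolve::ode(y = as.vector(pmax(y1, 0)), times = c(0, 50),
                         func = derivs2, parms = NULL, method = "lsoda",
                         rtol = 1e-8, atol = 1e-10 * max(mk$umax))
    matrix(sol2[nrow(sol2), -1], ncol = ns)[, 1]
  })
}

#' Boundary precision under a decaying gradient (sweep protocol)
#'
#' Lets an established exponential gradient decay from `t = 0` to the readout
#' time `t_f`, then freezes the morphogen profile, relaxes the network in
#' every cell to steady state, and computes the irregularity ratio `R`
#' against the frozen-profile bifurcation scan. Cells initially monostable
#' for the high state stay high as their surroundings turn bistable, while
#' the initially bistable (possibly irregular) region is swept into the
#' monostable-low regime — the mechanism by which slow gradient decay
#' enhances precision.
#'
#' @param m A `"toggle1"` `bf_model` whose gradient is `decaying`.
#' @param ens Ensemble of initial states at `t = 0`, or the string
#'   `"steady_state"` to start every cell at the attractor reached from the
#'   origin under the frozen `t = 0` profile.
#' @param t_f Readout time (see [readout_time_for_shift()]).
#' @param xs Grid of positions (default 100 over `[0, L]`).
#' @param scan_tf Optional precomputed `bifurcation_scan` of the profile
#'   frozen at `t_f` (reused across seeded ensembles).
#'
#' @return A one-row tibble: `t_f`, `x_a`, `x_p`, `x_tilde_a`, `x_tilde_p`,
#'   `R`, `swept` (TRUE if the domain is entirely monostable at `t_f`, in
#'   which case `R = 0` by convention), `n_indeterminate`. The frozen-profile
#'   scan is attached as attribute `"scan_tf"`; per-position labels as
#'   `"labels"`.
#' @export
sweep_experiment <- function(m, ens, t_f, xs = NULL, scan_tf = NULL) {
  stopifnot(inherits(m, "bf_model"))
  if (m$gradients[[1]]$kind != "decaying") {
    abort("`m` must carry a decaying gradient.")
  }
  xs <- xs %||% seq(0, m$L, length.out = 100L)
  m_tf <- freeze_model(m, t_f)
  scan_tf <- scan_tf %||% scan_axis(m_tf, t = 0, xs = xs)

  per_x_ic <- identical(ens, "steady_state")
  states <- if (per_x_ic) NULL else ensemble_states(ens)

  if (is.na(scan_tf$x_a)) {
    res <- tibble(t_f = t_f, x_a = NA_real_, x_p = NA_real_,
                  x_tilde_a = NA_real_, x_tilde_p = NA_real_,
                  R = 0, swept = TRUE, n_indeterminate = 0L)
    attr(res, "scan_tf") <- scan_tf
    class(res) <- c("sweep_result", class(res))
    return(res)
  }

  bi_idx <- which(scan_tf$classes == "bistable")
  fps_at_grid <- function(x) {
    i <- match(TRUE, abs(scan_tf$xs - x) < 1e-12)
    if (!is.na(i)) scan_tf$portraits[[i]] else find_fixed_points(m_tf, x, 0)
  }
  lab_grid <- nonautonomous_labeller(m, m_tf, t_f, fps_at = fps_at_grid)
  lab_free <- nonautonomous_labeller(m, m_tf, t_f, fps_at = NULL)

  get_states <- function(x) {
    if (!per_x_ic) return(states)
    matrix(steady_from_origin(m, x), nrow = 1L)
  }
  labels_by_x <- lapply(scan_tf$xs, function(x) lab_grid(x, get_states(x)))
  lab_fun <- function(x, ignored) lab_free(x, get_states(x))
  b <- dense_bounds(scan_tf, labels_by_x, bi_idx, lab_fun, states, scan_tf$tol)
  R <- irregularity_R(b, scan_tf)

  res <- tibble(t_f = t_f, x_a = scan_tf$x_a, x_p = scan_tf$x_p,
                x_tilde_a = b$x_tilde_a, x_tilde_p = b$x_tilde_p, R = R,
                swept = FALSE, n_indeterminate = b$n_indeterminate)
  attr(res, "scan_tf") <- scan_tf
  attr(res, "labels") <- labels_by_x
  class(res) <- c("sweep_result", class(res))
  res
}

# attractor reached from the origin under the frozen t = 0 profile
steady_from_origin <- function(m, x) {
  m0 <- freeze_model(m, 0)
  fps <- find_fixed_points(m0, x, 0)
  st <- stable_points(fps)
  lab <- label_states(m0, x, fps, matrix(0, 1L, m$n_species))
  hl <- high_low_states(fps)
  if (lab == "high") hl$high$state else hl$low$state
}

#' Readout time for a prescribed boundary shift
#'
#' For the decaying gradient \eqn{b e^{-x/\lambda - \gamma t}}, every level
#' set (in particular the bifurcation points) moves anteriorly at speed
#' \eqn{\lambda \gamma}, so a shift by `delta` takes `t_f = delta / (lambda *
#' gamma)`. A numeric root-find on the level-set trajectory is available for
#' checking or for non-exponential profiles.
#'
#' @param g A decaying `gradient_spec` with `gamma > 0`.
#' @param delta Target anterior shift (length).
#' @param method `"analytic"` (default) or `"numeric"`.
#' @param x0 Reference position for the numeric level-set trace.
#'
#' @return The readout time `t_f`.
#' @examples
#' readout_time_for_shift(gradient_decaying(1, 0.2, 0.1), delta = 0.02)  # 1
#' @export
readout_time_for_shift <- function(g, delta, method = c("analytic", "numeric"),
                                   x0 = g$lam) {
  method <- match.arg(method)
  stopifnot(inherits(g, "gradient_spec"))
  if (g$kind != "decaying") abort("`g` must be a decaying gradient.")
  if (is.null(g$gamma) || g$gamma <= 0) abort("no finite t_f for gamma = 0.")
  if (method == "analytic") return(delta / (g$lam * g$gamma))
  target <- eval_gradient(g, 0, x0)
  f <- function(t) eval_gradient(g, t, x0 - delta) - target
  upper <- 10 * delta / (g$lam * g$gamma) + 1
  uniroot(f, c(0, upper), tol = 1e-12)$root
}
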