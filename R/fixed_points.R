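#' Instantaneous fixed points of the local dynamics
#'
#' Finds the steady states of the frozen (time- and space-local) reaction
#' system at position `x` and time `t` by a multi-start damped Newton search
#' seeded on a log-spaced grid spanning the attainable concentration box,
#' merges duplicates, and classifies stability from the Jacobian eigenvalues.
#'
#' @param m A `bf_model`.
#' @param x Position along the axis.
#' @param t Frozen time.
#' @param tol Residual tolerance for accepting a root (relative to the
#'   production scale).
#' @param n_seed Seeds per species dimension (default 16 for one species,
#'   8 for two); raise to check classification stability.
#'
#' @return A list of fixed points, each a list with `state` (concentration
#'   vector), `stability` (`"stable"`, `"unstable"` or `"saddle"`) and
#'   `leading_rate` (largest real part of the Jacobian eigenvalues, 1/time).
#'   Empty (with a warning) if no root is found from any seed.
#' @examples
#' m <- build_model("scalar", scalar_params(0, 0.3))
#' length(find_fixed_points(m, x = 0, t = 0))  # 3: the cubic's roots
#' @export
find_fixed_points <- function(m, x, t, tol = 1e-9, n_seed = NULL) {
  stopifnot(inherits(m, "bf_model"))
  ns <- m$n_species
  scale <- pmax(m$umax, 1e-8)
  lr <- if (!is.null(m$local_reaction)) m$local_reaction(t, x) else {
    list(f = function(u) m$rhs(t, x, u), J = function(u) m$jac(t, x, u))
  }
  f <- lr$f
  J <- lr$J

  roots <- list()
  if (ns == 1L) {
    # one species: decompose [0, umax] into monotone segments (critical
    # points of f located from sign changes of f') and bracket one root per
    # segment. Robust for root pairs far closer than the sweep resolution.
    n_sweep <- max(n_seed %||% 16L, 16L) * 16L
    ug <- seq(0, m$umax * (1 + 1e-9), length.out = n_sweep)
    dg <- vapply(ug, function(u) J(u)[1, 1], numeric(1))
    crit <- ug[which(dg == 0)]
    for (i in which(dg[-n_sweep] * dg[-1] < 0)) {
      crit <- c(crit, uniroot(function(u) J(u)[1, 1], c(ug[i], ug[i + 1L]),
                              tol = 1e-13 * max(scale, 1))$root)
    }
    brk <- sort(unique(c(ug[1], crit, ug[n_sweep])))
    fb <- vapply(brk, function(u) f(u), numeric(1))
    for (i in which(abs(fb) <= tol * max(scale, 1e-8) * 1e-3)) {
      roots[[length(roots) + 1L]] <- brk[i]
    }
    for (i in seq_len(length(brk) - 1L)) {
      if (fb[i] * fb[i + 1L] < 0) {
        roots[[length(roots) + 1L]] <-
          uniroot(function(u) f(u), c(brk[i], brk[i + 1L]),
                  tol = 1e-13 * max(scale, 1))$root
      }
    }
    # dedupe (a near-zero breakpoint can also head a bracketed segment)
    if (length(roots) > 1L) {
      rv <- sort(unlist(roots))
      rv <- rv[c(TRUE, diff(rv) > 1e-7 * max(scale, 1))]
      roots <- as.list(rv)
    }
  } else {
    # log-spaced Newton seeds spanning [0, umax] per species (8x8 default)
    n_seed <- n_seed %||% 8L
    ax <- lapply(seq_len(ns), function(s) {
      c(0, scale[s] * exp(seq(log(1e-3), log(1.05), length.out = n_seed - 1L)))
    })
    seeds <- as.matrix(do.call(expand.grid, ax))
    for (i in seq_len(nrow(seeds))) {
      r <- newton_root(f, J, seeds[i, ], scale, tol = tol)
      if (is.null(r)) next
      # the attainable state space is [0, umax] (production is bounded);
      # roots beyond it are not admissible states
      if (any(r > m$umax * (1 + 1e-8) + 1e-12)) next
      dup <- any(vapply(roots, function(q) {
        max(abs(q - r) / pmax(scale, 1)) < 1e-6
      }, logical(1)))
      if (!dup) roots[[length(roots) + 1L]] <- r
    }
  }
  if (length(roots) == 0L) {
    warn("no fixed point found from any seed (degenerate parameters?)")
    return(list())
  }
  roots <- roots[order(vapply(roots, `[`, numeric(1), 1L))]
  lapply(roots, function(u) {
    ev <- eigen(J(u), only.values = TRUE)$values
    lead <- max(Re(ev))
    if (abs(lead) < 1e-8) {
      warn("marginal fixed point (|leading rate| < 1e-8); classified unstable")
      stab <- "unstable"
    } else if (lead < 0) {
      stab <- "stable"
    } else if (length(ev) > 1L && all(Im(ev) == 0) && min(Re(ev)) < 0) {
      stab <- "saddle"
    } else {
      stab <- "unstable"
    }
    list(state = unname(u), stability = stab, leading_rate = lead)
  })
}

# damped Newton iteration, nonnegativity-projected; NULL on failure.
# A root is accepted only if the residual is small AND the Newton correction
# is negligible: a small residual alone admits pseudo-roots wherever the
# reaction term is nearly flat (e.g. close to a saddle-node collision).
newton_root <- function(f, J, u0, scale, tol = 1e-9, max_iter = 60L) {
  u <- pmax(u0, 0)
  fscale <- pmax(scale, 1e-8)
  accept <- function(u, fu) {
    if (max(abs(fu) / fscale) >= tol) return(FALSE)
    corr <- tryCatch(solve(J(u), -fu), error = function(e) NULL)
    !is.null(corr) && all(is.finite(corr)) &&
      max(abs(corr) / fscale) < 1e-6
  }
  for (k in seq_len(max_iter)) {
    fu <- f(u)
    if (any(!is.finite(fu))) return(NULL)
    if (accept(u, fu)) return(u)
    Ju <- J(u)
    step <- tryCatch(solve(Ju, -fu), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # damp: halve until the residual decreases (or give up)
    lam <- 1
    repeat {
      u_new <- pmax(u + lam * step, 0)
      f_new <- f(u_new)
      if (all(is.finite(f_new)) &&
          max(abs(f_new) / fscale) <= max(abs(fu) / fscale) * (1 - 1e-4 * lam) + 1e-300) {
        break
      }
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    if (max(abs(u_new - u) / pmax(fscale, 1)) < 1e-14 &&
        max(abs(f_new) / fscale) >= tol) {
      return(NULL)
    }
    u <- u_new
  }
  fu <- f(u)
  if (accept(u, fu)) u else NULL
}

#' Classify an instantaneous phase portrait
#'
#' Maps a fixed-point list to one of three regimes: a single stable point is
#' `mono_high` or `mono_low` depending on whether its species-1 concentration
#' lies above or below the midpoint of the family's attainable range; two
#' stable points give `bistable`.
#'
#' @param fps Fixed points from [find_fixed_points()].
#' @param m The `bf_model` they came from (supplies the high/low midpoint).
#'
#' @return `"mono_high"`, `"mono_low"` or `"bistable"`.
#' @export
classify_portrait <- function(fps, m) {
  stopifnot(inherits(m, "bf_model"))
  stable <- Filter(function(p) p$stability == "stable", fps)
  if (length(stable) > 2L) {
    abort(sprintf("unsupported topology: %d stable fixed points.", length(stable)))
  }
  if (length(stable) == 2L) return("bistable")
  if (length(stable) == 0L) {
    warn("no stable fixed point; classifying by sign of drift is unsupported")
    return(NA_character_)
  }
  mid <- m$umax[1] / 2
  if (stable[[1]]$state[1] > mid) "mono_high" else "mono_low"
}

#' Local phase portrait at a point
#'
#' Convenience wrapper bundling [find_fixed_points()] and
#' [classify_portrait()].
#'
#' @inheritParams find_fixed_points
#' @return A list with `x`, `t`, `fixed_points`, `classification`.
#' @export
local_portrait <- function(m, x, t = 0) {
  fps <- find_fixed_points(m, x, t)
  structure(
    list(x = x, t = t, fixed_points = fps,
         classification = classify_portrait(fps, m)),
    class = "local_portrait")
}

#' @export
print.local_portrait <- function(x, ...) {
  cat(sprintf("<local_portrait> x = %g, t = %g: %s\n",
              x$x, x$t, x$classification))
  for (fp in x$fixed_points) {
    cat(sprintf("  (%s)  %s, leading rate %.4g\n",
                paste(signif(fp$state, 4), collapse = ", "),
                fp$stability, fp$leading_rate))
  }
  invisible(x)
}

# helpers shared by scan/basin code ------------------------------------------

stable_points <- function(fps) Filter(function(p) p$stability == "stable", fps)

unstable_points <- function(fps) {
  Filter(function(p) p$stability != "stable", fps)
}

# the high/low stable states by species-1 value (high = larger u1)
high_low_states <- function(fps) {
  st <- stable_points(fps)
  if (length(st) == 0L) return(list(high = NULL, low = NULL))
  v1 <- vapply(st, function(p) p$state[1], numeric(1))
  list(high = st[[which.max(v1)]], low = st[[which.min(v1)]])
}
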