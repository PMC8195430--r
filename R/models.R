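#' Reaction-system parameter sets
#'
#' Constructors for the parameter bundles of the model families:
#'
#' * `toggle_params()` — a two-gene mutually repressive switch in which
#'   species 1 is activated by a morphogen through an activating Hill
#'   function. `a1`, `a2` are maximal production rates, `beta` the shared
#'   first-order decay rate, `act`/`rep` the activation and repression Hill
#'   parameters, `D1`/`D2` diffusivities (0 for purely local dynamics).
#' * `hb_params()` — the Hunchback-Bicoid regulatory function: Hb production
#'   is a saturating function of Bcd (`alpha_b`, `b0`, `nb`) and of Hb itself
#'   (`alpha_h`, `h0`, `nh`), with decay `beta` and diffusivity `D`.
#' * `scalar_params()` — a one-species cubic bistable reaction
#'   \eqn{u(1-u)(u-\alpha(x))} with diffusivity `D`; `alpha_field` is a
#'   function of position giving the threshold \eqn{\alpha \in (0,1)} (the
#'   middle root, which is also the bifurcation parameter).
#'
#' @param a1,a2 Maximal production rates (concentration/time), `>= 0`.
#' @param beta Decay rate (1/time), `> 0`.
#' @param act,rep [hill_params()] for activation and repression.
#' @param D1,D2,D Diffusivities (length^2/time), `>= 0`.
#' @param alpha_b,alpha_h Maximal Bcd- and Hb-driven production rates.
#' @param b0,h0 Half-maximal concentrations of Bcd and Hb.
#' @param nb,nh Hill coefficients of Bcd and Hb activation.
#' @param alpha_field Function of `x` returning the local threshold, or a
#'   single number for a homogeneous threshold.
#'
#' @return A parameter object of class `toggle_params`, `hb_params` or
#'   `scalar_params`.
#' @name model_params
NULL

#' @rdname model_params
#' @export
toggle_params <- function(a1, a2, beta, act, rep, D1 = 0, D2 = 0) {
  stopifnot(inherits(act, "hill_params"), inherits(rep, "hill_params"))
  vals <- c(a1 = a1, a2 = a2, beta = beta, D1 = D1, D2 = D2)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("toggle rates and diffusivities must be finite and >= 0.")
  }
  if (beta <= 0) abort("`beta` must be > 0.")
  structure(list(a1 = a1, a2 = a2, beta = beta, act = act, rep = rep,
                 D1 = D1, D2 = D2),
            class = "toggle_params")
}

#' @rdname model_params
#' @export
hb_params <- function(alpha_b, alpha_h, b0, h0, nb, nh, beta, D) {
  vals <- c(alpha_b, alpha_h, b0, h0, nb, nh, beta)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all Hb parameters must be positive and finite.")
  }
  if (!is.finite(D) || D < 0) abort("`D` must be >= 0.")
  structure(list(alpha_b = alpha_b, alpha_h = alpha_h, b0 = b0, h0 = h0,
                 nb = nb, nh = nh, beta = beta, D = D),
            class = "hb_params")
}

#' @rdname model_params
#' @export
scalar_params <- function(D, alpha_field) {
  if (!is.finite(D) || D < 0) abort("`D` must be >= 0.")
  if (is.numeric(alpha_field) && length(alpha_field) == 1L) {
    a0 <- alpha_field
    alpha_field <- function(x) rep(a0, length(x))
  }
  stopifnot(is.function(alpha_field))
  structure(list(D = D, alpha_field = alpha_field), class = "scalar_params")
}

# spatially uniform gradient carrying a frozen morphogen value
const_gradient <- function(value) {
  if (value <= 0) new_gradient("static_zero") else gradient_static(value, Inf)
}

#' Build a reaction-system model
#'
#' Assembles a model family, its parameters and its morphogen gradient(s)
#' into a `bf_model` consumed by every downstream operation (phase-portrait
#' scans, precision experiments, the reaction-diffusion solver, velocity
#' maps).
#'
#' Families:
#' * `"toggle1"` — toggle switch with species 1 activated by a single
#'   morphogen gradient; no diffusion (set diffusivities explicitly to add
#'   it).
#' * `"toggle2"` — toggle switch with both species activated by their own
#'   (typically antiparallel) morphogen gradients; diffusivities from
#'   `D1`/`D2` of its `toggle_params`.
#' * `"hb"` — Hunchback dynamics over a Bcd-style gradient.
#' * `"scalar"` — the one-species cubic bistable reaction with a spatial
#'   threshold field (no gradient argument; the field lives in its params).
#'
#' @param family One of `"toggle1"`, `"toggle2"`, `"hb"`, `"scalar"`.
#' @param params Matching parameter object (see [model_params]).
#' @param gradients A `gradient_spec` or list of them; toggle1 and hb take
#'   one, toggle2 takes two, scalar none.
#' @param L Domain length (anterior `x = 0` to posterior `x = L`).
#'
#' @return A `bf_model` with elements `tag`, `n_species`, `params`,
#'   `gradients`, `L`, `diffusivities`, and reaction-term closures `rhs(t, x,
#'   u)`, `rhs_vec(t, xs, U)` (vectorised over nodes) and `jac(t, x, u)`.
#' @examples
#' m <- build_model("toggle1",
#'   toggle_params(3, 1, 1, hill_params(0.5, 2), hill_params(0.5, 2)),
#'   gradients = gradient_static(b = 1, lam = 0.3), L = 1)
#' m$rhs(0, 0.2, c(0, 0))
#' @export
build_model <- function(family = c("toggle1", "toggle2", "hb", "scalar"),
                        params, gradients = list(), L = 1) {
  family <- match.arg(family)
  if (inherits(gradients, "gradient_spec")) gradients <- list(gradients)
  if (!is.finite(L) || L <= 0) abort("`L` must be a positive length.")
  n_grad <- c(toggle1 = 1L, toggle2 = 2L, hb = 1L, scalar = 0L)[[family]]
  if (length(gradients) != n_grad) {
    abort(sprintf("family '%s' needs %d gradient(s), got %d.",
                  family, n_grad, length(gradients)))
  }
  ok <- switch(family,
    toggle1 = , toggle2 = inherits(params, "toggle_params"),
    hb = inherits(params, "hb_params"),
    scalar = inherits(params, "scalar_params"))
  if (!ok) abort(sprintf("`params` does not match family '%s'.", family))

  m <- switch(family,
    toggle1 = model_toggle(params, gradients, L, two_inputs = FALSE),
    toggle2 = model_toggle(params, gradients, L, two_inputs = TRUE),
    hb = model_hb(params, gradients, L),
    scalar = model_scalar(params, L))
  m$tag <- family
  structure(m, class = "bf_model")
}

model_toggle <- function(p, gradients, L, two_inputs) {
  g1 <- gradients[[1]]
  g2 <- if (two_inputs) gradients[[2]] else NULL
  rhs_vec <- function(t, xs, U) {
    a1eff <- p$a1 * hill_response(eval_gradient(g1, t, xs), p$act)
    a2eff <- if (two_inputs) {
      p$a2 * hill_response(eval_gradient(g2, t, xs), p$act)
    } else rep(p$a2, length(xs))
    cbind(a1eff * hill_response(U[, 2], p$rep, "repress") - p$beta * U[, 1],
          a2eff * hill_response(U[, 1], p$rep, "repress") - p$beta * U[, 2])
  }
  local_reaction <- function(t, x) {
    a1eff <- p$a1 * hill_response(eval_gradient(g1, t, x), p$act)
    a2eff <- if (two_inputs) {
      p$a2 * hill_response(eval_gradient(g2, t, x), p$act)
    } else p$a2
    list(
      f = function(u) {
        c(a1eff * hill_response(u[2], p$rep, "repress") - p$beta * u[1],
          a2eff * hill_response(u[1], p$rep, "repress") - p$beta * u[2])
      },
      J = function(u) {
        matrix(c(-p$beta, a2eff * hill_repress_deriv(u[1], p$rep),
                 a1eff * hill_repress_deriv(u[2], p$rep), -p$beta),
               nrow = 2L)
      })
  }
  list(
    n_species = 2L,
    params = p, gradients = gradients, L = L,
    diffusivities = c(p$D1, p$D2),
    umax = c(p$a1, p$a2) / p$beta,
    rhs = function(t, x, u) drop(rhs_vec(t, x, matrix(u, nrow = 1L))),
    rhs_vec = rhs_vec,
    local_reaction = local_reaction,
    jac = function(t, x, u) {
      a1eff <- p$a1 * hill_response(eval_gradient(g1, t, x), p$act)
      a2eff <- if (two_inputs) {
        p$a2 * hill_response(eval_gradient(g2, t, x), p$act)
      } else p$a2
      matrix(c(-p$beta, a2eff * hill_repress_deriv(u[1], p$rep),
               a1eff * hill_repress_deriv(u[2], p$rep), -p$beta),
             nrow = 2L)
    })
}

# Hb regulatory function: saturating activation by Bcd and by Hb itself
hb_f <- function(b, h, p) {
  B <- (b / p$b0)^p$nb
  S <- (h / p$h0)^p$nh
  (p$alpha_b * B + p$alpha_h * S) / (1 + B + S)
}

model_hb <- function(p, gradients, L) {
  g <- gradients[[1]]
  rhs_vec <- function(t, xs, U) {
    b <- eval_gradient(g, t, xs)
    cbind(hb_f(b, U[, 1], p) - p$beta * U[, 1])
  }
  local_reaction <- function(t, x) {
    b <- eval_gradient(g, t, x)
    B <- (b / p$b0)^p$nb
    list(
      f = function(u) {
        S <- (u[1] / p$h0)^p$nh
        (p$alpha_b * B + p$alpha_h * S) / (1 + B + S) - p$beta * u[1]
      },
      J = function(u) {
        S <- (u[1] / p$h0)^p$nh
        dS <- if (u[1] > 0) (p$nh / p$h0) * (u[1] / p$h0)^(p$nh - 1) else 0
        matrix((p$alpha_h * (1 + B) - p$alpha_b * B) / (1 + B + S)^2 * dS -
                 p$beta, 1L, 1L)
      })
  }
  list(
    n_species = 1L,
    params = p, gradients = gradients, L = L,
    diffusivities = p$D,
    umax = max(p$alpha_b, p$alpha_h) / p$beta,
    rhs = function(t, x, u) drop(rhs_vec(t, x, matrix(u, nrow = 1L))),
    rhs_vec = rhs_vec,
    local_reaction = local_reaction,
    jac = function(t, x, u) {
      b <- eval_gradient(g, t, x)
      B <- (b / p$b0)^p$nb
      S <- (u[1] / p$h0)^p$nh
      dS <- if (u[1] > 0) (p$nh / p$h0) * (u[1] / p$h0)^(p$nh - 1) else 0
      dfdh <- (p$alpha_h * (1 + B) - p$alpha_b * B) / (1 + B + S)^2 * dS
      matrix(dfdh - p$beta, 1L, 1L)
    })
}

model_scalar <- function(p, L) {
  rhs_vec <- function(t, xs, U) {
    a <- p$alpha_field(xs)
    u <- U[, 1]
    cbind(u * (1 - u) * (u - a))
  }
  local_reaction <- function(t, x) {
    a <- p$alpha_field(x)
    list(
      f = function(u) u[1] * (1 - u[1]) * (u[1] - a),
      J = function(u) matrix(-3 * u[1]^2 + 2 * (1 + a) * u[1] - a, 1L, 1L))
  }
  list(
    n_species = 1L,
    params = p, gradients = list(), L = L,
    diffusivities = p$D,
    umax = 1,
    rhs = function(t, x, u) drop(rhs_vec(t, x, matrix(u, nrow = 1L))),
    rhs_vec = rhs_vec,
    local_reaction = local_reaction,
    jac = function(t, x, u) {
      a <- p$alpha_field(x)
      matrix(-3 * u[1]^2 + 2 * (1 + a) * u[1] - a, 1L, 1L)
    })
}

#' Freeze a model's gradients at a time point
#'
#' Produces the autonomous system of the instantaneous phase portrait: the
#' morphogen profile at time `t` is made static so the frozen system can be
#' integrated in its own internal time.
#'
#' @param m A `bf_model`.
#' @param t Freeze time.
#' @return A `bf_model` with static gradients.
#' @export
freeze_model <- function(m, t) {
  stopifnot(inherits(m, "bf_model"))
  if (m$tag == "scalar" || length(m$gradients) == 0L) return(m)
  gl <- lapply(m$gradients, gradient_freeze, t = t)
  m2 <- build_model(m$tag, m$params, gl, m$L)
  m2$diffusivities <- m$diffusivities
  m2
}

#' Spatially homogeneous companion model at a point
#'
#' Freezes every bifurcation parameter at its value at time `t` and position
#' `x`, giving the homogeneous system whose travelling-front solutions define
#' the local front velocity at `x`.
#'
#' @param m A `bf_model`.
#' @param x Position whose parameter values are adopted everywhere.
#' @param t Freeze time.
#' @param L_aux Domain length of the companion system (defaults to `m$L`).
#' @return A `bf_model` with spatially uniform parameters.
#' @export
companion_model <- function(m, x, t, L_aux = m$L) {
  stopifnot(inherits(m, "bf_model"))
  if (m$tag == "scalar") {
    a0 <- m$params$alpha_field(x)
    m2 <- build_model("scalar", scalar_params(m$params$D, a0), L = L_aux)
  } else {
    gl <- lapply(m$gradients, function(g) const_gradient(eval_gradient(g, t, x)))
    m2 <- build_model(m$tag, m$params, gl, L_aux)
    m2$diffusivities <- m$diffusivities
  }
  m2
}

#' Override a model's diffusivities
#'
#' @param m A `bf_model`.
#' @param D Numeric vector of per-species diffusivities, `>= 0`.
#' @return The modified `bf_model`.
#' @export
set_diffusivities <- function(m, D) {
  stopifnot(inherits(m, "bf_model"), length(D) == m$n_species)
  if (any(!is.finite(D)) || any(D < 0)) abort("diffusivities must be >= 0.")
  m$diffusivities <- D
  m
}

#' @export
print.bf_model <- function(x, ...) {
  cat(sprintf("<bf_model: %s> %d species, L = %g, D = (%s)\n",
              x$tag, x$n_species, x$L,
              paste(signif(x$diffusivities, 3), collapse = ", ")))
  for (g in x$gradients) print(g)
  invisible(x)
}
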