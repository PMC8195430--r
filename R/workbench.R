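# Fixture generation (initial-condition ensembles, preset scenarios),
# configuration files, and table I/O.

#' Random initial-condition ensemble
#'
#' Draws `n` states uniformly within a per-species box. The same seed always
#' reproduces the same ensemble; the caller's RNG state is left untouched.
#'
#' @param n Number of states (`>= 1`).
#' @param box Per-species `(low, high)` bounds: a `2 x n_species` matrix, or
#'   a list of length-2 vectors. Bounds must be nonnegative.
#' @param seed Integer seed.
#' @param interpretation `"cells_within_embryo"` (precision reading) or
#'   `"embryos"` (reproducibility reading). The computation of tight bounds
#'   and `R` is identical for both; only the reporting label differs.
#'
#' @return An `ic_ensemble`: an `n x n_species` matrix with attributes
#'   `seed` and `interpretation`.
#' @examples
#' make_ic_ensemble(5, list(c(0, 0.2), c(0, 0.2)), seed = 1)
#' @export
make_ic_ensemble <- function(n, box, seed = NULL,
                             interpretation = c("cells_within_embryo",
                                                "embryos")) {
  interpretation <- match.arg(interpretation)
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1.")
  if (is.list(box)) box <- vapply(box, function(b) as.numeric(b[1:2]),
                                  numeric(2))
  box <- as.matrix(box)
  if (any(box < 0)) abort("box bounds must be nonnegative.")
  if (any(box[2, ] < box[1, ])) abort("box upper bounds below lower bounds.")
  draw <- function() {
    apply(box, 2, function(b) runif(n, b[1], b[2]))
  }
  states <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  states <- matrix(states, nrow = n)
  structure(states, class = c("ic_ensemble", "matrix", "array"),
            seed = seed, interpretation = interpretation, box = box)
}

# accept an ic_ensemble or a plain matrix of states
ensemble_states <- function(ens) {
  if (inherits(ens, "ic_ensemble")) return(unclass(ens)[, , drop = FALSE])
  if (is.matrix(ens)) return(ens)
  abort("expected an `ic_ensemble` or a matrix of states.")
}

#' @export
print.ic_ensemble <- function(x, ...) {
  cat(sprintf("<ic_ensemble> %d states x %d species (%s), seed = %s\n",
              nrow(x), ncol(x), attr(x, "interpretation"),
              format(attr(x, "seed"))))
  invisible(x)
}

# flat config files ----------------------------------------------------------

#' Read and write flat configuration files
#'
#' A minimal flat, sectioned `key = value` format (TOML-like): `[section]`
#' headers, numbers, booleans, quoted strings and comma-separated numeric
#' vectors; `#` comments. Round-trips the parameter sets and gradient specs
#' of every model family.
#'
#' @param path File path.
#' @param cfg Named list of named lists (sections of keys).
#' @return `read_config()` returns a named list of sections;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) abort(sprintf("key outside any section: '%s'", ln))
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      cfg[[section]][[key]] <- parse_config_value(val, section, key)
    } else {
      abort(sprintf("malformed config line: '%s'", ln))
    }
  }
  cfg
}

parse_config_value <- function(val, section, key) {
  if (!nzchar(val)) return(NULL)  # blank value: key treated as missing
  if (grepl('^".*"$', val)) return(gsub('^"|"$', "", val))
  if (val %in% c("true", "false")) return(val == "true")
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  num <- suppressWarnings(as.numeric(parts))
  if (any(is.na(num) & !(parts %in% c("inf", "Inf")))) {
    abort(sprintf("config key '%s.%s' has a malformed value: '%s'",
                  section, key, val))
  }
  num[parts %in% c("inf", "Inf")] <- Inf
  num
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(is.list(cfg))
  out <- character(0)
  for (sec in names(cfg)) {
    out <- c(out, sprintf("[%s]", sec))
    for (key in names(cfg[[sec]])) {
      v <- cfg[[sec]][[key]]
      val <- if (is.character(v)) sprintf('"%s"', v)
        else if (is.logical(v)) tolower(as.character(v))
        else paste(format(v, digits = 17, trim = TRUE), collapse = ", ")
      out <- c(out, sprintf("%s = %s", key, val))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

# model <-> config sections ---------------------------------------------------

gradient_to_section <- function(g) {
  sec <- g[setdiff(names(g), "table")]
  if (g$kind == "tabulated") {
    sec$x <- g$table$x
    sec$value <- g$table$value
  }
  sec
}

section_to_gradient <- function(sec) {
  switch(sec$kind,
    static_exp = gradient_static(sec$b, sec$lam),
    emerging   = gradient_emerging(sec$b, sec$lam, sec$gamma),
    decaying   = gradient_decaying(sec$b, sec$lam, sec$gamma),
    bcd        = gradient_bcd(sec$bm, sec$lam, sec$omega0, sec$t0 %||% 0),
    tabulated  = gradient_tabulated(data.frame(x = sec$x, value = sec$value)),
    abort(sprintf("unknown gradient kind '%s' in config.", sec$kind)))
}

#' Serialize a model to (and from) a flat config file
#'
#' One section per component: the model family and domain under `[model]`,
#' parameters under `[params]` (Hill parameters as `K_a`, `n_a`, `K_r`,
#' `n_r`), and gradients under `[gradient1]` (and `[gradient2]`). The scalar
#' family's threshold field is serialized as a table of sampled values.
#'
#' @param m A `bf_model`.
#' @param path File path.
#' @param n_samples Sampling resolution for the scalar threshold field.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a `bf_model`.
#' @export
write_model_config <- function(m, path, n_samples = 101L) {
  stopifnot(inherits(m, "bf_model"))
  p <- m$params
  params_sec <- switch(m$tag,
    toggle1 = , toggle2 = list(a1 = p$a1, a2 = p$a2, beta = p$beta,
      K_a = p$act$K, n_a = p$act$n, K_r = p$rep$K, n_r = p$rep$n,
      D1 = p$D1, D2 = p$D2),
    hb = list(alpha_b = p$alpha_b, alpha_h = p$alpha_h, b0 = p$b0, h0 = p$h0,
      nb = p$nb, nh = p$nh, beta = p$beta, D = p$D),
    scalar = {
      xs <- seq(0, m$L, length.out = n_samples)
      list(D = p$D, x = xs, alpha = p$alpha_field(xs))
    })
  cfg <- list(model = list(family = m$tag, L = m$L,
                           D = m$diffusivities),
              params = params_sec)
  for (i in seq_along(m$gradients)) {
    cfg[[paste0("gradient", i)]] <- gradient_to_section(m$gradients[[i]])
  }
  write_config(cfg, path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- read_config(path)
  if (is.null(cfg$model$family)) abort("config lacks `model.family`.")
  fam <- cfg$model$family
  ps <- cfg$params
  params <- switch(fam,
    toggle1 = , toggle2 = toggle_params(ps$a1, ps$a2, ps$beta,
      hill_params(ps$K_a, ps$n_a), hill_params(ps$K_r, ps$n_r),
      D1 = ps$D1 %||% 0, D2 = ps$D2 %||% 0),
    hb = hb_params(ps$alpha_b, ps$alpha_h, ps$b0, ps$h0, ps$nb, ps$nh,
                   ps$beta, ps$D),
    scalar = {
      af <- approxfun(ps$x, ps$alpha, rule = 2)
      scalar_params(ps$D, af)
    },
    abort(sprintf("unknown model family '%s' in config.", fam)))
  gl <- lapply(grep("^gradient[0-9]+$", names(cfg), value = TRUE),
               function(nm) section_to_gradient(cfg[[nm]]))
  m <- build_model(fam, params, gl, L = cfg$model$L)
  if (!is.null(cfg$model$D)) m$diffusivities <- cfg$model$D
  m
}

# scenarios -------------------------------------------------------------------

#' Default toggle-switch fixture
#'
#' The package's reference toggle switch for single-gradient examples:
#' asymmetric production (`a1 = 1.5`, `a2 = 1`, `beta = 1`), Hill
#' coefficients 2, `K_a = 0.5`, `K_r = 0.3`, over an exponential gradient
#' `b = 2`, `lam = 0.35` on `x` in `[0, 1]`. Chosen so that the final
#' profile yields the class sequence mono_high -> bistable -> mono_low along
#' the axis (the switch is bistable for morphogen concentrations roughly in
#' `[0.62, 1.13]`, i.e. `x` in `[0.20, 0.41]`).
#'
#' @param gradient A `gradient_spec` to attach (default the static profile).
#' @return A `"toggle1"` `bf_model`.
#' @export
default_toggle <- function(gradient = gradient_static(b = 2, lam = 0.35)) {
  build_model("toggle1",
              toggle_params(a1 = 1.5, a2 = 1, beta = 1,
                            act = hill_params(K = 0.5, n = 2),
                            rep = hill_params(K = 0.3, n = 2)),
              gradients = gradient, L = 1)
}

#' Preset experiment scenarios
#'
#' Fully wired experiment bundles reproducing the package's standard
#' computations:
#'
#' * `fig2_emergence` — precision of a boundary forming atop an emerging
#'   gradient, for a list of `kappa` values (default toggle fixture, 50
#'   random initial conditions clustered near the origin, 100 grid
#'   positions).
#' * `fig3_sweep` — precision enhancement by gradient decay at matched
#'   boundary shift (default `0.05 * L`), over seeded ensembles and `kappa`
#'   in `{0.1, 1, 10}`.
#' * `fig5_localization` — antiparallel-gradient toggle (`a = 1.7`, `beta =
#'   0.35`, `n_a = n_r = 2`, `K_a = 0.75`, `K_r = 1`, `D1 = D2 = 1`) with
#'   opposing exponentials crossing mid-domain; front localization and the
#'   ODE boundary approximation.
#' * `fig6_stripes` — scalar cubic model (`D = 0.1`) whose threshold field
#'   oscillates about the balance level 0.5 with amplitude 0.1, giving
#'   multiple localization points and stripe refinement.
#' * `hb_yang` — the Hunchback-Bicoid system; requires an explicit parameter
#'   file (no silent defaults) giving the published parameter values.
#'
#' @param name Scenario name.
#' @param overrides Named list of overrides merged into the scenario's
#'   configuration.
#' @param param_file For `hb_yang`: path to a config file with `[params]`
#'   and `[gradient1]` sections (see
#'   `system.file("extdata", "hb_yang_template.toml", package =
#'   "bistablefronts")`).
#'
#' @return A `bf_scenario`: list with `name`, `cfg`, `model`, and a
#'   `protocol` closure running the scenario's computation.
#' @export
scenario <- function(name = c("fig2_emergence", "fig3_sweep",
                              "fig5_localization", "fig6_stripes", "hb_yang"),
                     overrides = list(), param_file = NULL) {
  name <- match.arg(name)
  cfg <- scenario_defaults(name)
  cfg <- modifyList(cfg, overrides)
  switch(name,
    fig2_emergence = scenario_fig2(cfg),
    fig3_sweep = scenario_fig3(cfg),
    fig5_localization = scenario_fig5(cfg),
    fig6_stripes = scenario_fig6(cfg),
    hb_yang = scenario_hb(cfg, param_file))
}

scenario_defaults <- function(name) {
  switch(name,
    fig2_emergence = list(
      n_ics = 50L, seed = 1L, n_grid = 100L, ic_frac = 0.2,
      kappa = c(0.01, 0.1, 1, 10, Inf), b = 2, lam = 0.35),
    fig3_sweep = list(
      n_ics = 20L, seeds = 1:10, n_grid = 40L, ic_frac = 0.2,
      kappa = c(0.1, 1, 10), shift = 0.05, b = 2, lam = 0.35),
    fig5_localization = list(
      a = 1.7, beta = 0.35, n = 2, K_a = 0.75, K_r = 1, D1 = 1, D2 = 1,
      L = 100, lam = 40, b = 4, grid_n = 401L, t_end = 250,
      ic = c(0, 2), eps = 0, map_n = 33L),
    fig6_stripes = list(
      a = 0.1, D = 0.1, L = 40, n_cross = 3L, grid_n = 401L, t_end = 150,
      ic = 0.5),
    hb_yang = list(grid_n = 401L, t_end = 600, variant = "wt"))
}

scenario_fig2 <- function(cfg) {
  m <- default_toggle(gradient_emerging(cfg$b, cfg$lam, gamma = 1))
  amax <- max(m$umax)
  ens <- make_ic_ensemble(cfg$n_ics,
                          list(c(0, cfg$ic_frac * amax), c(0, cfg$ic_frac * amax)),
                          seed = cfg$seed)
  xs <- seq(0, m$L, length.out = cfg$n_grid)
  structure(list(
    name = "fig2_emergence", cfg = cfg, model = m, ensemble = ens, xs = xs,
    protocol = function(kappa = cfg$kappa, ...) {
      emergence_experiment(m, ens, kappa, xs = xs, ...)
    }), class = "bf_scenario")
}

scenario_fig3 <- function(cfg) {
  make_m <- function(gamma) default_toggle(gradient_decaying(cfg$b, cfg$lam, gamma))
  m0 <- make_m(1)
  amax <- max(m0$umax)
  xs <- seq(0, m0$L, length.out = cfg$n_grid)
  sk <- sigma_and_kappa(m0, gamma = 1, xs = xs)
  structure(list(
    name = "fig3_sweep", cfg = cfg, model = m0, sigma = sk$sigma, xs = xs,
    protocol = function(kappa = cfg$kappa, seeds = cfg$seeds, ...) {
      box <- list(c(0, cfg$ic_frac * amax), c(0, cfg$ic_frac * amax))
      res <- purrr::map(kappa, function(kap) {
        gam <- kap * sk$sigma
        mk <- make_m(gam)
        tf <- readout_time_for_shift(mk$gradients[[1]], cfg$shift * mk$L)
        scan_tf <- scan_axis(freeze_model(mk, tf), t = 0, xs = xs)
        purrr::map(seeds, function(seed) {
          ens <- make_ic_ensemble(cfg$n_ics, box, seed = seed)
          out <- sweep_experiment(mk, ens, tf, xs = xs, scan_tf = scan_tf)
          dplyr::mutate(as_tibble(out), kappa = kap, seed = seed,
                        .before = 1)
        }) |> dplyr::bind_rows()
      })
      dplyr::bind_rows(res)
    }), class = "bf_scenario")
}

fig5_model <- function(cfg) {
  p <- toggle_params(a1 = cfg$a, a2 = cfg$a, beta = cfg$beta,
                     act = hill_params(cfg$K_a, cfg$n),
                     rep = hill_params(cfg$K_r, cfg$n),
                     D1 = cfg$D1, D2 = cfg$D2)
  g1 <- gradient_static(cfg$b, cfg$lam)
  g2 <- gradient_tabulated(data.frame(
    x = seq(0, cfg$L, length.out = 201L),
    value = cfg$b * exp(-(cfg$L - seq(0, cfg$L, length.out = 201L)) / cfg$lam)))
  build_model("toggle2", p, list(g1, g2), L = cfg$L)
}

scenario_fig5 <- function(cfg) {
  m <- fig5_model(cfg)
  grid <- rd_grid(cfg$grid_n, cfg$L)
  structure(list(
    name = "fig5_localization", cfg = cfg, model = m, grid = grid,
    protocol = function(ic = cfg$ic, t_end = cfg$t_end, eps = cfg$eps, ...) {
      scan <- scan_axis(m, t = 0, xs = grid$xs[seq(1, grid$N, by = 4L)])
      sol <- integrate_rd(m, ic, c(0, t_end), grid = grid)
      traj <- extract_boundary(sol, scan)
      vm <- velocity_map(m, xs = seq(scan$x_a, scan$x_p,
                                     length.out = cfg$map_n),
                         t = 0, scan = scan, ...)
      loc <- localization_points(vm)
      t_form <- attr(traj, "t_form")
      w0 <- traj$w[match(t_form, traj$t)]
      appr <- ode_boundary(vm, w0 = w0, eps = eps, t_span = c(t_form, t_end),
                           times = traj$t[traj$t >= t_form])
      comp <- compare_boundary(traj, appr)
      list(scan = scan, solution = sol, trajectory = traj,
           velocity = vm, localization = loc, approx = appr,
           comparison = comp)
    }), class = "bf_scenario")
}

scenario_fig6 <- function(cfg) {
  af <- function(x) 0.5 + cfg$a * sin(cfg$n_cross * 2 * pi * x / cfg$L)
  m <- build_model("scalar", scalar_params(cfg$D, af), L = cfg$L)
  grid <- rd_grid(cfg$grid_n, cfg$L)
  structure(list(
    name = "fig6_stripes", cfg = cfg, model = m, grid = grid,
    protocol = function(ic = cfg$ic, t_end = cfg$t_end, ...) {
      sol <- integrate_rd(m, ic, c(0, t_end), grid = grid)
      vm <- velocity_map(m, xs = seq(0, cfg$L, length.out = 81L), t = 0)
      loc <- localization_points(vm)
      list(solution = sol, velocity = vm, localization = loc)
    }), class = "bf_scenario")
}

scenario_hb <- function(cfg, param_file) {
  if (is.null(param_file)) {
    abort(paste(
      "the hb_yang scenario requires an explicit parameter file with the",
      "published Hb-Bcd parameter values (Yang et al. 2020); none are",
      "bundled. See system.file('extdata', 'hb_yang_template.toml',",
      "package = 'bistablefronts') for the expected keys."))
  }
  pc <- read_config(param_file)
  need <- c("alpha_b", "alpha_h", "b0", "h0", "nb", "nh", "beta", "D")
  missing <- setdiff(need, names(pc$params))
  if (is.null(pc$model$L)) missing <- c("L", missing)
  if (is.null(pc$gradient1)) missing <- c(missing, "gradient1")
  if (length(missing) > 0L) {
    abort(sprintf("hb_yang parameter file lacks values for: %s (no defaults are assumed)",
                  paste(missing, collapse = ", ")))
  }
  ps <- pc$params
  params <- hb_params(ps$alpha_b, ps$alpha_h, ps$b0, ps$h0, ps$nb, ps$nh,
                      ps$beta, ps$D)
  g <- section_to_gradient(pc$gradient1)
  L <- pc$model$L
  variant <- cfg$variant
  if (variant == "bcd1.0") {
    g$bm <- g$bm / 2  # halved Bcd dosage
  }
  m <- build_model("hb", params, g, L = L)
  grid <- rd_grid(cfg$grid_n, L)
  structure(list(
    name = "hb_yang", cfg = cfg, model = m, grid = grid, variant = variant,
    protocol = function(ic, t_end = cfg$t_end, ...) {
      sol <- integrate_rd(m, ic, c(0, t_end), grid = grid)
      scan <- scan_axis(freeze_model(m, 0), t = 0,
                        xs = grid$xs[seq(1, grid$N, by = 4L)])
      traj <- extract_boundary(sol, scan)
      list(solution = sol, scan = scan, trajectory = traj)
    }), class = "bf_scenario")
}

#' @export
print.bf_scenario <- function(x, ...) {
  cat(sprintf("<bf_scenario: %s>\n", x$name))
  print(x$model)
  invisible(x)
}

# tables and run records ------------------------------------------------------

#' Write a result table as commented-header TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @param units Optional named character vector of column units for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, units = NULL) {
  hdr <- sprintf("# columns: %s", paste(names(df), collapse = "\t"))
  if (!is.null(units)) {
    hdr <- c(hdr, sprintf("# units: %s",
                          paste(units[names(df)] %||% "", collapse = "\t")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              comment.char = "#"))
}

#' Run record
#'
#' A provenance stub attached to every CLI run: configuration snapshot,
#' seed, package version, output paths and wall time.
#'
#' @param cfg Configuration list.
#' @param seed Seed(s) used.
#' @param outputs Character vector of output file paths.
#' @param wall_time Elapsed seconds.
#' @return A `run_record` list.
#' @export
run_record <- function(cfg, seed, outputs, wall_time) {
  structure(list(
    config = cfg, seed = seed,
    version = as.character(utils::packageVersion("bistablefronts")),
    outputs = outputs, wall_time = wall_time,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_record")
}
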