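test_that("ensembles are seeded, boxed and reproducible", {
  e1 <- make_ic_ensemble(20, list(c(0, 0.3), c(0.1, 0.5)), seed = 4)
  e2 <- make_ic_ensemble(20, list(c(0, 0.3), c(0.1, 0.5)), seed = 4)
  expect_identical(unclass(e1), unclass(e2))
  expect_true(all(e1[, 1] >= 0 & e1[, 1] <= 0.3))
  expect_true(all(e1[, 2] >= 0.1 & e1[, 2] <= 0.5))

  # a degenerate box gives identical (uniform) initial conditions
  ep <- make_ic_ensemble(5, list(c(0.2, 0.2), c(0.7, 0.7)), seed = 1)
  expect_true(all(ep[, 1] == 0.2 & ep[, 2] == 0.7))

  # empirical means sit within 3 standard errors of the box midpoints
  eb <- make_ic_ensemble(1e4, list(c(0, 1), c(0.5, 1.5)), seed = 8)
  se <- 1 / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(eb[, 1]) - 0.5), 3 * se)
  expect_lt(abs(mean(eb[, 2]) - 1.0), 3 * se)

  expect_error(make_ic_ensemble(3, list(c(-1, 1), c(0, 1))), "nonnegative")

  # drawing an ensemble does not disturb the caller's RNG stream
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(make_ic_ensemble(5, list(c(0, 1), c(0, 1)), seed = 9))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("config files round-trip every model family", {
  tmp <- withr::local_tempfile(fileext = ".toml")
  probes <- list(t = 0.7, xs = c(0.11, 0.52, 0.93))

  models <- list(
    toggle_fixture(gradient_emerging(2, 0.35, 0.4)),
    toggle2_fixture(),
    build_model("hb", hb_params(2, 3, 0.5, 0.4, 2, 3, 1, 0.1),
                gradient_bcd(1.2, 0.25, 0.05, t0 = 2), L = 1),
    scalar_fixture(D = 0.2, alpha = 0.35))
  for (m in models) {
    write_model_config(m, tmp)
    m2 <- read_model_config(tmp)
    expect_equal(m2$tag, m$tag)
    expect_equal(m2$diffusivities, m$diffusivities)
    u <- matrix(rep(0.4, m$n_species), nrow = 1)
    for (x in probes$xs * m$L) {
      expect_equal(m2$rhs(probes$t, x, u[1, ]), m$rhs(probes$t, x, u[1, ]),
                   tolerance = 1e-9)
    }
  }

  # a second write of the re-read model is byte-identical (stable serialization)
  write_model_config(models[[1]], tmp)
  txt1 <- readLines(tmp)
  write_model_config(read_model_config(tmp), tmp)
  expect_identical(readLines(tmp), txt1)
})

test_that("malformed configs fail loudly and name the offender", {
  tmp <- withr::local_tempfile(fileext = ".toml")
  writeLines(c("[params]", "beta = banana"), tmp)
  expect_error(read_config(tmp), "params.beta")
  writeLines(c("orphan = 1"), tmp)
  expect_error(read_config(tmp), "outside any section")
  expect_error(read_config(file.path(tempdir(), "nope.toml")), "not found")
})

test_that("scenarios wire their models and refuse silent Hb defaults", {
  sc2 <- scenario("fig2_emergence", overrides = list(n_ics = 5L))
  expect_equal(sc2$model$gradients[[1]]$kind, "emerging")
  expect_equal(nrow(sc2$ensemble), 5L)
  expect_true(is.function(sc2$protocol))

  sc5 <- scenario("fig5_localization")
  expect_equal(sc5$model$tag, "toggle2")
  expect_equal(sc5$model$diffusivities, c(1, 1))
  # the printed parameter set
  expect_equal(sc5$model$params$a1, 1.7)
  expect_equal(sc5$model$params$beta, 0.35)
  expect_equal(sc5$model$params$act$K, 0.75)
  expect_equal(sc5$model$params$rep$K, 1)
  # antiparallel gradients cross mid-domain
  g <- sc5$model$gradients
  mid <- sc5$model$L / 2
  expect_equal(eval_gradient(g[[1]], 0, mid), eval_gradient(g[[2]], 0, mid),
               tolerance = 1e-6)

  sc6 <- scenario("fig6_stripes")
  af <- sc6$model$params$alpha_field
  expect_true(sum(abs(diff(sign(af(seq(0.1, sc6$model$L - 0.1,
                                       length.out = 400)) - 0.5)))) >= 6)

  expect_error(scenario("hb_yang"), "parameter file")
  expect_error(scenario("hb_yang"), "Yang")

  # the shipped template is deliberately blank: using it as-is must fail,
  # naming the missing values
  tmpl <- system.file("extdata", "hb_yang_template.toml",
                      package = "bistablefronts")
  expect_error(scenario("hb_yang", param_file = tmpl), "alpha_b")
})

test_that("a filled Hb parameter file wires the model and its variants", {
  # synthetic stand-in values (NOT the published ones): chosen only to give
  # a bistable-at-low-Bcd regulatory function for structural checks
  tmp <- withr::local_tempfile(fileext = ".toml")
  writeLines(c(
    "[model]", 'family = "hb"', "L = 1",
    "[params]", "alpha_b = 0.6", "alpha_h = 1", "b0 = 0.1", "h0 = 0.5",
    "nb = 2", "nh = 5", "beta = 1", "D = 1e-4",
    "[gradient1]", 'kind = "bcd"', "bm = 1", "lam = 0.15",
    "omega0 = 0.0", "t0 = 0"), tmp)
  sc <- scenario("hb_yang", param_file = tmp)
  expect_equal(sc$model$tag, "hb")

  # high Bcd anterior is monostable-high, Bcd-poor posterior bistable
  scan <- scan_axis(sc$model, t = 0, xs = seq(0, 1, length.out = 41L))
  expect_equal(scan$classes[1], "mono_high")
  expect_equal(scan$classes[41], "bistable")
  expect_false(is.na(scan$x_crit))
  # x_crit sits where the Bcd profile crosses its critical concentration
  b_crit <- critical_parameter(function(b) {
    build_model("hb", sc$model$params, gradient_static(b, Inf), L = 1)
  }, c(1e-3, 0.9))
  x_pred <- -0.15 * log(b_crit / 1)
  expect_equal(scan$x_crit, x_pred, tolerance = 0.01)

  # the half-dosage variant halves the gradient amplitude
  scb <- scenario("hb_yang", overrides = list(variant = "bcd1.0"),
                  param_file = tmp)
  expect_equal(eval_gradient(scb$model$gradients[[1]], 0, 0.2),
               eval_gradient(sc$model$gradients[[1]], 0, 0.2) / 2)
})

test_that("result tables round-trip through commented TSV", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- tibble::tibble(x = c(0.1, 0.2), class = c("a", "b"), v = c(1L, 2L))
  write_result_table(df, tmp, units = c(x = "length", v = "count"))
  expect_true(startsWith(readLines(tmp, n = 1), "#"))
  back <- read_result_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(df))
})

test_that("the CLI runs a scan end to end and rejects unknown subcommands", {
  cli <- system.file("cli", "bistablefronts.R", package = "bistablefronts")
  skip_if(cli == "", "CLI script not installed")
  cfg <- withr::local_tempfile(fileext = ".toml")
  write_model_config(toggle_fixture(), cfg)
  out <- withr::local_tempdir()

  res <- system2("Rscript", c(cli, "scan", "--config", shQuote(cfg),
                              "--out", shQuote(out)),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(res, "status") %||% 0L, 0L)
  expect_true(file.exists(file.path(out, "scan.tsv")))
  expect_true(file.exists(file.path(out, "run_record.json")))
  tab <- read_result_table(file.path(out, "scan.tsv"))
  expect_true(all(c("x", "class") %in% names(tab)))
  expect_true(any(tab$class == "bistable"))

  bad <- suppressWarnings(
    system2("Rscript", c(cli, "frobnicate"), stdout = TRUE, stderr = TRUE))
  expect_false((attr(bad, "status") %||% 0L) == 0L)
})
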