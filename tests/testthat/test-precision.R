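test_that("tight bounds collapse for unanimous ensembles and widen for split ones", {
  m <- toggle_fixture()
  sc <- scan_axis(m, t = 0, xs = seq(0, 1, length.out = 21L))

  # one state deep in the high basin everywhere: precise boundary at x_p
  deep_high <- matrix(c(5, 0), nrow = 1L)
  b <- tight_bounds(m, sc, deep_high)
  expect_equal(b$x_tilde_a, sc$x_p)
  expect_equal(b$x_tilde_p, sc$x_p)
  expect_equal(irregularity_R(b, sc), 0)

  # an always-high and an always-low member: the whole interval is irregular
  split <- rbind(c(5, 0), c(0, 5))
  b2 <- tight_bounds(m, sc, split)
  expect_equal(b2$x_tilde_a, sc$x_a)
  expect_equal(b2$x_tilde_p, sc$x_p)
  expect_equal(irregularity_R(b2, sc), 1)
})

test_that("tight bounds agree with exhaustive dense-grid labelling", {
  m <- toggle_fixture()
  sc <- scan_axis(m, t = 0, xs = seq(0, 1, length.out = 21L))
  ens <- make_ic_ensemble(8, list(c(0, 0.3), c(0, 0.3)), seed = 11)
  b <- tight_bounds(m, sc, ens)

  xs_dense <- seq(sc$x_a, sc$x_p, length.out = 121L)
  labs <- sapply(xs_dense, function(x) basin_label(m, x, 0, unclass(ens)))
  all_high <- apply(labs, 2, function(l) all(l == "high"))
  none_high <- apply(labs, 2, function(l) all(l == "low"))
  xa_oracle <- if (any(all_high)) xs_dense[max(which(all_high))] else sc$x_a
  xp_oracle <- if (any(none_high)) xs_dense[min(which(none_high))] else sc$x_p

  step <- diff(xs_dense)[1]
  expect_lt(abs(b$x_tilde_a - xa_oracle), step + sc$tol)
  expect_lt(abs(b$x_tilde_p - xp_oracle), step + sc$tol)
  expect_true(b$mixed_seen)
  expect_true(sc$x_a <= b$x_tilde_a && b$x_tilde_a <= b$x_tilde_p &&
                b$x_tilde_p <= sc$x_p)
})

test_that("R and R_t follow their defining arithmetic", {
  fake_scan <- structure(list(x_a = 0.45, x_p = 0.75, t = 0, tol = 1e-4),
                         class = "bifurcation_scan")
  expect_equal(irregularity_R(list(x_tilde_a = 0.50, x_tilde_p = 0.70),
                              fake_scan), 2 / 3)
  expect_equal(irregularity_R(list(x_tilde_a = 0.6, x_tilde_p = 0.6),
                              fake_scan), 0)
  expect_error(irregularity_R(list(x_tilde_a = 0, x_tilde_p = 0),
                              structure(list(x_a = 0.5, x_p = 0.5),
                                        class = "bifurcation_scan")),
               "degenerate")

  sc_t <- structure(list(x_a = 0.1, x_p = 0.5), class = "bifurcation_scan")
  sc_f <- structure(list(x_a = 0.2, x_p = 0.4), class = "bifurcation_scan")
  expect_equal(irregularity_at_time(0.6, sc_f, sc_f), 0.6)   # t = t_f
  expect_equal(irregularity_at_time(0.6, sc_t, sc_f), 0.3)   # twice the width
  expect_equal(irregularity_at_time(0, sc_t, sc_f), 0)
  expect_error(irregularity_at_time(0.5, sc_f, structure(list(x_a = NA, x_p = NA),
                                                         class = "bifurcation_scan")))
})

test_that("adding members to an ensemble never decreases R", {
  m <- toggle_fixture()
  sc <- scan_axis(m, t = 0, xs = seq(0, 1, length.out = 21L))
  big <- make_ic_ensemble(10, list(c(0, 0.4), c(0, 0.4)), seed = 5)
  Rs <- vapply(c(2L, 5L, 10L), function(k) {
    irregularity_R(tight_bounds(m, sc, unclass(big)[seq_len(k), , drop = FALSE]),
                   sc)
  }, numeric(1))
  expect_true(all(diff(Rs) >= -1e-12))
})

test_that("readout time matches the level-set speed of the decaying gradient", {
  g <- gradient_decaying(b = 1, lam = 0.2, gamma = 0.1)
  expect_equal(readout_time_for_shift(g, 0.02), 1)
  expect_equal(readout_time_for_shift(gradient_decaying(1, 0.2, 0.2), 0.02), 0.5)
  t_num <- readout_time_for_shift(g, 0.02, method = "numeric")
  expect_lt(abs(t_num - 1) / 1, 1e-6)
  expect_error(readout_time_for_shift(gradient_decaying(1, 0.2, 0), 0.02),
               "gamma")
  expect_error(readout_time_for_shift(gradient_static(1, 0.2), 0.02),
               "decaying")
})

test_that("emergence: static control reproduces frozen-basin labels, kappa=0 washes out", {
  m <- default_toggle(gradient_emerging(2, 0.35, gamma = 1))
  xs <- seq(0, 1, length.out = 25L)
  ens <- make_ic_ensemble(8, list(c(0, 0.3), c(0, 0.3)), seed = 2)
  res <- emergence_experiment(m, ens, kappa_targets = c(0.01, Inf), xs = xs)

  expect_equal(res$R[res$kappa == 0.01], 0)

  # kappa = Inf is the static-gradient control: same answer as labelling the
  # ensemble in the frozen final-profile system directly
  m_inf <- default_toggle(gradient_static(2, 0.35))
  sc <- scan_axis(m_inf, t = 0, xs = xs)
  b <- tight_bounds(m_inf, sc, ens)
  expect_equal(res$x_tilde_a[res$kappa == Inf], b$x_tilde_a, tolerance = 1e-2)
  expect_equal(res$x_tilde_p[res$kappa == Inf], b$x_tilde_p, tolerance = 1e-2)
  expect_equal(res$R[res$kappa == Inf], irregularity_R(b, sc), tolerance = 0.05)
})

test_that("sweep: anterior cells preset to steady state stay high; gamma=0 errors", {
  m <- default_toggle(gradient_decaying(2, 0.35, gamma = 0.02))
  xs <- seq(0, 1, length.out = 25L)
  t_f <- readout_time_for_shift(m$gradients[[1]], 0.05)
  res <- sweep_experiment(m, ens = "steady_state", t_f = t_f, xs = xs)
  # single deterministic per-cell start: a precise boundary, R = 0
  expect_equal(res$R, 0)
  labs <- attr(res, "labels")
  sc_tf <- attr(res, "scan_tf")
  # cells anterior of the t_f bistable interval end high, posterior low
  expect_true(all(unlist(labs[xs < sc_tf$x_a]) == "high"))
  expect_true(all(unlist(labs[xs > sc_tf$x_p]) == "low"))
  # region that turned bistable during the sweep keeps its high state
  turned <- xs > sc_tf$x_a & xs < sc_tf$x_a + 0.04
  expect_true(all(unlist(labs[turned]) == "high"))

  expect_error(sweep_experiment(default_toggle(gradient_static(2, 0.35)),
                                "steady_state", 1, xs = xs), "decaying")
})

test_that("R_t at the readout time equals R (sweep consistency)", {
  m <- default_toggle(gradient_decaying(2, 0.35, gamma = 0.05))
  xs <- seq(0, 1, length.out = 25L)
  t_f <- readout_time_for_shift(m$gradients[[1]], 0.03)
  ens <- make_ic_ensemble(6, list(c(0, 0.3), c(0, 0.3)), seed = 9)
  res <- sweep_experiment(m, ens, t_f, xs = xs)
  sc_tf <- attr(res, "scan_tf")
  expect_equal(irregularity_at_time(res$R, sc_tf, sc_tf), res$R)
  expect_true(res$R >= 0 && res$R <= 1)
})
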