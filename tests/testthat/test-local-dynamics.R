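test_that("fixed points of the decoupled and cubic systems are exact", {
  # toggle1 with zero morphogen: u1 decouples; single stable point (0, a2/beta)
  m <- default_toggle(gradient_emerging(2, 0.35, 1))
  fps <- find_fixed_points(m, x = 0.5, t = 0)   # emerging gradient is 0 at t = 0
  expect_length(fps, 1L)
  expect_equal(fps[[1]]$state, c(0, 1), tolerance = 1e-7)
  expect_equal(fps[[1]]$stability, "stable")

  # scalar cubic: {0 stable, alpha unstable, 1 stable}
  ms <- scalar_fixture(alpha = 0.3)
  fps <- find_fixed_points(ms, 0.2, 0)
  expect_length(fps, 3L)
  expect_equal(vapply(fps, function(p) p$state, numeric(1)), c(0, 0.3, 1),
               tolerance = 1e-7)
  expect_equal(vapply(fps, function(p) p$stability, character(1)),
               c("stable", "unstable", "stable"))
  # leading rates are the cubic's derivative at its roots
  expect_equal(vapply(fps, function(p) p$leading_rate, numeric(1)),
               c(-0.3, 0.3 * 0.7, -0.7), tolerance = 1e-6)
})

test_that("the symmetric two-input toggle has a swap-symmetric portrait", {
  m <- toggle2_fixture()
  fps <- find_fixed_points(m, x = m$L / 2, t = 0)  # gradients cross here
  expect_length(fps, 3L)
  st <- Filter(function(p) p$stability == "stable", fps)
  expect_length(st, 2L)
  # the two stable states are mirror images; the middle point is symmetric
  expect_equal(st[[1]]$state, rev(st[[2]]$state), tolerance = 1e-6)
  mid <- Filter(function(p) p$stability != "stable", fps)[[1]]
  expect_equal(mid$state[1], mid$state[2], tolerance = 1e-6)
})

test_that("portrait classification distinguishes the three regimes", {
  m <- toggle_fixture()
  expect_equal(classify_portrait(find_fixed_points(m, 0.02, 0), m), "mono_high")
  expect_equal(classify_portrait(find_fixed_points(m, 0.30, 0), m), "bistable")
  expect_equal(classify_portrait(find_fixed_points(m, 0.90, 0), m), "mono_low")

  fake <- replicate(3, list(state = c(1, 1), stability = "stable",
                            leading_rate = -1), simplify = FALSE)
  expect_error(classify_portrait(fake, m), "topology")
})

test_that("scan_axis finds the class sequence and brackets its endpoints", {
  m <- toggle_fixture()
  sc <- scan_axis(m, t = 0, xs = seq(0, 1, length.out = 41L))
  expect_equal(rle(sc$classes)$values, c("mono_high", "bistable", "mono_low"))
  expect_equal(sc$x_crit, sc$x_a)
  expect_true(sc$x_a < sc$x_p)

  # classification flips just outside the refined endpoints
  d <- 20 * sc$tol
  expect_equal(classify_portrait(find_fixed_points(m, sc$x_a - d, 0), m),
               "mono_high")
  expect_equal(classify_portrait(find_fixed_points(m, sc$x_p + d, 0), m),
               "mono_low")
  expect_equal(classify_portrait(find_fixed_points(m, sc$x_a + d, 0), m),
               "bistable")

  # zero morphogen everywhere: uniform classification, no bistable interval
  m0 <- default_toggle(gradient_emerging(2, 0.35, 1))
  sc0 <- scan_axis(m0, t = 0, xs = seq(0, 1, length.out = 21L))
  expect_true(all(sc0$classes == "mono_low"))
  expect_true(is.na(sc0$x_a) && is.na(sc0$x_crit))

  # refining the fixed-point seed grid does not change the classification
  cls2 <- vapply(sc$xs, function(x) {
    classify_portrait(find_fixed_points(m, x, 0, n_seed = 16L), m)
  }, character(1))
  expect_equal(cls2, sc$classes)
})

test_that("tidy/glance expose the scan as tables", {
  m <- toggle_fixture()
  sc <- scan_axis(m, t = 0, xs = seq(0, 1, length.out = 21L))
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 21L)
  expect_true(all(c("x", "class", "u1_low", "u1_high", "u1_unstable") %in%
                    names(td)))
  bi <- td$class == "bistable"
  expect_true(all(!is.na(td$u1_unstable[bi])))
  expect_true(all(td$u1_high[bi] > td$u1_unstable[bi]))
  expect_true(all(td$u1_unstable[bi] > td$u1_low[bi]))
  gl <- glance(sc)
  expect_equal(gl$x_a, sc$x_a)
})

test_that("critical_parameter locates bifurcation values", {
  # scalar family: bistable exactly for alpha in (0, 1); probes graze the
  # marginal fixed point, whose warning is part of the documented behaviour
  f <- function(a) build_model("scalar", scalar_params(0.1, a))
  expect_equal(suppressWarnings(critical_parameter(f, c(0.5, 1.5))), 1,
               tolerance = 1e-5)
  expect_lt(abs(suppressWarnings(critical_parameter(f, c(-0.5, 0.5)))), 1e-5)
  expect_error(critical_parameter(f, c(0.2, 0.8)), "bracket")

  # toggle1 against a dense-scan oracle on the morphogen value
  mk <- function(al) default_toggle(gradient_static(max(al, 1e-12), Inf))
  crit <- critical_parameter(mk, c(0.3, 0.8))
  als <- seq(0.3, 0.8, length.out = 281)
  cls <- vapply(als, function(al) {
    classify_portrait(find_fixed_points(mk(al), 0, 0), mk(al))
  }, character(1))
  oracle <- als[max(which(cls == cls[1]))]
  # the dense scan brackets the bifurcation to one grid step
  expect_lt(abs(crit - oracle), diff(als)[1] + 1e-6)
})

test_that("basin labels identify the reached attractor", {
  m <- toggle_fixture()
  x <- 0.3  # bistable here
  fps <- find_fixed_points(m, x, 0)
  hl <- list(high = fps[[which.max(sapply(fps, function(p) p$state[1]))]],
             low = fps[[which.min(sapply(fps, function(p) p$state[1]))]])
  # starting exactly at a stable state stays there
  expect_equal(basin_label(m, x, 0, hl$high$state), "high")
  expect_equal(basin_label(m, x, 0, hl$low$state), "low")
  # far inside the high basin
  expect_equal(basin_label(m, x, 0, c(5, 0)), "high")
  expect_error(basin_label(m, x, 0, c(-1, 0)), "nonnegative")
})

test_that("basins are nested along the monotone gradient", {
  m <- toggle_fixture()
  sc <- scan_axis(m, t = 0, xs = seq(0, 1, length.out = 21L))
  xs <- seq(sc$x_a + 0.01, sc$x_p - 0.01, length.out = 4L)
  ens <- make_ic_ensemble(12, list(c(0, 1.5), c(0, 1.5)), seed = 3)
  labs <- sapply(xs, function(x) basin_label(m, x, 0, unclass(ens)))
  for (j in seq_len(ncol(labs) - 1L)) {
    # anything high at the posterior position is high at the anterior one
    expect_true(all(labs[labs[, j + 1L] == "high", j] == "high"))
  }
})

test_that("sigma matches the relaxation rate of simulated trajectories", {
  m <- default_toggle(gradient_emerging(2, 0.35, gamma = 1))
  xs <- seq(0, 1, length.out = 21L)
  sk <- sigma_and_kappa(m, gamma = 0.05, xs = xs)
  expect_equal(sk$kappa, 0.05 / sk$sigma)

  # locate the slowest stable state and fit its decay exponent directly
  bi <- which(sk$scan$classes == "bistable")
  rates <- lapply(sk$scan$portraits[bi], function(fps) {
    vapply(Filter(function(p) p$stability == "stable", fps),
           function(p) abs(p$leading_rate), numeric(1))
  })
  i_min <- bi[which.min(vapply(rates, min, numeric(1)))]
  fps <- sk$scan$portraits[[i_min]]
  st <- Filter(function(p) p$stability == "stable", fps)
  slow <- st[[which.min(vapply(st, function(p) abs(p$leading_rate), numeric(1)))]]
  x_slow <- sk$scan$xs[i_min]

  m_inf <- sk$scan$model
  u0 <- slow$state * (1 + 1e-4)  # small perturbation: stay in the linear regime
  ts <- seq(0, 18 / sk$sigma, length.out = 40L)
  sol <- deSolve::ode(y = u0, times = ts,
                      func = function(t, y, p) {
                        list(m_inf$rhs(0, x_slow, y))
                      }, parms = NULL, rtol = 1e-12, atol = 1e-14)
  d <- sqrt(rowSums((sol[, -1, drop = FALSE] -
                       matrix(slow$state, nrow(sol), 2, byrow = TRUE))^2))
  keep <- d > 1e-10 & seq_along(d) > 10  # late-time, pre-floor window
  fit <- lm(log(d[keep]) ~ ts[keep])
  expect_equal(unname(-coef(fit)[2]), sk$sigma, tolerance = 0.05)
})
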