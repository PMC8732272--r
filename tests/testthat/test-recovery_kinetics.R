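test_that("body_burden and normalize_burden are the stated products/ratios", {
  expect_equal(body_burden(100, 1000), 1e5)
  expect_equal(body_burden(0, 50), 0)
  expect_equal(body_burden(2.5, 400), 1000)
  expect_error(body_burden(10, 0), "mass")
  expect_equal(normalize_burden(500, 500), 1)
  expect_equal(normalize_burden(1000, 500), 2)
  expect_error(normalize_burden(1, 0), "positive")
})

test_that("population_burden_series combines and normalizes at t0", {
  conc <- data.frame(year = 2007:2009, conc_ww = c(10, 5, NA))
  wt <- data.frame(year = 2007:2009, mass_g = c(1000, 1000, 1000))
  b <- population_burden_series(conc, wt, 2007)
  expect_equal(b$normalized, c(1, 0.5, NA))
  expect_equal(b$x, 0:2)
  # weight doubling while conc halves: burden constant
  b2 <- population_burden_series(
    data.frame(year = 2007:2008, conc_ww = c(10, 5)),
    data.frame(year = 2007:2008, mass_g = c(1000, 2000)), 2007)
  expect_equal(b2$normalized, c(1, 1))
  expect_error(population_burden_series(
    data.frame(year = 2008, conc_ww = 5),
    data.frame(year = 2008, mass_g = 100), 2007), "t0")
})

test_that("decay fit recovers noiseless exponentials exactly", {
  x <- 2:8
  y <- 2 * exp(-0.3 * x)
  fit <- fit_exponential_decay(x, y)
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$k, 0.3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n, 7)
  # constant series: degenerate flag, k = 0
  fc <- fit_exponential_decay(x, rep(0.8, 7))
  expect_true(fc$degenerate)
  expect_equal(fc$k, 0)
  # start_offset excludes early points
  y2 <- c(5, 5, 2 * exp(-0.3 * (2:8)))
  f2 <- fit_exponential_decay(c(0, 1, 2:8), y2)
  expect_equal(f2$k, 0.3, tolerance = 1e-9)
  expect_error(fit_exponential_decay(2:3, c(1, 0.5)), "insufficient")
  expect_warning(fit_exponential_decay(c(2:8, 9), c(y, 0)), "non-positive")
})

test_that("time_to_fraction inverts the fitted model", {
  expect_equal(as.numeric(time_to_fraction(list(a = 1, k = 0.2), 0.5)),
               log(2) / 0.2)
  set.seed(20)
  for (i in 1:50) {
    a <- runif(1, 0.3, 3); k <- runif(1, 0.05, 1); f <- runif(1, 0.05, 0.95)
    t <- as.numeric(time_to_fraction(list(a = a, k = k), f))
    expect_equal(a * exp(-k * t), f, tolerance = 1e-12)
  }
  # below threshold at x = 0: negative analytic root, flagged
  t <- time_to_fraction(list(a = 0.4, k = 0.3), 0.5)
  expect_lt(as.numeric(t), 0)
  expect_true(attr(t, "below_at_start"))
  expect_error(time_to_fraction(list(a = 1, k = 0), 0.5), "positive")
})

test_that("burden pipeline is unit-scale invariant end to end", {
  conc <- data.frame(year = 2007:2015,
                     conc_ww = 10 * exp(-0.25 * (0:8)) + 0.3)
  wt <- data.frame(year = 2007:2015, mass_g = seq(900, 1100, length.out = 9))
  b_ng <- population_burden_series(conc, wt, 2007)
  conc_ug <- conc; conc_ug$conc_ww <- conc_ug$conc_ww / 1000  # ug/g
  b_ug <- population_burden_series(conc_ug, wt, 2007)
  expect_equal(b_ng$normalized, b_ug$normalized, tolerance = 1e-12)
  f1 <- fit_exponential_decay(b_ng$x, b_ng$normalized)
  f2 <- fit_exponential_decay(b_ug$x, b_ug$normalized)
  expect_equal(f1$k, f2$k, tolerance = 1e-9)
})

test_that("individual trajectories never mix fish and need a t0 capture", {
  fish <- rbind(
    make_fish("northern_pike", 2007, 500, 100, fish_id = "A", mass_g = 800),
    make_fish("northern_pike", 2009, 520, 60, fish_id = "A", mass_g = 900),
    make_fish("northern_pike", 2009, 450, 50, fish_id = "B", mass_g = 700),
    make_fish("northern_pike", 2007, 480, 90, fish_id = "C", mass_g = 750))
  tr <- individual_burden_trajectories(fish, t0_year = 2007)
  # B lacks a t0 capture, C lacks a recapture: only A qualifies
  expect_equal(unique(tr$fish_id), "A")
  expect_equal(tr$normalized[tr$year == 2007], 1)
  expect_equal(tr$normalized[tr$year == 2009],
               (60 * 0.2 * 900) / (100 * 0.2 * 800))
})
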