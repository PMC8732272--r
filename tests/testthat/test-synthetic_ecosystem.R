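# One quick noiseless simulation shared by several blocks (generated once;
# reduced recruitment and burn-in keep the suite fast).
quiet_sim <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- simulate_ecosystem(quick_config(obs_noise_cv = 0),
                                               seed = 101)
    ds
  }
})

test_that("config validation rejects invalid parameterizations", {
  expect_error(sim_config(water_loss_rate = 0.9, water_to_sediment = 0.2),
               "sum below 1")
  expect_error(sim_config(methylation_yield = 1.5), "methylation_yield")
  dem <- default_demography(); dem$northern_pike$mortality <- 1
  expect_error(sim_config(demography = dem), "mortality")
  up <- default_uptake(); up$yellow_perch$diet <- c(zooplankton = 0.5)
  expect_error(sim_config(uptake = up), "sum to 1")
})

test_that("zero lake loading yields identically zero lake-spike everywhere", {
  cfg <- quick_config(obs_noise_cv = 0, lake_load_rate = 0,
                      upland_fraction = 0, wetland_fraction = 0)
  ds <- simulate_ecosystem(cfg, seed = 5)
  for (col in c("conc_lake_spike", "conc_upland_spike", "conc_wetland_spike")) {
    expect_identical(unique(ds$samples[[col]]), 0)
    expect_identical(unique(ds$fish[[col]]), 0)
  }
})

test_that("identical seeds give byte-identical datasets; seeds matter", {
  cfg <- quick_config()
  d1 <- simulate_ecosystem(cfg, seed = 42)
  d2 <- simulate_ecosystem(cfg, seed = 42)
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$fish, d2$fish)
  expect_identical(attr(d1, "ledger"), attr(d2, "ledger"))
  d3 <- simulate_ecosystem(cfg, seed = 43)
  expect_false(identical(d1$fish, d3$fish))
  # byte-identical on disk
  p1 <- file.path(tempdir(), "det1"); p2 <- file.path(tempdir(), "det2")
  write_hg_dataset(d1, p1); write_hg_dataset(d2, p2)
  expect_identical(readLines(file.path(p1, "fish.csv")),
                   readLines(file.path(p2, "fish.csv")))
})

test_that("spike mass balance closes each year to 1e-9 relative", {
  ds <- quiet_sim()
  audit <- spike_mass_balance(ds, tol = 1e-9)
  expect_lt(max(audit$rel_imbalance), 1e-9)
  # independent re-summation of the ledger identity
  led <- attr(ds, "ledger")
  led <- led[led$channel == "lake_spike", ]
  expect_equal(led$added_cum_ug,
               led$water_ug + led$sediment_ug + led$fish_ug +
                 led$losses_cum_ug,
               tolerance = 1e-12)
  # additions stop after the last addition year
  expect_equal(diff(led$added_cum_ug[led$year >= 2007]),
               rep(0, sum(led$year >= 2007) - 1))
})

test_that("pools and burdens are non-negative and ambient is stationary", {
  ds <- quiet_sim()
  led <- attr(ds, "ledger")
  expect_true(all(led$water_ug >= 0 & led$sediment_ug >= 0 &
                    led$fish_ug >= 0 & led$losses_cum_ug >= 0))
  for (col in paste0("conc_", hg_channels())) {
    expect_true(all(ds$samples[[col]] >= 0))
    expect_true(all(ds$fish[[col]] >= 0))
  }
  # ambient compartment truth is constant to within the tiny fish draw
  tr <- attr(ds, "truth")
  amb <- tr[tr$channel == "ambient", ]
  expect_lt(diff(range(amb$water_ng_L)) / mean(amb$water_ng_L), 0.02)
  expect_lt(diff(range(amb$sediment_ng_g)) / mean(amb$sediment_ng_g), 0.02)
})

test_that("generate_decay_series is exact, seeded and unbiased", {
  x <- 2:8
  s0 <- generate_decay_series(2, 0.3, 0, x, seed = 1)
  expect_equal(s0$y, 2 * exp(-0.3 * x))
  s1 <- generate_decay_series(2, 0.3, 0.2, x, seed = 9)
  s2 <- generate_decay_series(2, 0.3, 0.2, x, seed = 9)
  expect_identical(s1, s2)
  expect_error(generate_decay_series(2, 0.3, -0.1), "noise_cv")
  # law of large numbers at one grid point over 1000 seeds
  y3 <- vapply(1:1000, function(s)
    generate_decay_series(2, 0.3, 0.1, x = 3, seed = s)$y, numeric(1))
  truth <- 2 * exp(-0.9)
  se <- sd(y3) / sqrt(length(y3))
  expect_lt(abs(mean(y3) - truth), 3 * se + 1e-12)
})

test_that("calibrated defaults reproduce the configured compartment declines", {
  # configured-behaviour regression, not a scientific claim: the default
  # rate constants were calibrated once to 3-year post-cessation declines
  # of ~81% (water) and ~35% (sediment), with invertebrates intermediate
  ds <- simulate_ecosystem(sim_config(obs_noise_cv = 0), seed = 1)
  tr <- attr(ds, "truth")
  spike <- tr[tr$channel == "lake_spike", ]
  r3 <- function(col) spike[[col]][spike$year == 2010] /
    spike[[col]][spike$year == 2007]
  expect_equal(r3("water_ng_L"), 0.19, tolerance = 0.05)
  expect_equal(r3("sediment_ng_g"), 0.65, tolerance = 0.05)
  expect_equal(r3("zooplankton_dw"), 0.34, tolerance = 0.06)
  expect_equal(r3("chaoborus_dw"), 0.33, tolerance = 0.06)
  # t0 per cent increases near the configured 60% (water) / 30% (sediment)
  amb <- tr[tr$channel == "ambient", ]
  pw <- 100 * spike$water_ng_L[spike$year == 2007] /
    amb$water_ng_L[amb$year == 2007]
  ps <- 100 * spike$sediment_ng_g[spike$year == 2007] /
    amb$sediment_ng_g[amb$year == 2007]
  expect_equal(pw, 60, tolerance = 0.05)
  expect_equal(ps, 30, tolerance = 0.05)
  # wetland spike sits below the 0.5%-of-ambient detection limit in fish
  f <- ds$fish[ds$fish$conc_ambient > 0, ]
  expect_true(all(f$conc_wetland_spike < 0.005 * f$conc_ambient))
})
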