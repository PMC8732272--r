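test_that("percent_increase matches the definition and is scale invariant", {
  expect_equal(percent_increase(2, 2), 100)
  expect_equal(percent_increase(0, 5), 0)
  expect_equal(percent_increase(1.2, 2), 60)
  expect_error(percent_increase(1, 0), "ambient")
  expect_error(percent_increase(-1, 2), "non-negative")
  set.seed(1)
  cs <- runif(100, 0, 10); ca <- runif(100, 0.1, 10)
  lam <- runif(100, 0.01, 100)
  expect_equal(percent_increase(lam * cs, lam * ca),
               percent_increase(cs, ca))
})

test_that("bmf is log10(pred/prey) with chain additivity and antisymmetry", {
  expect_equal(bmf(10, 1), 1)
  expect_equal(bmf(7.7, 7.7), 0)
  expect_equal(bmf(3.9, 1), log10(3.9))
  expect_error(bmf(0, 1), "positive")
  expect_error(bmf(5, 0), "positive")
  set.seed(2)
  a <- runif(200, 0.01, 100); b <- runif(200, 0.01, 100)
  cc <- runif(200, 0.01, 100)
  expect_equal(bmf(a, cc), bmf(a, b) + bmf(b, cc))
  expect_equal(bmf(a, b), -bmf(b, a))
})

test_that("prey_exposure_mean averages the open-water season wet basis", {
  zoo <- make_samples("zooplankton", c("2005-06-15", "2005-08-15"),
                      conc_ambient = c(4, 6))
  ds <- hg_dataset(zoo, make_fish("yellow_perch", 2005, 80, 1)[0, ])
  # dry-basis {4, 6} -> mean 5 -> x0.15 wet
  expect_equal(prey_exposure_mean(ds, "yellow_perch", 2005, "ambient"),
               5 * 0.15)
  # samples only in year y-1 -> missing for year y
  expect_true(is.na(prey_exposure_mean(ds, "yellow_perch", 2006, "ambient")))
  # single sample -> that value
  one <- hg_dataset(zoo[1, ], ds$fish)
  expect_equal(prey_exposure_mean(one, "yellow_perch", 2005, "ambient"),
               4 * 0.15)
  # forage-fish pool: wet basis from individual dw proportions
  ff <- rbind(make_fish("yellow_perch", 2005, 80, conc_lake_spike = 10,
                        dw_proportion = 0.2),
              make_fish("blacknose_shiner", 2005, 60, conc_lake_spike = 30,
                        dw_proportion = 0.2))
  ds2 <- hg_dataset(zoo, ff)
  expect_equal(prey_exposure_mean(ds2, "northern_pike", 2005, "lake_spike"),
               mean(c(10, 30)) * 0.2)
})

test_that("phase_trend_test matches the closed-form OLS oracle", {
  # exactly linear series: slope 1, p below machine level
  r <- phase_trend_test(2001:2005, 1:5)
  expect_equal(r$slope, 1)
  expect_lt(r$p_value, 1e-12)
  expect_false(r$degenerate)
  # constant series: degenerate, slope 0
  r <- phase_trend_test(2001:2005, rep(3, 5))
  expect_equal(r$slope, 0)
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
  expect_error(phase_trend_test(2001:2002, 1:2), "at least 3")

  # closed-form t-test oracle on a noisy series
  set.seed(3)
  x <- 2001:2008
  y <- 0.2 * (x - 2000) + rnorm(8)
  r <- phase_trend_test(x, y)
  xc <- x - mean(x)
  bhat <- sum(xc * y) / sum(xc^2)
  ahat <- mean(y) - bhat * mean(x)
  rss <- sum((y - ahat - bhat * x)^2)
  se <- sqrt(rss / (8 - 2) / sum(xc^2))
  p_oracle <- 2 * pt(abs(bhat / se), df = 6, lower.tail = FALSE)
  expect_equal(r$slope, bhat)
  expect_equal(r$p_value, p_oracle)
})

# minimal permutation enumerator used only by the test below
combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in combinat_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

test_that("phase_trend_test p matches an exact permutation null", {
  set.seed(4)
  x <- 2001:2006
  y <- rnorm(6) + 0.3 * seq_len(6)
  r <- phase_trend_test(x, y)
  # enumerate all 720 permutations: exact permutation p for |slope|
  xc <- x - mean(x)
  slope <- function(yy) sum(xc * yy) / sum(xc^2)
  obs <- abs(slope(y))
  perms <- rbind(y, do.call(rbind, combinat_perms(y)))
  stats <- abs(apply(perms, 1, slope))
  p_perm <- mean(stats >= obs - 1e-12)
  expect_lt(abs(r$p_value - p_perm), 0.1)
})

test_that("annual_percent_increase honours both aggregation methods", {
  s <- rbind(
    make_samples("water", c("2005-06-15", "2005-08-15"),
                 conc_ambient = c(2, 4), conc_lake_spike = c(1, 1)),
    make_samples("water", "2005-12-15", conc_ambient = 100,
                 conc_lake_spike = 100))
  ds <- hg_dataset(s, make_fish("northern_pike", 2005, 500, 10)[0, ])
  rom <- annual_percent_increase(ds, "water", method = "ratio_of_means")
  expect_equal(rom$percent_increase[rom$year == 2005], 100 * 1 / 3)
  mor <- annual_percent_increase(ds, "water", method = "mean_of_ratios")
  expect_equal(mor$percent_increase[mor$year == 2005], mean(c(50, 25)))
  # fish default: mean of individual ratios
  fh <- make_fish("northern_pike", 2005, c(400, 500),
                  conc_lake_spike = c(100, 300), conc_ambient = c(200, 300))
  ds2 <- hg_dataset(s[0, ], fh)
  r <- annual_percent_increase(ds2, "northern_pike")
  expect_equal(r$percent_increase[r$year == 2005], mean(c(50, 100)))
})
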