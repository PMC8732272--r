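test_that("length-concentration fit recovers known polynomial truth", {
  set.seed(10)
  fl <- seq(300, 700, length.out = 12)
  truth <- c(2, 0.01, 1e-5)
  conc <- truth[1] + truth[2] * fl + truth[3] * fl^2
  fit <- fit_length_concentration(fl, conc, "quadratic")
  expect_equal(fit$coefficients, poly_oracle(fl, conc, 2), tolerance = 1e-8)
  expect_equal(fit$coefficients, truth, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-16)
  # constant concentrations: intercept c, higher coefficients ~ 0
  fitc <- fit_length_concentration(fl, rep(5.5, 12), "quadratic")
  expect_equal(as.numeric(standardized_concentration(fitc, 475)), 5.5)
  # sample-size ladder
  expect_error(fit_length_concentration(fl[1:3], conc[1:3], "quadratic"),
               "insufficient")
  expect_error(fit_length_concentration(fl[1:2], conc[1:2], "linear"),
               "insufficient")
  expect_error(fit_length_concentration(rep(500, 6), runif(6), "quadratic"),
               "singular")
})

test_that("standardized_concentration evaluates and back-transforms", {
  fl <- seq(350, 650, by = 50)
  cf <- c(1.5, 0.004, 2e-6)
  conc <- cf[1] + cf[2] * fl + cf[3] * fl^2
  fit <- fit_length_concentration(fl, conc, "quadratic")
  expect_equal(as.numeric(standardized_concentration(fit, 475)),
               cf[1] + 475 * cf[2] + 475^2 * cf[3], tolerance = 1e-8)
  # sqrt-transform truth: sqrt(conc) = 0.01 * FL -> conc(500) = 25
  conc_s <- (0.01 * fl)^2
  fit_s <- fit_length_concentration(fl, conc_s, "quadratic",
                                    transform = "sqrt")
  expect_equal(as.numeric(standardized_concentration(fit_s, 500)), 25,
               tolerance = 1e-8)
  # negative raw prediction floored with a warning flag
  fit_n <- fit_length_concentration(c(100, 200, 300, 400),
                                    c(40, 25, 12, 1), "linear")
  expect_warning(v <- standardized_concentration(fit_n, 450), "floored")
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "floored"))
})

test_that("standardized_weight recovers quadratic mass truth", {
  fl <- seq(300, 700, by = 50)
  mass <- 10 + 0.5 * fl + 0.003 * fl^2
  expect_equal(standardized_weight(fl, mass, 475),
               10 + 0.5 * 475 + 0.003 * 475^2, tolerance = 1e-8)
  expect_equal(standardized_weight(fl, rep(800, length(fl)), 530), 800,
               tolerance = 1e-8)
  expect_error(standardized_weight(fl[1:2], mass[1:2], 475), "insufficient")
})

test_that("standardization is permutation/duplication invariant and mean-exact", {
  set.seed(11)
  for (case in 1:10) {
    fl <- runif(15, 300, 800)
    conc <- 50 + 0.05 * fl + rnorm(15, sd = 3)
    f1 <- fit_length_concentration(fl, conc, "quadratic")
    idx <- sample(15)
    f2 <- fit_length_concentration(fl[idx], conc[idx], "quadratic")
    expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
    f3 <- fit_length_concentration(c(fl, fl), c(conc, conc), "quadratic")
    expect_equal(f1$coefficients, f3$coefficients, tolerance = 1e-9)
    # conc independent of FL: standardized value ~ sample mean
    conc_flat <- rnorm(15, 20, 2)
    ff <- fit_length_concentration(fl, conc_flat, "quadratic")
    # quadratic fit of noise is not the mean; the linear-free case is
    fm <- fit_length_concentration(fl, rep(mean(conc_flat), 15), "quadratic")
    expect_equal(as.numeric(standardized_concentration(fm, 475)),
                 mean(conc_flat), tolerance = 1e-8)
    # nesting: linear rss >= quadratic rss on the same data
    fq <- fit_length_concentration(fl, conc, "quadratic")
    fli <- fit_length_concentration(fl, conc, "linear")
    expect_gte(fli$rss + 1e-12, fq$rss)
  }
})

test_that("standardize_annual falls back quadratic -> linear -> mean", {
  fish <- rbind(
    make_fish("northern_pike", 2007, c(400, 450, 500, 550, 600),
              conc_lake_spike = c(100, 120, 150, 160, 180)),
    make_fish("northern_pike", 2008, c(420, 470, 520),
              conc_lake_spike = c(90, 100, 110)),
    make_fish("northern_pike", 2009, c(480, 490),
              conc_lake_spike = c(80, 85)))
  s <- standardize_annual(fish, "northern_pike", "lake_spike")
  expect_equal(s$fit_model[s$year == 2007], "quadratic")
  expect_equal(s$fit_model[s$year == 2008], "linear")
  expect_equal(s$fit_model[s$year == 2009], "mean")
  expect_true(is.na(s$conc_ww[s$year == 2010]))
  expect_equal(s$conc_ww[s$year == 2009], mean(c(80, 85)) * 0.2)
  # pike default transform is sqrt: check against an explicit fit
  fy <- fish[fish$date == "2007-09-15", ]
  f <- fit_length_concentration(fy$fork_length_mm,
                                fy$conc_lake_spike * fy$dw_proportion,
                                "quadratic", transform = "sqrt")
  expect_equal(s$conc_ww[s$year == 2007],
               as.numeric(standardized_concentration(f, 475)))
})

test_that("standard fork lengths default to the species means", {
  expect_equal(standard_fork_length("northern_pike"), 475)
  expect_equal(standard_fork_length("lake_whitefish"), 530)
  expect_error(standard_fork_length("yellow_perch"), "no standard")
})
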