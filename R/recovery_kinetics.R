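# Body burdens, normalisation to the end of additions, exponential-decay
# regression of the population series and time-to-fraction estimation.

#' Whole-body tracer burden
#'
#' Relative whole-body MeHg content: muscle concentration (ng/g wet weight)
#' times body mass (g), in ng.
#'
#' @param conc_ww Concentration, ng/g ww; non-negative.
#' @param mass_g Body mass, g; positive.
#' @return Burden in ng.
#' @examples
#' body_burden(100, 1000)  # 1e5 ng
#' @export
body_burden <- function(conc_ww, mass_g) {
  if (any(!is.na(mass_g) & mass_g <= 0))
    stop("mass_g must be positive", call. = FALSE)
  if (any(!is.na(conc_ww) & conc_ww < 0))
    stop("conc_ww must be non-negative", call. = FALSE)
  conc_ww * mass_g
}

#' Burden normalised to the end of additions
#'
#' Proportion of the original (t0, autumn of the final addition year)
#' burden still present: `burden_t / burden_t0`.  Values above 1 are
#' legitimate early in recovery.
#'
#' @param burden_t Burden at time t (ng).
#' @param burden_t0 Burden at t0 (ng); strictly positive.
#' @return Dimensionless fraction of the t0 burden.
#' @export
normalize_burden <- function(burden_t, burden_t0) {
  if (any(!is.na(burden_t0) & burden_t0 <= 0))
    stop("burden_t0 must be positive to normalize", call. = FALSE)
  burden_t / burden_t0
}

#' Population burden series from standardised series
#'
#' Combines per-year standardised concentrations with per-year standardised
#' body weights into a population burden series, normalised to the t0 year.
#'
#' @param conc_series Data frame `year`, `conc_ww` (or `value`), ng/g ww.
#' @param weight_series Data frame `year`, `mass_g` (or `value`), g.
#' @param t0_year Reference year (final addition year).
#' @return Data frame `year`, `x` (years since t0), `burden_ng`,
#'   `normalized`; missing years propagate as `NA`.
#' @export
population_burden_series <- function(conc_series, weight_series, t0_year) {
  cval <- if ("conc_ww" %in% names(conc_series)) conc_series$conc_ww
          else conc_series$value
  wval <- if ("mass_g" %in% names(weight_series)) weight_series$mass_g
          else weight_series$value
  years <- sort(union(conc_series$year, weight_series$year))
  conc <- cval[match(years, conc_series$year)]
  wt <- wval[match(years, weight_series$year)]
  burden <- ifelse(is.na(conc) | is.na(wt), NA_real_,
                   body_burden(conc, wt))
  i0 <- match(t0_year, years)
  if (is.na(i0) || is.na(burden[i0]) || burden[i0] <= 0)
    stop("t0 year ", t0_year, " burden missing or non-positive; ",
         "cannot normalize", call. = FALSE)
  data.frame(year = years, x = years - t0_year, burden_ng = burden,
             normalized = normalize_burden(burden, burden[i0]))
}

#' Fit an exponential decay to a normalised burden series
#'
#' Nonlinear least squares of `y = a * exp(-k * x)` on the untransformed
#' normalised burdens, using points with `x >= start_offset` (burden-loss
#' regression conventionally starts in the second recovery year because
#' burdens often rise first).  The fit is initialised by log-linear OLS;
#' non-positive y among the fitted points are excluded with a warning.
#' Goodness of fit is reported on the untransformed scale:
#' `R^2 = 1 - RSS/TSS`, regression F with (1, n-2) df and its p-value.
#'
#' @param x Years since t0.
#' @param y Normalised burdens (fraction of t0 burden).
#' @param start_offset Fit only points with `x >= start_offset`; default 2.
#' @return An object of class `hg_decayfit`: `a`, `k` (per year),
#'   `r_squared`, `f_stat`, `p_value`, `n`, `start_offset`, `se_a`, `se_k`
#'   (classical), `se_a_robust`, `se_k_robust` (HC3 sandwich, appropriate
#'   under multiplicative noise), `degenerate`.
#' @export
fit_exponential_decay <- function(x, y, start_offset = 2) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y) & x >= start_offset
  if (any(keep & y <= 0)) {
    warning("excluding ", sum(keep & y <= 0),
            " non-positive burden value(s) from the decay fit")
    keep <- keep & y > 0
  }
  xs <- as.numeric(x[keep])
  ys <- as.numeric(y[keep])
  n <- length(ys)
  if (n < 3)
    stop("insufficient data: decay fit needs >= 3 usable points", call. = FALSE)
  tss <- sum((ys - mean(ys))^2)
  if (tss <= .Machine$double.eps * max(1, sum(ys^2))) {
    # constant series: no decline to fit
    return(structure(list(a = mean(ys), k = 0, r_squared = NA_real_,
                          f_stat = NA_real_, p_value = NA_real_, n = n,
                          start_offset = start_offset, se_a = NA_real_,
                          se_k = NA_real_, se_a_robust = NA_real_,
                          se_k_robust = NA_real_, degenerate = TRUE),
                     class = "hg_decayfit"))
  }
  init <- lm(log(ys) ~ xs)
  start <- list(a = exp(unname(coef(init)[1])), k = -unname(coef(init)[2]))
  # scaleOffset makes the convergence test valid for zero-residual data
  fit <- nls(ys ~ a * exp(-k * xs), start = start,
             control = nls.control(maxiter = 500, scaleOffset = 1))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    c(a = NA_real_, k = NA_real_))
  # burden series carry multiplicative (heteroscedastic) noise, for which
  # the classical nls covariance is anti-conservative; also report HC3
  # sandwich standard errors for normal-approximation intervals
  rob <- tryCatch({
    G <- cbind(exp(-cf[["k"]] * xs), -cf[["a"]] * xs * exp(-cf[["k"]] * xs))
    r <- ys - cf[["a"]] * exp(-cf[["k"]] * xs)
    bread <- solve(t(G) %*% G)
    h <- pmin(diag(G %*% bread %*% t(G)), 0.999)
    V <- bread %*% t(G) %*% (G * (r^2 / (1 - h)^2)) %*% bread
    sqrt(pmax(diag(V), 0))
  }, error = function(e) c(NA_real_, NA_real_))
  rss <- sum((ys - cf[["a"]] * exp(-cf[["k"]] * xs))^2)
  r2 <- 1 - rss / tss
  fstat <- if (rss > 0) ((tss - rss) / 1) / (rss / (n - 2)) else Inf
  pval <- if (is.finite(fstat)) pf(fstat, 1, n - 2, lower.tail = FALSE) else 0
  structure(list(a = unname(cf[["a"]]), k = unname(cf[["k"]]),
                 r_squared = r2, f_stat = fstat, p_value = pval, n = n,
                 start_offset = start_offset,
                 se_a = unname(se[["a"]]), se_k = unname(se[["k"]]),
                 se_a_robust = rob[1], se_k_robust = rob[2],
                 degenerate = FALSE),
            class = "hg_decayfit")
}

#' @export
print.hg_decayfit <- function(x, ...) {
  cat("<hg_decayfit> y = ", signif(x$a, 5), " * exp(-", signif(x$k, 5),
      " x), n = ", x$n, "\n", sep = "")
  if (!x$degenerate)
    cat("  R^2 = ", signif(x$r_squared, 3), ", F(1,", x$n - 2, ") = ",
        signif(x$f_stat, 4), ", p = ", signif(x$p_value, 3), "\n", sep = "")
  else cat("  degenerate (constant series)\n")
  invisible(x)
}

#' Time until the burden reaches a fraction of the original
#'
#' Solves `fraction = a * exp(-k t)` analytically:
#' `t = log(a / fraction) / k`, in years since t0.  The fraction refers to
#' the original (t0) burden, i.e. the normalised y itself.  If the fitted
#' curve starts below the requested fraction the (negative) analytic root
#' is returned with attribute `below_at_start = TRUE`.
#'
#' @param fit An `hg_decayfit`, or a list/vector with elements `a` and `k`.
#' @param fraction Target fraction of the t0 burden, in (0, 1]; default 0.5
#'   (the population half-life).
#' @return Years since t0, with attribute `below_at_start`.
#' @examples
#' fit <- list(a = 1, k = log(2))
#' time_to_fraction(fit, 0.5)  # 1 year
#' @export
time_to_fraction <- function(fit, fraction = 0.5) {
  a <- fit[["a"]]
  k <- fit[["k"]]
  stopifnot(is.numeric(a), is.numeric(k), is.numeric(fraction),
            fraction > 0)
  if (k <= 0)
    stop("decay rate k must be positive: no decline, time undefined",
         call. = FALSE)
  t <- log(a / fraction) / k
  structure(t, below_at_start = t < 0)
}

#' Individual recovery trajectories for recaptured fish
#'
#' Normalised spike burden trajectories for individual tagged fish that
#' were captured in the t0 year and recaptured at least once afterwards.
#' Burdens use each fish's own measured concentration and mass; each
#' trajectory is normalised to that fish's own t0 burden.  Fish lacking a
#' t0 capture are excluded.
#'
#' @param fish Fish observation data frame with `fish_id`.
#' @param species Species (default `northern_pike`).
#' @param channel Spike channel.
#' @param t0_year Final addition year.
#' @return Data frame `fish_id`, `year`, `x`, `burden_ng`, `normalized`.
#' @export
individual_burden_trajectories <- function(fish, species = "northern_pike",
                                           channel = "lake_spike",
                                           t0_year = 2007) {
  channel <- match.arg(channel, hg_channels())
  fish <- fish_wet_concentrations(fish)
  col <- paste0("conc_", channel, "_ww")
  date <- as.Date(fish$date)
  fish$year <- as.integer(format(date, "%Y"))
  keep <- fish$species == species & !is.na(fish$fish_id) &
    fish$fish_id != "" & !is.na(fish[[col]]) & !is.na(fish$mass_g)
  fish <- fish[keep, , drop = FALSE]
  out <- list()
  for (id in unique(fish$fish_id)) {
    fi <- fish[fish$fish_id == id, , drop = FALSE]
    fi <- fi[order(fi$year), , drop = FALSE]
    i0 <- match(t0_year, fi$year)
    if (is.na(i0) || !any(fi$year > t0_year)) next
    b <- body_burden(fi[[col]], fi$mass_g)
    if (b[i0] <= 0) next
    out[[id]] <- data.frame(fish_id = id, year = fi$year,
                            x = fi$year - t0_year, burden_ng = b,
                            normalized = normalize_burden(b, b[i0]),
                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(fish_id = character(), year = integer(), x = integer(),
                      burden_ng = numeric(), normalized = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
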