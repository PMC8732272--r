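# Per-year length standardisation of large-bodied fish MeHg and
# fork-length/body-weight standardisation.

#' Species standard fork lengths
#'
#' The standard fork length is the mean FL of all individuals sampled over
#' the study: 475 mm for northern pike, 530 mm for lake whitefish.
#'
#' @param species Species label.
#' @return Standard fork length in mm.
#' @export
standard_fork_length <- function(species) {
  std <- c(northern_pike = 475, lake_whitefish = 530)
  if (!species %in% names(std))
    stop("no standard fork length defined for ", species, call. = FALSE)
  unname(std[[species]])
}

#' Fit a length-concentration regression for one species-year
#'
#' Ordinary least-squares polynomial regression of (optionally square-root
#' transformed) wet-basis muscle MeHg on fork length.  The default model is
#' a quadratic polynomial; a linear fit is available for sparse years.
#' Northern pike concentrations require the square-root transform to
#' satisfy normality and homoscedasticity; prediction back-transforms by
#' squaring.
#'
#' @param fork_length_mm Fork lengths (mm).
#' @param conc_ww Wet-basis concentrations (ng/g); same length.
#' @param model `"quadratic"` (needs n >= 4) or `"linear"` (n >= 3).
#' @param transform `"none"` or `"sqrt"` (applied to the response).
#' @return An object of class `hg_lengthfit`: coefficients in ascending
#'   power order, `model`, `transform`, `n`, `rss`, and the observed FL
#'   range.
#' @export
fit_length_concentration <- function(fork_length_mm, conc_ww,
                                     model = c("quadratic", "linear"),
                                     transform = c("none", "sqrt")) {
  model <- match.arg(model)
  transform <- match.arg(transform)
  keep <- !is.na(fork_length_mm) & !is.na(conc_ww)
  fl <- as.numeric(fork_length_mm[keep])
  y <- as.numeric(conc_ww[keep])
  n <- length(y)
  n_min <- if (model == "quadratic") 4L else 3L
  if (n < n_min)
    stop(sprintf("insufficient data: %s fit needs n >= %d, got %d",
                 model, n_min, n), call. = FALSE)
  if (length(unique(fl)) < (if (model == "quadratic") 3L else 2L))
    stop("fork lengths do not span enough distinct values (singular design)",
         call. = FALSE)
  if (transform == "sqrt") {
    if (any(y < 0)) stop("sqrt transform requires non-negative concentrations",
                         call. = FALSE)
    y <- sqrt(y)
  }
  fit <- if (model == "quadratic") lm(y ~ fl + I(fl^2)) else lm(y ~ fl)
  cf <- unname(coef(fit))
  if (model == "linear") cf <- c(cf, 0)
  structure(list(coefficients = cf, model = model, transform = transform,
                 n = n, rss = sum(residuals(fit)^2),
                 fl_range = range(fl)),
            class = "hg_lengthfit")
}

#' @export
print.hg_lengthfit <- function(x, ...) {
  cat("<hg_lengthfit> ", x$model,
      if (x$transform == "sqrt") " (sqrt response)", ", n = ", x$n,
      ", rss = ", signif(x$rss, 4), "\n  coefficients: ",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate a length fit at the standard fork length
#'
#' Evaluates the fitted polynomial at `standard_fl`; with a `sqrt`
#' transform the prediction is squared back to the concentration scale
#' (naive back-transform, no retransformation bias correction).  A negative
#' raw prediction on the untransformed scale is floored at 0 and flagged
#' via the `"floored"` attribute.
#'
#' @param fit An `hg_lengthfit`.
#' @param standard_fl Fork length (mm) at which to standardise; positive.
#' @return Standardised concentration (ng/g ww) with attribute `floored`.
#' @export
standardized_concentration <- function(fit, standard_fl) {
  stopifnot(inherits(fit, "hg_lengthfit"), standard_fl > 0)
  cf <- fit$coefficients
  pred <- cf[1] + cf[2] * standard_fl + cf[3] * standard_fl^2
  floored <- FALSE
  if (fit$transform == "sqrt") {
    pred <- pred^2
  } else if (pred < 0) {
    warning("negative standardized concentration floored at 0")
    pred <- 0
    floored <- TRUE
  }
  structure(pred, floored = floored)
}

#' Body weight at the standard fork length
#'
#' Quadratic OLS of body mass on fork length for one species-year,
#' evaluated at the standard FL.
#'
#' @param fork_length_mm Fork lengths (mm).
#' @param mass_g Body masses (g); same length.
#' @param standard_fl Standard fork length (mm).
#' @return Predicted mass (g) at `standard_fl`.
#' @export
standardized_weight <- function(fork_length_mm, mass_g, standard_fl) {
  keep <- !is.na(fork_length_mm) & !is.na(mass_g)
  fl <- as.numeric(fork_length_mm[keep])
  m <- as.numeric(mass_g[keep])
  if (length(m) < 4)
    stop("insufficient data: quadratic FL-weight fit needs n >= 4",
         call. = FALSE)
  if (length(unique(fl)) < 3)
    stop("fork lengths do not span enough distinct values (singular design)",
         call. = FALSE)
  fit <- lm(m ~ fl + I(fl^2))
  cf <- unname(coef(fit))
  cf[1] + cf[2] * standard_fl + cf[3] * standard_fl^2
}

#' Per-year standardised concentrations for one species
#'
#' For each year with observations, fits the length-concentration
#' regression and evaluates it at the species standard fork length.
#' Model choice follows a fallback ladder driven by sample size:
#' quadratic (n >= 4), else linear (n >= 3), else the annual mean, with the
#' applied model recorded per year in `fit_model`.  Northern pike uses the
#' square-root transform by default.
#'
#' @param fish Fish observation data frame (dry-basis concentrations).
#' @param species Species to standardise (`northern_pike` or
#'   `lake_whitefish` by default carry standard lengths).
#' @param channel Isotope channel.
#' @param standard_fl Standard fork length; default
#'   [standard_fork_length()] for the species.
#' @param transform Response transform; default `sqrt` for northern pike,
#'   `none` otherwise.
#' @param calendar A [study_calendar()].
#' @return Data frame with `year`, `conc_ww` (standardised, ng/g ww), `n`,
#'   `fit_model`, `rss`, `floored`.
#' @export
standardize_annual <- function(fish, species, channel = "lake_spike",
                               standard_fl = NULL, transform = NULL,
                               calendar = study_calendar()) {
  channel <- match.arg(channel, hg_channels())
  if (is.null(standard_fl)) standard_fl <- standard_fork_length(species)
  if (is.null(transform))
    transform <- if (species == "northern_pike") "sqrt" else "none"
  fish <- fish_wet_concentrations(fish)
  col <- paste0("conc_", channel, "_ww")
  date <- as.Date(fish$date)
  years <- all_years(calendar)
  out <- data.frame(year = years, conc_ww = NA_real_, n = 0L,
                    fit_model = NA_character_, rss = NA_real_,
                    floored = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(years)) {
    keep <- fish$species == species &
      as.integer(format(date, "%Y")) == years[i] &
      !is.na(fish[[col]]) & !is.na(fish$fork_length_mm)
    fl <- fish$fork_length_mm[keep]
    cc <- fish[[col]][keep]
    n <- length(cc)
    out$n[i] <- n
    if (n == 0) next
    fit <- NULL
    for (m in c("quadratic", "linear")) {
      fit <- tryCatch(
        fit_length_concentration(fl, cc, model = m, transform = transform),
        error = function(e) NULL)
      if (!is.null(fit)) { out$fit_model[i] <- m; break }
    }
    if (is.null(fit)) {
      out$conc_ww[i] <- mean(cc)
      out$fit_model[i] <- "mean"
      next
    }
    v <- standardized_concentration(fit, standard_fl)
    out$conc_ww[i] <- as.numeric(v)
    out$rss[i] <- fit$rss
    out$floored[i] <- isTRUE(attr(v, "floored"))
  }
  out
}

#' Per-year body weight at the standard fork length
#'
#' @inheritParams standardize_annual
#' @return Data frame `year`, `mass_g`, `n`.
#' @export
standardize_weight_annual <- function(fish, species, standard_fl = NULL,
                                      calendar = study_calendar()) {
  if (is.null(standard_fl)) standard_fl <- standard_fork_length(species)
  date <- as.Date(fish$date)
  years <- all_years(calendar)
  out <- data.frame(year = years, mass_g = NA_real_, n = 0L)
  for (i in seq_along(years)) {
    keep <- fish$species == species &
      as.integer(format(date, "%Y")) == years[i] &
      !is.na(fish$fork_length_mm) & !is.na(fish$mass_g)
    fl <- fish$fork_length_mm[keep]
    m <- fish$mass_g[keep]
    out$n[i] <- length(m)
    if (length(m) == 0) next
    w <- tryCatch(standardized_weight(fl, m, standard_fl),
                  error = function(e) NULL)
    out$mass_g[i] <- if (is.null(w)) mean(m) else w
  }
  out
}
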