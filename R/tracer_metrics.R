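# Tracer statistics: per cent increase, biomagnification factors,
# prey-exposure averaging and phase trend tests.

#' Per cent increase of spike over ambient MeHg
#'
#' The relative change in MeHg caused by the experimental loading:
#' `100 * spike / ambient`, computed on matched concentrations (same sample
#' or same annual mean).
#'
#' @param spike_conc Spike-channel concentration(s); non-negative.
#' @param ambient_conc Ambient concentration(s); strictly positive.
#' @return Per cent increase(s).
#' @examples
#' percent_increase(1.2, 2.0)  # 60
#' @export
percent_increase <- function(spike_conc, ambient_conc) {
  if (!is.numeric(spike_conc) || !is.numeric(ambient_conc))
    stop("inputs must be numeric", call. = FALSE)
  if (any(!is.na(ambient_conc) & ambient_conc <= 0))
    stop("ambient_conc must be positive", call. = FALSE)
  if (any(!is.na(spike_conc) & spike_conc < 0))
    stop("spike_conc must be non-negative", call. = FALSE)
  100 * spike_conc / ambient_conc
}

#' Biomagnification factor
#'
#' `log10` of the predator-to-prey MeHg concentration ratio, both wet basis.
#' Spike concentrations censored to zero have no defined BMF and must be
#' passed as `NA` (the function refuses non-positive inputs rather than
#' returning `-Inf`).
#'
#' @param pred_conc Predator concentration(s), ng/g ww; positive.
#' @param prey_conc Prey concentration(s), ng/g ww; positive.
#' @return `log10(pred/prey)`; `NA` where either input is `NA`.
#' @examples
#' bmf(10, 1)   # 1
#' bmf(3.9, 1)  # ~0.591
#' @export
bmf <- function(pred_conc, prey_conc) {
  if (!is.numeric(pred_conc) || !is.numeric(prey_conc))
    stop("inputs must be numeric", call. = FALSE)
  if (any(!is.na(pred_conc) & pred_conc <= 0) ||
      any(!is.na(prey_conc) & prey_conc <= 0))
    stop("BMF requires positive concentrations; censored-to-zero values ",
         "must be passed as NA", call. = FALSE)
  log10(pred_conc / prey_conc)
}

#' Default predator-to-prey mapping
#'
#' Dominant prey item per predator: age-1+ yellow perch eat zooplankton,
#' northern pike eat forage fishes (young-of-year and age-1+ perch plus
#' blacknose shiner, pooled), lake whitefish eat *Chaoborus*.
#'
#' @return Named list mapping predator species to a prey descriptor.
#' @export
prey_map <- function() {
  list(yellow_perch = "zooplankton",
       northern_pike = "forage_fish",
       lake_whitefish = "chaoborus")
}

#' Mean prey MeHg exposure for one year
#'
#' Wet-basis mean prey concentration over the open-water season of the
#' given calendar year (the season immediately preceding autumn fish
#' sampling).  Invertebrate prey are converted dry-to-wet with the standard
#' 0.15 proportion; the forage-fish pool averages individual wet-basis
#' muscle concentrations of young-of-year and age-1+ yellow perch and
#' blacknose shiner, pooled unweighted.
#'
#' @param dataset An [hg_dataset()].
#' @param predator Predator species (a name of [prey_map()]).
#' @param year Calendar year.
#' @param channel Isotope channel.
#' @param calendar A [study_calendar()].
#' @return Mean prey concentration (ng/g ww), or `NA_real_` if no prey
#'   samples fall in the season.
#' @export
prey_exposure_mean <- function(dataset, predator, year, channel,
                               calendar = study_calendar()) {
  stopifnot(inherits(dataset, "hg_dataset"))
  channel <- match.arg(channel, hg_channels())
  prey <- prey_map()[[predator]]
  if (is.null(prey))
    stop("no prey mapping for predator: ", predator, call. = FALSE)
  if (prey == "forage_fish") {
    fish <- fish_wet_concentrations(dataset$fish)
    date <- as.Date(fish$date)
    keep <- fish$species %in% c("yellow_perch", "blacknose_shiner") &
      as.integer(format(date, "%Y")) == as.integer(year) &
      as.integer(format(date, "%m")) %in% calendar$open_water_months
    vals <- fish[[paste0("conc_", channel, "_ww")]][keep]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NA_real_)
    return(mean(vals))
  }
  m_dw <- open_water_annual_mean(dataset$samples, year, channel, calendar,
                                 compartment = prey)
  if (is.na(m_dw)) return(NA_real_)
  dry_to_wet(m_dw, INVERT_DW_PROPORTION)
}

#' Annual per cent increase series
#'
#' For water and sediment the annual per cent increase is the ratio of the
#' open-water annual mean spike concentration to the annual mean ambient
#' concentration (`method = "ratio_of_means"`).  For fish it is the mean of
#' individual-level spike/ambient ratios over the autumn sample
#' (`method = "mean_of_ratios"`), computed from raw (not size-standardised)
#' concentrations.
#'
#' @param dataset An [hg_dataset()].
#' @param target A compartment or fish species label.
#' @param channel Spike channel (default `lake_spike`).
#' @param calendar A [study_calendar()].
#' @param method Aggregation method; defaults depend on whether `target`
#'   is a compartment or a species.
#' @return Data frame with columns `year`, `percent_increase`, `n`.
#' @export
annual_percent_increase <- function(dataset, target,
                                    channel = "lake_spike",
                                    calendar = study_calendar(),
                                    method = NULL) {
  stopifnot(inherits(dataset, "hg_dataset"))
  channel <- match.arg(channel, setdiff(hg_channels(), "ambient"))
  years <- all_years(calendar)
  is_fish <- target %in% hg_species()
  if (is.null(method))
    method <- if (is_fish) "mean_of_ratios" else "ratio_of_means"
  method <- match.arg(method, c("ratio_of_means", "mean_of_ratios"))
  out <- data.frame(year = years, percent_increase = NA_real_, n = 0L)
  for (i in seq_along(years)) {
    y <- years[i]
    if (is_fish) {
      fish <- dataset$fish
      date <- as.Date(fish$date)
      keep <- fish$species == target &
        as.integer(format(date, "%Y")) == y &
        !is.na(fish$conc_ambient) & fish$conc_ambient > 0 &
        !is.na(fish[[paste0("conc_", channel)]])
      sp <- fish[[paste0("conc_", channel)]][keep]
      am <- fish$conc_ambient[keep]
      if (length(sp) == 0) next
      out$n[i] <- length(sp)
      out$percent_increase[i] <- if (method == "mean_of_ratios")
        mean(percent_increase(sp, am))
      else percent_increase(mean(sp), mean(am))
    } else {
      if (method == "ratio_of_means") {
        sp <- open_water_annual_mean(dataset$samples, y, channel, calendar,
                                     compartment = target)
        am <- open_water_annual_mean(dataset$samples, y, "ambient", calendar,
                                     compartment = target)
        if (is.na(sp) || is.na(am) || am <= 0) next
        out$percent_increase[i] <- percent_increase(sp, am)
        out$n[i] <- sum(dataset$samples$compartment == target &
                          format(as.Date(dataset$samples$date), "%Y") ==
                          as.character(y))
      } else {
        s <- dataset$samples
        date <- as.Date(s$date)
        keep <- s$compartment == target &
          as.integer(format(date, "%Y")) == y &
          as.integer(format(date, "%m")) %in% calendar$open_water_months &
          !is.na(s$conc_ambient) & s$conc_ambient > 0 &
          !is.na(s[[paste0("conc_", channel)]])
        if (!any(keep)) next
        out$n[i] <- sum(keep)
        out$percent_increase[i] <-
          mean(percent_increase(s[[paste0("conc_", channel)]][keep],
                                s$conc_ambient[keep]))
      }
    }
  }
  out
}

#' Annual biomagnification factor series
#'
#' BMF per year for one predator and channel: `log10` of predator
#' concentration (mean wet-basis for forage fish, length-standardised for
#' large-bodied fish) over the open-water mean prey concentration.
#'
#' @param dataset An [hg_dataset()].
#' @param predator Predator species.
#' @param channel Isotope channel.
#' @param calendar A [study_calendar()].
#' @param predator_conc Optional data frame `year`, `value` of predator
#'   concentrations (ng/g ww) to use instead of the built-in choice, e.g.
#'   the output of [standardize_annual()].
#' @return Data frame `year`, `pred_conc`, `prey_conc`, `bmf`.
#' @export
bmf_series <- function(dataset, predator, channel = "lake_spike",
                       calendar = study_calendar(), predator_conc = NULL) {
  stopifnot(inherits(dataset, "hg_dataset"))
  channel <- match.arg(channel, hg_channels())
  years <- all_years(calendar)
  if (is.null(predator_conc)) {
    if (predator %in% c("northern_pike", "lake_whitefish")) {
      std <- standardize_annual(dataset$fish, predator, channel,
                                calendar = calendar)
      predator_conc <- data.frame(year = std$year, value = std$conc_ww)
    } else {
      fish <- fish_wet_concentrations(dataset$fish)
      date <- as.Date(fish$date)
      vals <- vapply(years, function(y) {
        keep <- fish$species == predator &
          as.integer(format(date, "%Y")) == y
        v <- fish[[paste0("conc_", channel, "_ww")]][keep]
        v <- v[!is.na(v)]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
      predator_conc <- data.frame(year = years, value = vals)
    }
  }
  out <- data.frame(year = years, pred_conc = NA_real_, prey_conc = NA_real_,
                    bmf = NA_real_)
  for (i in seq_along(years)) {
    y <- years[i]
    pc <- predator_conc$value[match(y, predator_conc$year)]
    pr <- prey_exposure_mean(dataset, predator, y, channel, calendar)
    out$pred_conc[i] <- pc
    out$prey_conc[i] <- pr
    if (!is.na(pc) && !is.na(pr) && pc > 0 && pr > 0)
      out$bmf[i] <- bmf(pc, pr)
  }
  out
}

#' Linear trend test over a study phase
#'
#' Ordinary least-squares regression of an annual series on calendar year,
#' restricted to one phase, with the two-sided t-test for zero slope.
#' A series with zero residual variance is degenerate: the slope is still
#' reported but the p-value is `NA` with `degenerate = TRUE`.
#'
#' @param years Integer years.
#' @param values Annual values (same length); `NA`s dropped.
#' @param phase Years to include (e.g. `calendar$addition_years`); default
#'   all supplied years.
#' @return List with `slope`, `intercept`, `p_value`, `n`, `degenerate`.
#' @export
phase_trend_test <- function(years, values, phase = NULL) {
  stopifnot(length(years) == length(values))
  keep <- !is.na(values)
  if (!is.null(phase)) keep <- keep & years %in% phase
  x <- as.numeric(years[keep])
  y <- as.numeric(values[keep])
  n <- length(y)
  if (n < 3)
    stop("phase_trend_test requires at least 3 non-missing annual values",
         call. = FALSE)
  if (length(unique(x)) < 2)
    stop("all years identical; cannot fit a trend", call. = FALSE)
  fit <- lm(y ~ x)
  rss <- sum(residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  # constant response: no trend to test; an exactly linear series instead
  # has rss ~ 0 with a nonzero slope and p below machine level
  degenerate <- tss <= .Machine$double.eps^2 * max(1, sum(y^2))
  p <- if (degenerate) {
    NA_real_
  } else if (rss <= .Machine$double.eps^2 * tss) {
    0
  } else {
    unname(summary(fit)$coefficients["x", "Pr(>|t|)"])
  }
  list(slope = unname(coef(fit)["x"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       p_value = p, n = n, degenerate = degenerate)
}
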