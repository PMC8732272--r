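# End-to-end orchestration: run every stage on a dataset and collect the
# headline series into one report, with per-stage logging and provenance.

#' Analysis options for the full pipeline
#'
#' @param calendar A [study_calendar()].
#' @param policy A [detection_policy()].
#' @param species Large-bodied species to standardise and the species used
#'   for recovery kinetics.
#' @param recovery_species Species for the burden/decay stage.
#' @param spike_channel Spike channel analysed (default `lake_spike`).
#' @param start_offset Years after t0 at which the decay fit begins.
#' @param fraction Burden fraction for the time-to-fraction estimate.
#' @param include_white_sucker Include white sucker (excluded by default
#'   because of consistently low annual catches).
#' @return List of options (class `hg_analysis_options`).
#' @export
analysis_options <- function(calendar = study_calendar(),
                             policy = detection_policy(),
                             species = c("northern_pike", "lake_whitefish"),
                             recovery_species = "northern_pike",
                             spike_channel = "lake_spike",
                             start_offset = 2,
                             fraction = 0.5,
                             include_white_sucker = FALSE) {
  structure(list(calendar = calendar, policy = policy, species = species,
                 recovery_species = recovery_species,
                 spike_channel = spike_channel, start_offset = start_offset,
                 fraction = fraction,
                 include_white_sucker = include_white_sucker),
            class = "hg_analysis_options")
}

#' Run the full tracer analysis
#'
#' Deterministic composition of all pipeline stages on a validated dataset:
#' detection-limit censoring of spike channels, annual per cent increase
#' series for compartments and species, length-standardised concentrations
#' and BMFs, and the population burden series with its exponential-decay
#' fit and time-to-fraction.  Stages with insufficient data produce flagged
#' gaps (`NA` plus a log entry), never silent omissions.
#'
#' @param dataset An [hg_dataset()].
#' @param options An [analysis_options()].
#' @return An object of class `hg_report`.
#' @export
run_full_analysis <- function(dataset, options = analysis_options()) {
  stopifnot(inherits(dataset, "hg_dataset"))
  validate_samples(dataset$samples)
  validate_fish(dataset$fish)
  cal <- options$calendar
  ch <- options$spike_channel
  sim_seed <- attr(dataset, "seed")
  sim_config_attr <- attr(dataset, "config")
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # censor spike channels in fish against per-sample ambient
  fish <- dataset$fish
  if (!options$include_white_sucker) {
    n_ws <- sum(fish$species == "white_sucker")
    if (n_ws) note("excluded %d white_sucker observations", n_ws)
    fish <- fish[fish$species != "white_sucker", , drop = FALSE]
  }
  n_cens <- 0L
  for (sch in setdiff(hg_channels(), "ambient")) {
    col <- paste0("conc_", sch)
    ok <- !is.na(fish[[col]]) & !is.na(fish$conc_ambient) &
      fish$conc_ambient > 0
    cz <- censor_spike(fish[[col]][ok], fish$conc_ambient[ok],
                       options$policy)
    fish[[col]][ok] <- cz$value
    n_cens <- n_cens + sum(cz$below_dl)
  }
  note("censored %d below-detection spike values in fish", n_cens)
  dataset <- hg_dataset(dataset$samples, fish)

  # per cent increase series
  pinc <- list()
  for (tg in c("water", "sediment", "zooplankton", "chaoborus")) {
    s <- annual_percent_increase(dataset, tg, ch, cal)
    s$target <- tg
    pinc[[tg]] <- s
  }
  for (sp in intersect(unique(fish$species), hg_species())) {
    s <- annual_percent_increase(dataset, sp, ch, cal)
    s$target <- sp
    pinc[[sp]] <- s
  }
  pinc <- do.call(rbind, c(pinc, list(make.row.names = FALSE)))

  # standardised concentrations for large-bodied species, both channels
  std <- list()
  for (sp in options$species) {
    for (chan in c("ambient", ch)) {
      s <- standardize_annual(fish, sp, chan, calendar = cal)
      s$species <- sp
      s$channel <- chan
      std[[paste(sp, chan)]] <- s
      note("standardized %s/%s: %d year(s) with data", sp, chan,
           sum(!is.na(s$conc_ww)))
    }
  }
  std <- do.call(rbind, c(std, list(make.row.names = FALSE)))

  # BMF series
  bmfs <- list()
  for (sp in intersect(c("yellow_perch", "northern_pike", "lake_whitefish"),
                       unique(fish$species))) {
    for (chan in c("ambient", ch)) {
      pc <- NULL
      if (sp %in% options$species) {
        si <- std[std$species == sp & std$channel == chan, ]
        pc <- data.frame(year = si$year, value = si$conc_ww)
      }
      b <- bmf_series(dataset, sp, chan, cal, predator_conc = pc)
      b$species <- sp
      b$channel <- chan
      bmfs[[paste(sp, chan)]] <- b
    }
  }
  bmfs <- do.call(rbind, c(bmfs, list(make.row.names = FALSE)))

  # recovery kinetics on the standardised population of the focal species
  rsp <- options$recovery_species
  conc_s <- std[std$species == rsp & std$channel == ch,
                c("year", "conc_ww")]
  wt_s <- standardize_weight_annual(fish, rsp, calendar = cal)
  burden <- NULL; decay <- NULL; ttf <- NA_real_
  burden <- tryCatch(
    population_burden_series(conc_s, wt_s, cal$t0_year),
    error = function(e) { note("burden series: %s", conditionMessage(e)); NULL })
  if (!is.null(burden)) {
    decay <- tryCatch(
      fit_exponential_decay(burden$x, burden$normalized,
                            start_offset = options$start_offset),
      error = function(e) { note("decay fit: %s", conditionMessage(e)); NULL })
  }
  if (!is.null(decay) && !decay$degenerate && decay$k > 0)
    ttf <- as.numeric(time_to_fraction(decay, options$fraction))
  else if (!is.null(decay))
    note("time-to-fraction undefined (degenerate or non-declining fit)")

  trajectories <- individual_burden_trajectories(
    fish, rsp, ch, t0_year = cal$t0_year)

  prov <- list(
    seed = sim_seed,
    config_hash = if (!is.null(sim_config_attr))
      digest_config(sim_config_attr) else NA_character_,
    package_version = as.character(utils::packageVersion("hgtracer")),
    n_samples = nrow(dataset$samples), n_fish = nrow(dataset$fish))

  structure(list(percent_increase = pinc, standardized = std, bmf = bmfs,
                 burden = burden, decay = decay, time_to_fraction = ttf,
                 trajectories = trajectories, log = log_lines,
                 provenance = prov, options = options),
            class = "hg_report")
}

# cheap deterministic config fingerprint (no external digest dependency)
digest_config <- function(config) {
  txt <- paste(deparse(config[sort(names(config))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997)) %%
            .Machine$integer.max)
}

#' @export
print.hg_report <- function(x, ...) {
  cat("<hg_report>\n")
  if (!is.null(x$decay) && !x$decay$degenerate) {
    cat("  decay fit: a = ", signif(x$decay$a, 5), ", k = ",
        signif(x$decay$k, 5), " yr-1, R^2 = ", signif(x$decay$r_squared, 3),
        "\n", sep = "")
    cat("  time to ", 100 * x$options$fraction, "% of t0 burden: ",
        signif(x$time_to_fraction, 3), " yr\n", sep = "")
  }
  cat("  stages logged:", length(x$log), "\n")
  invisible(x)
}

#' Write report tables to disk
#'
#' One tidy CSV per series (stable column order), the decay fit and
#' provenance as JSON.  Empty sections produce header-only CSVs.
#'
#' @param report An `hg_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
render_tables <- function(report, dir) {
  stopifnot(inherits(report, "hg_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE, na = "")
    files <<- c(files, p)
  }
  wr(report$percent_increase, "percent_increase.csv")
  wr(report$standardized, "standardized_concentrations.csv")
  wr(report$bmf, "bmf.csv")
  wr(if (is.null(report$burden))
       data.frame(year = integer(), x = integer(), burden_ng = numeric(),
                  normalized = numeric())
     else report$burden, "burden_series.csv")
  wr(report$trajectories, "individual_trajectories.csv")
  fitjson <- file.path(dir, "decay_fit.json")
  jsonlite::write_json(
    list(decay = if (is.null(report$decay)) NULL else unclass(report$decay),
         time_to_fraction = report$time_to_fraction,
         provenance = report$provenance, log = report$log),
    fitjson, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, fitjson)
  invisible(files)
}
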