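# Domain vocabulary: isotope channels, compartments, species, study calendar,
# basis/unit conversions and detection-limit censoring.

#' Isotope channels
#'
#' Every concentration in the package is indexed by one of four isotope
#' channels: the `ambient` (background) pool and three experimentally added
#' spikes, distinguishable by stable-isotope enrichment, applied to the lake
#' surface, the upland catchment and the wetland respectively.
#'
#' @return Character vector of the four channel labels.
#' @export
hg_channels <- function() {
  c("ambient", "lake_spike", "upland_spike", "wetland_spike")
}

# concentration column names used throughout the CSV schemas
channel_cols <- function() paste0("conc_", hg_channels())

#' Non-fish compartments and fish species recognised by the data model
#' @return Character vector of labels.
#' @export
hg_compartments <- function() {
  c("water", "sediment", "zooplankton", "chaoborus", "chironomid")
}

#' @rdname hg_compartments
#' @export
hg_species <- function() {
  c("yellow_perch", "blacknose_shiner", "lake_whitefish", "northern_pike",
    "white_sucker")
}

#' Study calendar
#'
#' Defines the experiment phases: a contiguous block of spike-addition years
#' followed immediately by recovery years, and the open-water months over
#' which aquatic samples are aggregated.  `t0_year` (the reference year for
#' burden normalisation) is always the final addition year.
#'
#' @param addition_years Integer vector of consecutive addition-phase years.
#' @param recovery_years Integer vector of consecutive recovery-phase years;
#'   must start the year after additions end.
#' @param open_water_months Integer months (1-12) defining the ice-free
#'   sampling window; default May-October.
#' @return An object of class `hg_calendar`.
#' @examples
#' cal <- study_calendar()
#' cal$t0_year  # 2007
#' @export
study_calendar <- function(addition_years = 2001:2007,
                           recovery_years = 2008:2015,
                           open_water_months = 5:10) {
  addition_years <- as.integer(addition_years)
  recovery_years <- as.integer(recovery_years)
  open_water_months <- as.integer(open_water_months)
  stopifnot(length(addition_years) > 0, length(recovery_years) > 0)
  if (any(diff(addition_years) != 1L) || any(diff(recovery_years) != 1L))
    stop("addition and recovery year ranges must be consecutive", call. = FALSE)
  if (recovery_years[1] != max(addition_years) + 1L)
    stop("recovery phase must begin the year after additions end",
         call. = FALSE)
  if (any(open_water_months < 1L | open_water_months > 12L))
    stop("open_water_months must be in 1..12", call. = FALSE)
  structure(
    list(addition_years = addition_years,
         recovery_years = recovery_years,
         open_water_months = sort(unique(open_water_months)),
         t0_year = max(addition_years)),
    class = "hg_calendar")
}

#' @export
print.hg_calendar <- function(x, ...) {
  cat("Study calendar: additions ", min(x$addition_years), "-",
      max(x$addition_years), ", recovery ", min(x$recovery_years), "-",
      max(x$recovery_years), ", open water months ",
      paste(range(x$open_water_months), collapse = "-"),
      ", t0 = ", x$t0_year, "\n", sep = "")
  invisible(x)
}

all_years <- function(calendar) {
  c(calendar$addition_years, calendar$recovery_years)
}

#' Detection-limit policy for spike channels
#'
#' Spike concentrations are quantified against the ambient channel; the
#' detection limit for each spike is a fixed fraction of the ambient
#' concentration in the same sample (default 0.5%).  Values below the limit
#' are substituted with zero (default), half the detection limit, or left
#' unchanged and only flagged.
#'
#' @param spike_dl_fraction Detection limit as a fraction of ambient,
#'   in (0, 1).
#' @param substitution One of `"zero"`, `"half_dl"`, `"flag_only"`.
#' @return An object of class `hg_detection_policy`.
#' @export
detection_policy <- function(spike_dl_fraction = 0.005,
                             substitution = c("zero", "half_dl", "flag_only")) {
  substitution <- match.arg(substitution)
  if (!is.numeric(spike_dl_fraction) || length(spike_dl_fraction) != 1L ||
      is.na(spike_dl_fraction) ||
      spike_dl_fraction <= 0 || spike_dl_fraction >= 1)
    stop("spike_dl_fraction must be a single number in (0, 1)", call. = FALSE)
  structure(list(spike_dl_fraction = spike_dl_fraction,
                 substitution = substitution),
            class = "hg_detection_policy")
}

#' Convert a dry-weight concentration to wet weight
#'
#' Muscle and invertebrate MeHg is measured on freeze-dried tissue; wet-basis
#' values are obtained by multiplying with the dry-weight proportion of the
#' sample.  Fish use their individually measured proportion; bulk
#' invertebrate samples use the standard proportion 0.15.
#'
#' @param conc_dw Dry-basis concentration(s), ng/g; non-negative.
#' @param dw_proportion Dry-weight proportion(s) in (0, 1]; recycled.
#' @return Wet-basis concentration(s), ng/g.
#' @examples
#' dry_to_wet(200, 0.15)  # 30 ng/g ww
#' @export
dry_to_wet <- function(conc_dw, dw_proportion) {
  if (!is.numeric(conc_dw) || !is.numeric(dw_proportion))
    stop("inputs must be numeric", call. = FALSE)
  bad <- !is.na(dw_proportion) & (dw_proportion <= 0 | dw_proportion > 1)
  if (any(bad))
    stop("dw_proportion must be in (0, 1]", call. = FALSE)
  if (any(!is.na(conc_dw) & conc_dw < 0))
    stop("conc_dw must be non-negative", call. = FALSE)
  conc_dw * dw_proportion
}

# standard dry:wet proportion for bulk invertebrate samples
INVERT_DW_PROPORTION <- 0.15

#' Censor a spike concentration against its detection limit
#'
#' The detection limit for a spike channel is `spike_dl_fraction` times the
#' ambient concentration of the same sample.  Below-limit values are
#' substituted according to the policy and flagged.
#'
#' @param spike_conc Spike concentration(s); non-negative, same units as
#'   `ambient_conc`.
#' @param ambient_conc Ambient concentration(s); strictly positive.
#' @param policy A [detection_policy()].
#' @return A list with components `value` (censored concentrations) and
#'   `below_dl` (logical flags).
#' @examples
#' censor_spike(0.8, 200)                       # below DL 1.0 -> 0, TRUE
#' censor_spike(0.8, 200, detection_policy(substitution = "half_dl"))
#' @export
censor_spike <- function(spike_conc, ambient_conc, policy = detection_policy()) {
  stopifnot(inherits(policy, "hg_detection_policy"))
  if (!is.numeric(spike_conc) || !is.numeric(ambient_conc))
    stop("concentrations must be numeric", call. = FALSE)
  n <- max(length(spike_conc), length(ambient_conc))
  spike_conc <- rep_len(spike_conc, n)
  ambient_conc <- rep_len(ambient_conc, n)
  if (any(!is.na(ambient_conc) & ambient_conc <= 0))
    stop("ambient_conc must be positive to evaluate the detection limit",
         call. = FALSE)
  if (any(!is.na(spike_conc) & spike_conc < 0))
    stop("spike_conc must be non-negative", call. = FALSE)
  dl <- policy$spike_dl_fraction * ambient_conc
  below <- !is.na(spike_conc) & !is.na(dl) & spike_conc < dl
  value <- spike_conc
  if (policy$substitution == "zero") {
    value[below] <- 0
  } else if (policy$substitution == "half_dl") {
    value[below] <- dl[below] / 2
  } # flag_only leaves values unchanged
  list(value = value, below_dl = below)
}

#' Open-water season annual mean
#'
#' Unweighted arithmetic mean of a channel's concentration over all samples
#' falling in the open-water months of one calendar year.  Samples outside
#' the window are excluded; an empty window yields `NA` (missing, distinct
#' from zero).
#'
#' @param samples Compartment sample data frame (see [read_hg_dataset()]).
#' @param year Calendar year.
#' @param channel One of [hg_channels()].
#' @param calendar A [study_calendar()].
#' @param compartment Optional compartment filter.
#' @param depth_max Optional maximum depth (m) filter for water samples.
#' @return Mean concentration, or `NA_real_` when no samples fall in the
#'   window.
#' @export
open_water_annual_mean <- function(samples, year, channel,
                                   calendar = study_calendar(),
                                   compartment = NULL, depth_max = NULL) {
  channel <- match.arg(channel, hg_channels())
  stopifnot(is.data.frame(samples))
  date <- as.Date(samples$date)
  keep <- as.integer(format(date, "%Y")) == as.integer(year) &
    as.integer(format(date, "%m")) %in% calendar$open_water_months
  if (!is.null(compartment))
    keep <- keep & samples$compartment %in% compartment
  if (!is.null(depth_max) && "depth_m" %in% names(samples))
    keep <- keep & (is.na(samples$depth_m) | samples$depth_m <= depth_max)
  vals <- samples[[paste0("conc_", channel)]][keep]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

# ---- dataset container and CSV round trip ----------------------------------

#' Construct a tracer dataset
#'
#' Bundles compartment samples and fish observations after validation.
#'
#' @param samples Data frame with columns `compartment`, `date` (ISO-8601),
#'   `depth_m`, `basis` (`wet`/`dry`), `units` (`ng_per_L`/`ng_per_g`) and
#'   the four `conc_*` channel columns.
#' @param fish Data frame with columns `species`, `age_class`, `fish_id`,
#'   `date`, `fork_length_mm`, `mass_g`, `dw_proportion`, the four `conc_*`
#'   columns (dry basis, ng/g) and `age_years`.
#' @return An object of class `hg_dataset`.
#' @export
hg_dataset <- function(samples, fish) {
  validate_samples(samples)
  validate_fish(fish)
  structure(list(samples = samples, fish = fish), class = "hg_dataset")
}

#' @export
print.hg_dataset <- function(x, ...) {
  cat("<hg_dataset> ", nrow(x$samples), " compartment samples, ",
      nrow(x$fish), " fish observations\n", sep = "")
  if (nrow(x$samples))
    cat("  compartments:",
        paste(sort(unique(x$samples$compartment)), collapse = ", "), "\n")
  if (nrow(x$fish))
    cat("  species:",
        paste(sort(unique(x$fish$species)), collapse = ", "), "\n")
  invisible(x)
}

sample_schema <- function() {
  c("compartment", "date", "depth_m", "basis", "units", channel_cols())
}

fish_schema <- function() {
  c("species", "age_class", "fish_id", "date", "fork_length_mm", "mass_g",
    "dw_proportion", channel_cols(), "age_years")
}

fail_rows <- function(what, rows) {
  stop(sprintf("%s (rows: %s)", what,
               paste(utils::head(rows, 10), collapse = ", ")), call. = FALSE)
}

#' Validate compartment sample / fish observation tables
#'
#' Checks the mandatory column schema and field invariants; errors report
#' the offending row numbers.
#'
#' @param samples,fish Data frames in the documented CSV schemas.
#' @return The validated data frame, invisibly.
#' @export
validate_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  missing_cols <- setdiff(sample_schema(), names(samples))
  if (length(missing_cols))
    stop("samples table missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(samples) == 0) return(invisible(samples))
  bad <- which(!samples$compartment %in% hg_compartments())
  if (length(bad)) fail_rows("unknown compartment", bad)
  d <- suppressWarnings(as.Date(samples$date))
  if (any(is.na(d))) fail_rows("unparseable date", which(is.na(d)))
  bad <- which(!samples$basis %in% c("wet", "dry"))
  if (length(bad)) fail_rows("basis must be 'wet' or 'dry'", bad)
  bad <- which(!samples$units %in% c("ng_per_L", "ng_per_g"))
  if (length(bad)) fail_rows("units must be ng_per_L or ng_per_g", bad)
  bad <- which(samples$compartment == "water" & samples$units != "ng_per_L")
  if (length(bad)) fail_rows("water samples must be ng_per_L", bad)
  bad <- which(samples$compartment != "water" & samples$units != "ng_per_g")
  if (length(bad)) fail_rows("non-water samples must be ng_per_g", bad)
  bad <- which(samples$compartment == "sediment" & samples$basis != "dry")
  if (length(bad)) fail_rows("sediment concentrations must be dry basis", bad)
  for (col in channel_cols()) {
    bad <- which(!is.na(samples[[col]]) & samples[[col]] < 0)
    if (length(bad)) fail_rows(paste0("negative concentration in ", col), bad)
  }
  invisible(samples)
}

#' @rdname validate_samples
#' @export
validate_fish <- function(fish) {
  stopifnot(is.data.frame(fish))
  missing_cols <- setdiff(fish_schema(), names(fish))
  if (length(missing_cols))
    stop("fish table missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(fish) == 0) return(invisible(fish))
  bad <- which(!fish$species %in% hg_species())
  if (length(bad)) fail_rows("unknown species", bad)
  d <- suppressWarnings(as.Date(fish$date))
  if (any(is.na(d))) fail_rows("unparseable date", which(is.na(d)))
  bad <- which(!(is.na(fish$age_class) | fish$age_class %in%
                   c("YOY", "age1plus", "adult")))
  if (length(bad)) fail_rows("age_class must be YOY/age1plus/adult", bad)
  bad <- which(!is.na(fish$fork_length_mm) & fish$fork_length_mm <= 0)
  if (length(bad)) fail_rows("fork_length_mm must be positive", bad)
  bad <- which(!is.na(fish$mass_g) & fish$mass_g <= 0)
  if (length(bad)) fail_rows("mass_g must be positive", bad)
  bad <- which(!is.na(fish$dw_proportion) &
                 (fish$dw_proportion <= 0 | fish$dw_proportion > 1))
  if (length(bad)) fail_rows("dw_proportion must be in (0, 1]", bad)
  for (col in channel_cols()) {
    bad <- which(!is.na(fish[[col]]) & fish[[col]] < 0)
    if (length(bad)) fail_rows(paste0("negative concentration in ", col), bad)
  }
  invisible(fish)
}

#' Read / write a tracer dataset as CSV
#'
#' A dataset directory holds `samples.csv` and `fish.csv` in the documented
#' schemas (ISO-8601 dates, decimal point, UTF-8, mandatory header row).
#' The round trip `read_hg_dataset(write_hg_dataset(x, d))` reproduces every
#' record.
#'
#' @param dir Directory containing (or to receive) `samples.csv` and
#'   `fish.csv`.
#' @param dataset An [hg_dataset()].
#' @return `read_hg_dataset()` returns an `hg_dataset`;
#'   `write_hg_dataset()` returns the directory path invisibly.
#' @export
read_hg_dataset <- function(dir) {
  sp <- file.path(dir, "samples.csv")
  fp <- file.path(dir, "fish.csv")
  for (p in c(sp, fp))
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
  samples <- read.csv(sp, stringsAsFactors = FALSE,
                      colClasses = c(date = "character"))
  fish <- read.csv(fp, stringsAsFactors = FALSE,
                   colClasses = c(date = "character"))
  # empty files come back with logical NA columns; coerce to schema types
  if (nrow(samples) == 0) samples <- empty_samples()
  if (nrow(fish) == 0) fish <- empty_fish()
  if (!"fish_id" %in% names(fish)) fish$fish_id <- NA_character_
  fish$fish_id <- as.character(fish$fish_id)
  hg_dataset(samples, fish)
}

#' @rdname read_hg_dataset
#' @export
write_hg_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "hg_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # %.17g guarantees doubles survive the text round trip bit-for-bit
  fmt <- function(df) {
    for (col in names(df)) {
      if (is.double(df[[col]])) {
        v <- sprintf("%.17g", df[[col]])
        v[is.na(df[[col]])] <- ""
        df[[col]] <- v
      }
    }
    df
  }
  write.csv(fmt(dataset$samples), file.path(dir, "samples.csv"),
            row.names = FALSE, na = "")
  write.csv(fmt(dataset$fish), file.path(dir, "fish.csv"),
            row.names = FALSE, na = "")
  invisible(dir)
}

empty_samples <- function() {
  df <- data.frame(compartment = character(), date = character(),
                   depth_m = numeric(), basis = character(),
                   units = character(), stringsAsFactors = FALSE)
  for (col in channel_cols()) df[[col]] <- numeric()
  df
}

empty_fish <- function() {
  df <- data.frame(species = character(), age_class = character(),
                   fish_id = character(), date = character(),
                   fork_length_mm = numeric(), mass_g = numeric(),
                   dw_proportion = numeric(), stringsAsFactors = FALSE)
  for (col in channel_cols()) df[[col]] <- numeric()
  df$age_years <- numeric()
  df
}

#' Wet-basis fish concentrations
#'
#' Adds `conc_<channel>_ww` columns (dry-basis muscle MeHg times the
#' individual dry-weight proportion) to a fish table.
#'
#' @param fish Fish observation data frame.
#' @return The data frame with four additional wet-basis columns.
#' @export
fish_wet_concentrations <- function(fish) {
  for (ch in hg_channels()) {
    fish[[paste0("conc_", ch, "_ww")]] <-
      dry_to_wet(fish[[paste0("conc_", ch)]], fish$dw_proportion)
  }
  fish
}
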