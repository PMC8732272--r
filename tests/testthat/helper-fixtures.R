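# In-code fixtures shared across test files.

make_samples <- function(compartment, dates, conc_ambient,
                         conc_lake_spike = 0, conc_upland_spike = 0,
                         conc_wetland_spike = 0, depth_m = NA_real_) {
  n <- length(dates)
  data.frame(
    compartment = rep_len(compartment, n), date = dates,
    depth_m = rep_len(depth_m, n),
    basis = rep_len(if (compartment[1] == "water") "wet" else "dry", n),
    units = rep_len(if (compartment[1] == "water") "ng_per_L" else
                      "ng_per_g", n),
    conc_ambient = rep_len(conc_ambient, n),
    conc_lake_spike = rep_len(conc_lake_spike, n),
    conc_upland_spike = rep_len(conc_upland_spike, n),
    conc_wetland_spike = rep_len(conc_wetland_spike, n),
    stringsAsFactors = FALSE)
}

make_fish <- function(species, year, fork_length_mm, conc_lake_spike,
                      conc_ambient = 1000, mass_g = NULL,
                      dw_proportion = 0.2, fish_id = NA_character_,
                      age_class = "adult") {
  n <- max(length(fork_length_mm), length(conc_lake_spike))
  fl <- rep_len(fork_length_mm, n)
  data.frame(
    species = rep_len(species, n), age_class = rep_len(age_class, n),
    fish_id = rep_len(fish_id, n),
    date = rep_len(sprintf("%04d-09-15", year), n),
    fork_length_mm = fl,
    mass_g = if (is.null(mass_g)) 1e-5 * fl^3 else rep_len(mass_g, n),
    dw_proportion = rep_len(dw_proportion, n),
    conc_ambient = rep_len(conc_ambient, n),
    conc_lake_spike = rep_len(conc_lake_spike, n),
    conc_upland_spike = 0, conc_wetland_spike = 0,
    age_years = NA_real_, stringsAsFactors = FALSE)
}

# independent normal-equations solve for polynomial OLS (test oracle; kept
# deliberately separate from the lm-based implementation path)
poly_oracle <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# small quick simulator configuration for tests that need a full dataset
quick_config <- function(...) {
  dem <- default_demography()
  for (sp in names(dem)) dem[[sp]]$recruits <- ceiling(dem[[sp]]$recruits / 2)
  sim_config(demography = dem, burnin_years = 15L, ...)
}
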