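# hgtracer

Tracer accounting and recovery kinetics for whole-lake mercury
stable-isotope loading experiments.

## What it is for

In a whole-ecosystem loading experiment, inorganic mercury enriched in
distinct stable isotopes ("spikes") is added to a lake surface and its
catchment for several years and then stopped. Because the spike is
isotopically distinguishable from background ("ambient") mercury, the
methylmercury (MeHg) formed from it can be followed separately through
water, sediment, invertebrates and fish — first as it accumulates, then
as the ecosystem sheds it. `hgtracer` is for ecotoxicologists and
ecosystem scientists analysing such experiments (or planning them): it
implements the standard analysis chain and a synthetic ecosystem
generator so the whole pipeline is testable end to end.

The core quantities, in the field's notation:

* **Per cent increase** `= 100 × [spike MeHg] / [ambient MeHg]` — how
  much the experimental loading raised MeHg in each compartment.
* **Biomagnification factor**
  `BMF = log10([MeHg]_predator / [MeHg]_prey)`, wet weight, with prey
  exposure averaged over the open-water season.
* **Length-standardised concentration** — per-year OLS polynomial of
  muscle MeHg on fork length (FL), evaluated at a species standard FL
  (pike 475 mm, whitefish 530 mm); square-root transform for pike.
* **Body burden** `= MeHg (ng/g ww) × mass (g)`, normalised to t0 (the
  autumn of the final addition year), fitted from the second recovery
  year by nonlinear least squares `y = a·e^(−kx)`, with the time to 50%
  of the original burden `t½ = ln(a/0.5)/k`.

Spike detection limits are 0.5% of ambient per sample; below-limit values
are censored (zero by default). Dry-to-wet conversion uses 0.15 for bulk
invertebrates and each fish's own dry-weight proportion.

## Worked example

```r
library(hgtracer)

# a full synthetic experiment: 7 addition years, 8 recovery years
ds <- simulate_ecosystem(sim_config(), seed = 1)
ds
#> <hg_dataset> 1125 compartment samples, 1155 fish observations
#>   compartments: chaoborus, chironomid, sediment, water, zooplankton
#>   species: blacknose_shiner, lake_whitefish, northern_pike, white_sucker, yellow_perch

spike_mass_balance(ds)          # errors if the tracer ledger leaks

report <- run_full_analysis(ds)
report
#> <hg_report>
#>   decay fit: a = 1.8577, k = 0.23928 yr-1, R^2 = 0.956
#>   time to 50% of t0 burden: 5.49 yr
#>   stages logged: 6

subset(report$burden, year >= 2007)
#>    year x burden_ng normalized
#> 7  2007 0  636.3721  1.0000000
#> 8  2008 1  658.0700  1.0340963
#> 9  2009 2  689.8828  1.0840872
#> 10 2010 3  601.5504  0.9452810
#> ...
#> 15 2015 8  142.5180  0.2239539
```

The normalised pike burden rises just after additions stop (the food web
is still contaminated), then decays; the fitted curve says this synthetic
population sheds half its original tracer burden in ~5.5 years. The same
machinery applied to published fit parameters (a = 1.7439,
k = 0.2928 yr⁻¹) gives the canonical population half-life:

```r
time_to_fraction(list(a = 1.7439, k = 0.2928), 0.5)
#> [1] 4.266636  (years since the final addition)
```

Per-compartment loading response at the end of additions, from the same
simulated dataset:

```r
subset(report$percent_increase, year == 2007 & target %in% c("water", "sediment"))
#>    year percent_increase  n   target
#> 7  2007         55.94784 36    water
#> 22 2007         29.37147 24 sediment
```

## Command line

```sh
Rscript inst/exec/hgtracer simulate --out data/ --seed 1
Rscript inst/exec/hgtracer validate --data data/
Rscript inst/exec/hgtracer analyze  --data data/ --out results/
```

Subcommands: `simulate`, `validate`, `metrics`, `standardize`,
`recovery`, `analyze`. Nonzero exit with a stage-attributed message on
failure; every simulated dataset is written with its exact config and a
mass-balance ledger.

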