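---
title: "Methods: isotope-tracer accounting and fish-population recovery kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-tracer accounting and fish-population recovery kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtracer)
```

## The problem

Whole-ecosystem mercury loading experiments add inorganic Hg enriched in
distinct stable isotopes ("spikes") to a lake and its catchment, so that
newly deposited mercury can be followed through methylation and
bioaccumulation against the background ("ambient") pool. After additions
stop, the question becomes kinetic: how quickly do fish populations shed
the tracer? `hgtracer` implements the analysis chain for such experiments
— isotope-channel accounting, trophic statistics, size standardisation and
burden-decay regression — together with a synthetic ecosystem generator so
that every stage can be exercised and validated without field data.

## Isotope channels, units and censoring

Every concentration is indexed by one of four channels: `ambient`,
`lake_spike`, `upland_spike`, `wetland_spike`. Water is carried in ng/L;
sediment in ng/g dry weight; invertebrates are measured dry and converted
wet with the standard proportion 0.15; fish muscle is measured dry and
converted with each individual's dry-weight proportion. No implicit
conversion between ng/L and ng/g ever occurs; units and basis travel with
each record.

Spike channels are quantified against ambient: the detection limit is
0.5% of the ambient concentration in the same sample
(`detection_policy()`). Below-limit values are substituted with zero by
default — the wetland spike never rises above detection in fish, and a
zero substitution keeps downstream per cent increases honest — with
`half_dl` and `flag_only` available. Censoring to zero means a spike BMF
is *missing*, never `-Inf`; `bmf()` refuses non-positive inputs by design.

Annual aggregation uses the open-water season (May–October, configurable)
and is an unweighted mean over samples; depth is recorded but not used for
weighting (the source experiments do not state a weighting), and a depth
filter is exposed for sensitivity analyses. Missing years propagate as
`NA` and are never interpolated.

## Tracer statistics

*Per cent increase* is `100 × spike/ambient`. For water and sediment the
annual value is the ratio of annual means (default); for fish it is the
mean of individual-level ratios over the autumn sample, computed from raw
(not size-standardised) concentrations. Both aggregations are implemented
(`annual_percent_increase(method=)`) because the convention for abiotic
series is ambiguous in the field literature; the default is documented and
configurable.

*Biomagnification factor* is `log10([MeHg]_predator / [MeHg]_prey)`, wet
basis, with prey exposure averaged over the open-water season immediately
preceding autumn fish sampling. Default prey mapping: age-1+ yellow perch
← zooplankton; northern pike ← forage fishes (young-of-year and age-1+
perch plus blacknose shiner, pooled unweighted, as diet proportions are
not available); lake whitefish ← *Chaoborus*. Predator concentration is
the annual mean for forage fish and the length-standardised value for
large-bodied fish.

*Phase trend tests* are per-channel, per-species OLS regressions of annual
value on year with a two-sided t-test for zero slope, unadjusted for
multiple comparisons. A constant series is reported as degenerate (slope
0, p `NA`) rather than p = 1, since the residual variance is zero.

## Length standardisation

To remove size bias, per-year OLS polynomial regressions of wet-basis
muscle MeHg on fork length (FL) are evaluated at a species standard FL
(the study-mean FL: northern pike 475 mm, lake whitefish 530 mm; note a
535 mm variant appears in some summaries — the default here is 530, and
the value is configurable). The default model is a quadratic polynomial;
northern pike concentrations are square-root transformed before fitting
(normality/homoscedasticity), with a naive squaring back-transform and no
retransformation bias correction, matching the source convention. The
transform is applied to concentrations only, not to the FL–weight fit.

Sparse years fall back down a ladder — quadratic (n ≥ 4) → linear (n ≥ 3)
→ annual mean — with the model used recorded per year (`fit_model`), so a
year fitted linearly (as happens in real datasets) is visible in the
output rather than silently different. Negative raw predictions are
floored at zero with a flag. FL–weight standardisation always uses a
quadratic.

## Recovery kinetics

Body burden is concentration (ng/g ww) × mass (g), in ng throughout
(reporting layers may display µg). The population series multiplies the
standardised concentration by the standardised body weight per year and
normalises to t0, the autumn of the final addition year; values above 1
in early recovery are real (continued accumulation from a still-contaminated
food web) and are retained.

The decay model `y = a·e^(−kx)` is fitted by nonlinear least squares on
the untransformed normalised burdens, initialised by log-linear OLS, with
`x` in whole years since t0 and fitting restricted to `x ≥ 2` ("beginning
in the second year of recovery") because burdens typically rise first.
NLS on raw proportions — not a log-linear fit — is deliberate: it matches
fitted amplitudes above 1 for series that decline late. `nls` is run with
`scaleOffset = 1` so the convergence test is valid on zero-residual
(noiseless) data, which makes the exactness tests meaningful rather than
relying on a hand-rolled optimiser. Goodness of fit is reported on the
untransformed scale (R², F with (1, n−2) df, p).

Two standard errors are reported for each parameter: the classical `nls`
covariance and an HC3 sandwich estimate. Burden series carry
multiplicative noise (variance proportional to the squared mean), under
which the classical covariance is anti-conservative — in simulation at
10% lognormal noise its nominal 95% interval covers only ~79% — while the
HC3 interval attains ~92% coverage. Normal-approximation intervals should
therefore use `se_k_robust`.

Time-to-fraction solves `fraction = a·e^(−kt)` analytically,
`t = ln(a/fraction)/k`; the fraction refers to the original (t0) burden,
i.e. to y itself, not to the fitted value at x = 0. If the curve starts
below the target fraction, the negative analytic root is returned with a
`below_at_start` flag. No bootstrap confidence interval is attached (the
analysis it mirrors reports none).

Individual recovery trajectories are computed per recaptured tagged fish
with its own t0 burden; fish lacking a t0 capture are excluded from the
individual panel but still contribute to the population series.

## The synthetic ecosystem

The generator is a stated world, not a fitted model: the experiments it
emulates published no mechanistic equations, so all simulator dynamics are
artifact plumbing whose *defaults* were calibrated once to printed
aggregate behaviours, then frozen. What it emulates:

* **Forcing.** Nine bi-weekly within-season lake additions are aggregated
  to one annual load of 22 µg m⁻² yr⁻¹ over 8.4 ha during 2001–2007, then
  zero. A fixed `methylation_yield` (0.07) of the inorganic load enters
  the coupled MeHg pools; the unmethylated remainder is out of scope of
  the MeHg ledger. Watershed spikes arrive as small trickle inputs
  (upland 1.5% and wetland 0.1% of ambient input) so the censoring paths
  are exercised: the wetland channel sits below the 0.5% detection limit
  everywhere, as observed.
* **Abiotic pools.** Water and sediment MeHg follow an annual linear
  first-order scheme (gain from input split 40/60 water/sediment;
  water→loss 0.430 yr⁻¹, water→sediment 0.139 yr⁻¹, sediment→water
  0.0217 yr⁻¹, sediment→loss 0.136 yr⁻¹). These four rates come from a
  one-time least-squares calibration to the canonical three-year
  post-cessation declines (−81% water, −35% sediment) and are not free
  parameters of any test.
* **Ambient.** A constant ambient MeHg input (195,800 µg yr⁻¹) with pools
  initialised at the fixed point of the same linear system, plus an inert
  legacy sediment store (418,900 µg), chosen analytically so the
  end-of-additions per cent increases land near the printed ~60% (water)
  and ~30% (sediment). Ambient is therefore stationary by construction up
  to the (sub-percent) fish uptake draw.
* **Invertebrates** equilibrate instantaneously to a weighted sum of the
  water and sediment concentrations; the taxon weights were derived from
  the printed intermediate invertebrate declines (−66% zooplankton, −67%
  *Chaoborus*), which places their per cent increases in the observed
  45–57% band without further tuning.
* **Fish** are individuals in age-structured populations: von Bertalanffy
  growth with individual length/condition multipliers, length–mass
  allometry, annual diet-weighted MeHg uptake proportional to body mass,
  first-order elimination, growth dilution via mass increase (not an
  explicit rate), stochastic annual mortality, and recruitment of
  zero-burden young. Pike demography (median biopsy age ≈ 3 yr) and
  whitefish demography (long-lived, low mortality) mirror the study
  populations. The whitefish "elimination" default (0.20 yr⁻¹) is an
  *effective* population loss rate calibrated once to the printed 38%
  eight-year decline; it bundles unmodelled losses and is not a
  physiological claim — boreal fish eliminate MeHg far more slowly.
* **Observation model.** Monthly open-water compartment samples (six
  water depths, four sediment stations, invertebrate tows) and autumn
  fish samples with lognormal noise of mean 1 (CV 0.2 by default, a
  typical field analytical+ecological CV); forage fish are sampled
  lethally (removed), large-bodied fish are tagged and recaptured with
  probability 0.35 per year. All randomness derives from one seed; the
  global RNG state is restored on exit.

**Mass balance.** Every spike flow is double-entry: additions, pool
transfers, fish uptake (drawn from the water/sediment pools in proportion
to the diet pathway), elimination, deaths and lethal sampling all land
either in a pool or in cumulative losses. The audit
(`spike_mass_balance()`) checks `added = water + sediment + fish + losses`
per year and channel to 1e−9 relative tolerance; it closes to machine
precision by construction. One deliberate simplification: piscivore
uptake is routed through the pelagic pool rather than debited from prey
fish burdens (< 1% of pool masses); prey burdens leave the fish pool at
death.

**What a green test does not establish.** The generator reproduces
*configured* aggregate behaviours — the calibration targets above are
regression checks on defaults, not scientific claims — and its annual
time step has no within-year kinetics, no spatial structure, no
bioenergetics, and no temperature dependence. Field-scale percentages
(e.g. the printed 76% pike decline) are emulated only approximately
(~69% here) and the mechanism tests are deliberately qualitative:
with elimination forced to ~0, turnover-ON populations shed burden
(normalised burden < 1 at t0+8) while turnover-OFF individuals never do,
and long-lived populations decline more slowly than short-lived ones.

## Numerical and design choices

* `x` is measured in whole years since autumn t0; "second year of
  recovery" means `x ≥ 2`. The printed population fit implies eight
  points (F(1,6)) where whole-year offsets from the stated rule give
  seven; the discrepancy is not resolvable from the text and whole-year
  offsets are used.
* White sucker is excluded from analyses by default (consistently low
  annual catches), re-enablable via `analysis_options()`.
* The pipeline is deterministic given (dataset, options); the end-to-end
  consistency test compares the pipeline's fitted k against the *same
  estimand* (standard-length pike burden) computed from the complete
  noise-free population, because the population burden lags the water
  pool by construction — no generator recovers the water rate from fish.
* CSV serialisation uses `%.17g`, making write→read round trips bit-exact
  for doubles.
* The CLI config file is JSON (no YAML parser in the supported
  dependency set); all config fields are overridable and the exact config
  used is written next to every simulated dataset.

## Known limitations

Annual resolution only; no isotope-dilution chemistry or analytical QC
(out of scope); no mixed-effects or age-standardisation alternatives to
the per-year fits; no bootstrap uncertainty for the half-life; the
turnover experiment manipulates demography globally rather than
per-species.
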