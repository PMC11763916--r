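---
title: "The daily RATIO pipeline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The daily RATIO pipeline: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratioflux)
library(dplyr)
```

## The statistic and why it is useful

Eddy-covariance (EC) towers measure half-hourly exchanges of energy, water
vapor and CO2 between an ecosystem and the atmosphere. The central statistic
of this package is the **daily RATIO**: the latent-heat flux (LE, the energy
equivalent of evapotranspiration) summed over the photosynthetic period of a
day, divided by the LE sum over the whole day,

$$\mathrm{RATIO} = \frac{\sum_{\text{day}} LE}{\sum_{\text{day}} LE + \sum_{\text{night}} LE}.$$

Physically a daytime share of a day's vapor flux must lie strictly between 0
and 1. Measured half-hourly LE, however, can be negative at night
(condensation, instrument artifacts), which pushes the computed ratio outside
the open interval; such days are discarded by `filter_ratio()` rather than
clamped, because a clamped value would misstate the daytime share. On the
global flux-network archive this screen removes roughly a quarter of all
site-days, and the synthetic generator reproduces that operating point
(23.4% of days engineered out of range by default).

The daily RATIO turns out to be a useful *index of ecosystem functioning*:
when site-days from any mix of ecosystems are binned by it, the per-bin means
of the other EC variables trace out consistent curves. The package quantifies
that coupling, exploits it to transfer observations between places, and reads
climate-effect predictions off the temporal-trend structure it induces.

## Pipeline stages

1. **Ingestion** (`read_fluxnet_hh()`, `read_site_metadata()`): FLUXNET2015
   FULLSET-dialect CSVs with `-9999` decoded to `NA` and timestamps validated.
   The default column map uses the VUT reference and nighttime-partitioning
   product columns; both are configurable because archives differ.
2. **Day/night partition and daily summaries** (`partition_day_night()`,
   `summarize_daily()`): the photosynthetic period defaults to slots with
   positive potential shortwave radiation (`sw_in_pot > 0`), with a measured
   `SW_IN > 20 W m^-2` rule as the alternative; the two differ mainly around
   dawn and dusk. Days with less than 90% of LE slots present are marked
   invalid — a conventional completeness requirement for daily flux sums.
3. **RATIO filter** (`filter_ratio()`): strict open-interval screen, discard
   share reported.
4. **Coupling** (`bin_by_ratio()`, `fit_coupling_curve()`): the RATIO range is
   divided into 200 half-open sub-intervals; per-bin means of one variable
   are fitted against bin centers either by a count-weighted degree-6
   polynomial or by a 500-tree random forest. Fitting on bin means rather
   than raw site-days (an option) reflects that the coupling is a property of
   the binned curve; count weighting keeps sparse extreme bins from steering
   the fit. Degree 6 is the lowest even degree that tracks a unimodal curve
   with asymmetric shoulders without visible lack of fit; empty bins are
   skipped, never interpolated.
5. **Mapping** (`map_observations()`, `evaluate_mapping()`): a coupling model
   fitted in one region predicts another region's site-days from their
   observed RATIOs alone. Comparison is at site-day resolution; target days
   outside the source fit domain are excluded and counted rather than
   extrapolated.
6. **Trends** (`bootstrap_trends()`, `curve_features()`): see below.
7. **Drivers** (`driver_table()`, `screen_contributors()`, `lai_ratio_curve()`):
   random-forest importance of nine candidate factors (day length, LAI, day
   minus night temperature, P, SWC, CO2, P/PET, VPD, wind speed) for the
   daily RATIO; permutation importance is the default because it is
   comparable across predictor scales. PET uses the Hargreaves
   temperature-and-radiation form — a deliberate, documented stand-in since
   wetness-index conventions vary across studies; Thornthwaite-type
   alternatives can be substituted upstream of `wetness_index()`.
8. **Effect classification** (`classify_effect()`): a mean daily RATIO plus
   the sign of a vegetation change (greening/browning) maps to a predicted
   daytime-temperature effect through the regime table below.

## The bootstrap trend model

For each of 50 RATIO sub-intervals, `bootstrap_trends()` draws `B` samples of
4,000 site-day records (with replacement, redrawn until at least 10 distinct
sites are present — a guard against a single site's local trend masquerading
as a network signal). Each sample is collapsed to one mean per calendar year
and regressed on year; the signed coefficient $r = \pm\sqrt{R^2}$ (the
Pearson correlation with year, signed by the slope) is stored per bin.

The regression unit matters. With one point per year of an 18-year record,
the two-sided 5% critical value of $r$ is

$$r_c = \frac{t_{0.975,\,16}}{\sqrt{t_{0.975,\,16}^2 + 16}} \approx 0.47,$$

which `critical_r()` recomputes from the observed year span rather than
hard-coding. A record-level regression on 4,000 points would make $|r| > 0.47$
unreachable under any realistic noise and would disconnect the curves from
their significance band, so annual means are the default and record-level
regression is an explicit option (`unit = "records"`).

### Reading features off a noisy curve

Each bin's median $r$ inherits the sampling noise of an 18-point correlation,
roughly $(1-\rho^2)/\sqrt{n_\text{years}-3}$ — around 0.05–0.1. Features of
the curve therefore cannot be read from single bins: the raw argmax of the
median curve wanders by several bin widths across the flat top. The package
reports the raw readings (`all_crossings`, `vertex_raw`) and, as headline
estimates, locally pooled versions: the zero crossing from an iterated local
linear fit and the vertex from an iterated local quadratic fit, both on the
variance-stabilizing $\mathrm{atanh}(r)$ scale (where the per-bin noise is
approximately constant and, conveniently,
$\mathrm{atanh}(c/\sqrt{1+c^2}) = \mathrm{asinh}(c)$ for a signal-to-noise
ratio $c$). In repeated runs of the default synthetic network the pooled
estimators localize the crossing within about 0.012 and the vertex within
about 0.003 RATIO; the raw argmax is 10–20 times noisier.

## The effect regime table

The daytime-temperature trend coefficient as a function of the daily RATIO
crosses zero near 0.55, climbs to a vertex near 0.90, and declines at an
accelerating pace beyond it. Since greening raises an ecosystem's RATIO, the
local slope of that curve gives the sign of the predicted daytime-temperature
response:

| mean RATIO | greening effect | browning effect |
|---|---|---|
| (0, 0.75) | strong warming | strong cooling |
| [0.75, 0.90) | weak warming | weak cooling |
| [0.90, 1) | strong cooling | strong warming |

Intervals are half-open by design (the regime descriptions are open ranges
with no stated boundary rule, so a deterministic convention is required);
an optional split at 0.93 separates weak from strong cooling for users who
want the finer distinction in the 0.90–0.93 band. `classify_from_trend_curve()`
derives the same labels from a fitted trend curve's local derivative and
falls back to the static table when the curve is too noisy.

## The synthetic generator: what it emulates, what it does not

`simulate_daily_summaries()` generates a network whose ground truth is known
exactly, so every stage of the pipeline can be tested quantitatively:

- **Network**: 30 sites from 70°S to 70°N, years 1997–2014 — the scale at
  which the trend design carries signal while the full test suite stays in
  the minutes range. Test configurations shrink the network, not the years,
  when they exercise the trend stage.
- **Latent RATIO**: each site's mean RATIO comes from a monotone LAI link
  (`0.50 + 0.47·LAI/(LAI+1)`, spanning ≈0.58–0.90 over LAI 0.2–6); daily
  values follow a Beta distribution with SD 0.12 around it. LAI is assigned
  in scrambled order across latitude so vegetation and climate zone are not
  confounded.
- **Couplings**: flux and energy variables follow a smooth sextic rising over
  (0, 0.94) and declining by ~6% of range toward 1 (NEE-type variables
  inverted); matter variables (P, CO2, SWC) decline linearly. The sextic
  family was chosen during calibration: a degree-6 polynomial fit is unbiased
  for the location of its own extremum, whereas kinked or effectively flat
  peak shapes displace the fitted argmax by far more than a bin width —
  an approximation artifact, not a data property.
- **Noise**: observation noise 10% of each curve's range for flux/energy
  variables and 40% for matter variables; site offsets 1.5% / 3% / 10% of
  range for flux / energy / matter. The ordering encodes the empirical
  regularity the mapping stage relies on: at a common RATIO the flux
  magnitudes are nearly ecosystem-invariant, matter variables much less so.
  The site-offset scale was calibrated by Monte Carlo so that the
  site-composition drift across RATIO bins (sites enter and leave bins as
  RATIO varies, dragging their offsets with them) stays below the coupling
  fit's one-bin peak-recovery tolerance.
- **Trends**: daytime air temperature carries a slope profile with a steep
  zero-crossing at RATIO 0.55, a plateau, and a quadratic cap of half-width
  0.10 peaking at 0.90 (peak slope 0.05 °C yr⁻¹); CO2 rises at 2 ppm yr⁻¹
  everywhere; all other variables are trend-free and double as the
  type-I-error null. The cap concentrates curvature at the vertex: a profile
  that is near-flat right of 0.75 has no localizable vertex at any
  bootstrap size.
- **Out-of-range days**: 23.4% of days are perturbed to raw ratios outside
  (0, 1) — 70% above 1, 30% below 0, mimicking negative nocturnal LE. The
  coupled variables of those days still follow the latent in-range RATIO, so
  the filter removes exactly the days it should.
- **Water balance**: every site-day closes `P = ΔSWC + LE_water + R` by
  construction, with runoff a fixed 40% of precipitation and LE converted to
  mm via a fixed latent heat of 2.45 MJ kg⁻¹.
- **Half-hourly realization** (`simulate_half_hourly()`): the daily latent
  RATIO is realized by a diurnal LE profile shaped by potential radiation
  (day) and uniform (night); per-period aggregates reproduce the daily
  generator's values exactly, so the summarizer can be tested end to end.

What the generator does **not** emulate: gap patterns and quality-flag
structure, storage-flux corrections, advection, energy-balance closure gaps,
seasonal phenology of the couplings, spatially correlated weather, or
autocorrelated noise. Passing recovery tests on this generator therefore
demonstrates that the estimators are correct and well-calibrated for clean
tabular inputs of realistic size and noise — not that the scientific
conclusions would survive every artifact of real tower data.

## Numerical conventions and degenerate inputs

- Bins are half-open `[a, b)` with the last bin closed; a ratio exactly on an
  interior edge belongs to the right bin.
- Aggregation is permutation-invariant; bootstrap records are canonically
  ordered by (site, date) before sampling, and per-bin seeds derive from the
  global seed, so results are invariant to input row order and each bin is
  independently reproducible.
- A monotone coupling curve returns its domain boundary from
  `peak_location()` with an explicit flag rather than silently.
- Days with a zero whole-day LE sum have an undefined ratio (`NA`) and are
  excluded from the filter's denominator.
- Polar days and nights (no partition possible) spread LE uniformly in the
  half-hourly realization; `summarize_daily()` handles all-day and all-night
  days without special cases.
- Mapping groups with fewer than 3 pairs or zero variance report `r = NA`
  with a reason string instead of failing.

## Problem sizes used by the packaged checks

The test suite runs networks of 2–15 sites over 1–18 years; the acceptance
script runs the full default network (30 sites × 18 years ≈ 197,000
site-days), 200-bin coupling fits for all 15 variables, cross-hemisphere
mapping, and 50-bin bootstrap trend curves at B = 200 with samples of 4,000
records. B = 200 (rather than the 1,000 a production analysis would use)
keeps the bootstrap stage under a minute per variable; the per-bin medians it
feeds to the feature estimators are already stable at that size.

## Known limitations

- The daytime definition is radiation-based; a GPP-based photosynthetic
  period would differ at high latitudes in winter.
- `wuei_gpp` divides by the daytime LE sum and is undefined when that sum is
  not positive.
- The wetness index depends on the PET formula; Hargreaves is a stand-in
  choice and is reported as such in outputs.
- Driver importances are predictive, not causal; strongly RATIO-coupled
  covariates (e.g. VPD) dominate the ranking on the default generator by
  construction.
- The effect classifier predicts sign-and-strength classes, not °C
  magnitudes.
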