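---
title: "Methods: fire-sourced air pollution estimation and exposure mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fire-sourced air pollution estimation and exposure mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firesmoke)
```

## The estimation model

Paired chemical-transport-model (CTM) simulations — one with fire emissions,
one without — give a daily all-source concentration `C_chem_total` and a
fire-sourced component `C_chem_fire` on a coarse grid. Both are biased and
far too coarse for exposure work. The package's estimation chain makes three
assumptions, one per step:

1. *Downscaling is interpolation.* The coarse field varies smoothly enough
   between cell centers that inverse-distance-weighted (IDW) interpolation
   to 0.25° centers is adequate. IDW cannot create variance, so all
   sub-coarse-cell structure in the final product must come from the
   calibration covariates.
2. *CTM bias is learnable.* The discrepancy between the downscaled field
   and station observations is a (possibly nonlinear) function of the
   downscaled value itself, local meteorology, location and calendar. A
   random forest on 17 such predictors absorbs it. This is the only fitted
   component of the pipeline.
3. *The fire share survives calibration.* Calibration corrects the total;
   the with/without-fire *ratio* of the CTM is taken as trustworthy, so the
   fire-sourced estimate is `C_est_fire = C_est_total × (C_chem_fire /
   C_chem_total)`. Wherever `C_est_total > 0` the identity
   `C_est_fire / C_est_total = C_chem_fire / C_chem_total` holds exactly,
   and the test suite asserts it at every cell-date.

Negative fire-sourced O3 is physically meaningful (fire plumes can titrate
ozone) and is retained through attribution; the exposure layer treats
negative fire values as non-qualifying for the 50% share rule.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| IDW power `p` | 2 | — | conventional inverse-square decay |
| IDW neighbours `k` | 4 | cells | the four surrounding coarse centers |
| coincidence tolerance | 1e-6 | degrees | exact copy at coincident centers |
| trees | 500 | — | stable forest averages |
| `mtry` | tuned over {3, 5, 7, 9} | — | 10-fold CV RMSE, or pinned |
| min leaf size | 5 | rows | regression default |
| PM2.5 guideline | 15 | µg m⁻³ | WHO 2021 daily guideline |
| O3 guideline | 100 | µg m⁻³ | WHO 2021 daily max-8h guideline |
| fire share | 0.5 | — | "substantial" = at least half |
| annual completeness | 0.75 | — | cell-year means need 75% of days |
| station R² minimum | 30 | days | avoid unstable per-station R² |

IDW distances are great-circle kilometres, not degrees: at high latitude a
degree of longitude shrinks, and degree-space weighting would overweight
zonal neighbours. The guideline thresholds are read strictly ("exceeds"
means `>`) and the share inclusively (`≥ 0.5`); both are configurable in
`pipeline_config()` under `sfap:`.

## Conventions chosen where the problem is underdetermined

Several operational details admit no single canonical choice; the package
fixes them once, documents them here, and keeps them configurable where
sensible:

* **Local time.** Each cell's local day is UTC + `round(lon/15)` hours.
  This is reproducible without a timezone database and never more than
  ~30 min from solar time; political timezones can differ by more.
* **MDA8.** The daily maximum 8-h ozone mean scans the 24 windows starting
  at each local hour, borrowing up to 7 h from the next day; a window needs
  6 of 8 hours, a day needs 18 of 24 windows. These completeness rules
  follow common regulatory practice for this metric.
* **Relative humidity.** Magnus–Tetens with constants (17.625, 243.04),
  clipped into (0, 100]; dew points above the temperature are clipped to
  100% with a warning.
* **Station–grid linkage.** A station belongs to the cell whose center is
  nearest; a point exactly on a shared edge goes to the lower index. The
  lon/lat predictors are station coordinates at training time and cell
  centers at prediction time.
* **Cluster count selection.** "Minimize within-group sum of squares" is
  monotone in k, so it cannot select k by itself; when a range of k is
  supplied the elbow rule (maximum second difference of the WSS curve) is
  used, and k can always be pinned.
* **Fire fraction at zero.** `C_chem_total = 0` gives fraction 0 (no fire
  signal attributable); fractions outside [−1, 1] are clipped with a count
  attached to the result rather than silently.
* **Smoke background.** Smoke PM2.5 is floored at 0, and non-smoke days
  are 0 by definition; the background is the station-and-month median of
  non-smoke days over the previous, current and next years.
* **Trend fitting.** Plain OLS on annual values with a two-sided t-test,
  no autocorrelation correction; annual cell values are calendar-year means
  subject to the 75% completeness rule.

## The synthetic world

`make_world()` generates every input the pipeline consumes, from one seed
with named substreams per component:

* **Truth.** A smooth spatial baseline times a seasonal cycle, plus
  episodic fire plumes: Gaussian spatial kernels (σ ~ U(0.5°, 1.1°)) with
  half-sine temporal profiles, log-normal peak amplitudes, and Poisson
  event counts. O3 plume amplitudes are proportional to PM amplitudes and
  negative in a configurable fraction of events.
* **Coarse CTM analogue.** The block mean of truth times a smooth
  multiplicative spatial bias field (amplitude 0.3 by default) plus
  additive noise; the fire component is noised only where a fire signal
  exists, so a fire-free world yields an exactly zero chem fire field.
  With bias and noise switched off the coarse fields equal the block means
  exactly — the conservation property the tests check at 1e-10.
* **Covariates.** Ten meteorological fields with smooth spatial modes,
  seasonal cycles and AR(1) daily anomalies. The truth background is a
  smooth nonlinear function of them (quadratic temperature response, wind
  dilution, humidity and precipitation scavenging terms), so a flexible
  regressor genuinely can out-predict the raw coarse field — the
  structure the calibration-gain experiment requires.
* **Stations.** A clustered point process (cluster centers + Gaussian
  scatter) mimicking the density imbalance of real monitoring networks.
  Observations are truth at the station's cell plus N(0, σ²) noise floored
  at zero, with the *effective* noise recorded so `obs = truth + noise`
  holds exactly.
* **Population.** Log-normal integer counts per cell, partitioned into
  contiguous countries (nearest of n seeded centers), with reference
  totals deliberately ≠ raster sums so the adjustment step has work to do.
* **Planted footprint.** At generation time a deliberately plain per-cell
  scan (independent of the exposure module's vectorized code) records the
  exact SFAP person-days, category decomposition and people exposed per
  calendar year from the truth fields and the unadjusted integer
  population. The exposure module must reproduce these integers exactly.

What the generator does *not* emulate: atmospheric transport (plumes do not
advect), emission inventories, terrain effects, station data gaps and QC
artefacts, or population dasymetrics. Passing tests therefore demonstrate
the correctness and internal consistency of the pipeline's operations and
the learnability claim under its assumptions — not the accuracy of any
real-world product.

## Evaluation studies and problem sizes

The default synthetic world is 40 × 60 cells (0.25°) nested in a 5 × 6
coarse grid, two years of days, 120 stations per pollutant and 8 countries.
The replicated studies use smaller worlds chosen so the full suite runs
comfortably on a single CPU:

* `calibration_gain_study()`: twenty 24 × 30-cell, 180-day worlds with 36
  PM2.5 stations, 100-tree forests, spatial tenfold CV and 6-cluster
  leave-one-cluster-out CV. The expected pattern — calibrated out-of-sample
  R² above the raw downscaled field's in at least 19 of 20 replicates, and
  cluster-CV at or below tenfold CV on average — is the package's central
  qualitative claim, and is scale-free: it expresses that the covariates
  carry recoverable signal and that leaving out whole regions is harder
  than leaving out interleaved stations.
* `trend_recovery_study()`: 200 twenty-year annual series with a planted
  0.5-per-decade slope and unit noise; the 95% CI of the fitted slope
  should cover the planted value ~95% of the time.
* `trend_type1_study()`: a 1000-cell null world; the per-cell p < 0.05
  rate should sit within sampling error of 0.05.

## Known limitations

* IDW transfers coarse-cell bias structure into the fine field; the
  calibration can only correct it where covariates are informative.
* The ratio-scaling step inherits the CTM's fire fraction unchanged: any
  bias in the *partitioning* between fire and non-fire sources (as opposed
  to the total) propagates directly into `C_est_fire`.
* Random-forest predictions cannot extrapolate beyond the training
  response range, which truncates extreme plume peaks in regions far from
  any station.
* `people_exposed` counts whole-cell populations; gridded inputs admit no
  finer rule, and the metric is therefore resolution-dependent.
* The within-R² demeaning assumes the two fixed-effect groupings are
  crossed, not nested; nested groupings absorb the estimate and return
  `NaN` with a diagnostic.
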