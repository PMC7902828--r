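---
title: "Fire-deforestation decoupling diagnostics: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fire-deforestation decoupling diagnostics: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amazonfire)
```

## The scientific problem

Fires in the Brazilian Amazon biome come in three anthropogenic kinds:
deforestation fires (piled forest-clearing residue burned repeatedly over
days), maintenance fires (pasture/cropland upkeep, light fuels consumed in a
single burn), and forest understory fires (unintended, drought-sensitive,
low intensity). The *decoupling hypothesis* holds that total fire activity
detached from deforestation as annual clearing collapsed after 2004, with
drought-driven understory burning taking over. Testing it requires a chain
of measurable quantities: typed fire counts, trend tests, the
fires-per-area-deforested ratio, anomaly extents, intensity percentiles, and
emission trends. This package implements that chain as composable stages
with a synthetic generator providing ground truth for every one of them.

## The classification model

The unit of classification is the **pixel-year**, because persistence — the
number of *distinct detection days* on a pixel within a year — is the
primary discriminator. Same-day duplicate detections (multiple satellite
overpasses) never count twice. The rules, applied in order:

1. **deforestation** iff days ≥ 2 and annual deforestation rate ≥ 5% (5%
   being the smallest clearing the annual deforestation product resolves);
2. otherwise **forest** iff days ≤ 3, year-2000 tree cover ≥ 70%, and
   cumulative deforestation since 2001 ≤ 20%;
3. otherwise **maintenance**.

Pixel-years with 2–3 days can satisfy both rule 1 and rule 2; the stated
order (deforestation first) resolves the overlap, and
`classify_all(precedence = )` lets a sensitivity analysis flip it. All
thresholds are fields of `classification_thresholds()`, in percent and days,
and boundary values are inclusive exactly as written above. Persistence
counting defaults to the calendar year; a `window = "season"` mode restricts
it to the configured dry-season months, since both conventions appear in
field practice and neither is canonical.

## Trend and regression machinery

* `mann_kendall()` implements the two-tailed test with the standard
  tie-corrected variance and the ±1 continuity correction. For tie-free
  series up to n = 25 it also computes the exact permutation p-value
  P(|S| ≥ |s|) from the inversion-count distribution and uses it for the
  significance flag: at n = 17 the attainable level just below 0.05 is
  0.0422, so an exact decision is both feasible and preferable at study
  lengths. Annual-count trends are tested at α = 0.01 by convention;
  everything else at 0.05. No autocorrelation correction (prewhitening) is
  applied — out of scope by design.
* `theil_sen()` returns the median of pairwise slopes; the intercept uses
  the `median(y − slope·t)` convention, and rank-based 95% confidence limits
  are reported as such (interval conventions differ across the literature,
  so the level is stated rather than implied).
* `ols_regression()` is a thin wrapper over `lm()` reporting slope, R², and
  the two-sided slope t-test; phases with three usable years are flagged
  `low_n` (a 3-point regression has essentially no power), and phases with
  fewer are `testable = FALSE` rather than dropped.

## Anomalies, intensity, modes

**Anomaly extent.** `standardize()` z-scores each pixel's annual counts
against a reference window (sample SD, n−1, configurable to population).
Pixels with zero variance — including pixels that never burn — carry no
anomaly and are masked; `extent_above()` therefore reports the exceedance
share both over the valid pixels (default reading) and over the whole grid,
since the biome-scale denominator is a genuine ambiguity. Exceedance is
strict (z > threshold).

**FRP.** Percentiles use linear interpolation between order statistics
(`quantile()` type 7; values 1..10 → 9.1 at the 90th). Densities are
estimated on log FRP with the default data-driven bandwidth, transformed
back, and renormalized to integrate to exactly 1; they are descriptive and
never feed other stages. The breakpoint fit constrains the two segments to
meet at the knot (the standard segmented-regression reading of a
"linear model with a break point"); a discontinuous mode is available behind
a flag, where the fit partitions years disjointly (knot with the pre-branch)
so the nested-SSE property against the continuous fit holds, while the
per-branch Mann–Kendall tests include the knot year on both sides, as
sub-periods are conventionally printed. SSE ties across candidates break to
the earliest year and raise a `no_break` flag.

**EOF/PCA.** The decomposition runs on the years × valid-pixels matrix (the
temporal-covariance orientation — natural when 17 years face thousands of
pixels) via SVD, with variance fractions from squared singular values. The
sign convention — largest-magnitude loading positive — makes results
deterministic across platforms; no rotation is applied. Inputs reuse the
same standardization as the anomaly stage (one implementation, one formula).

## [CO] analyses

The [CO] trend uses the OLS-on-time framing (R² with p), matching how
emission trends are conventionally reported; Mann–Kendall remains available
on the same series. `window_adjust()` recomputes one year's annual mean over
a shifted 12-month window (e.g. April–March for a late-onset season) and is
applied before any sensitivity scan when both are used.
`sensitivity_scan()` multiplies designated years by (1 − k/100) in steps
(default 5%) and reports the smallest k making the trend significant —
operationalizing imported-emission corrections exactly as a k% discount,
with no transport modeling.

## The synthetic generator

`synthetic_config()` defaults encode the study conditions: a 60 × 60 km
1-km grid, years 2003–2019, drought years 2005/2007/2010/2015, a type mix of
8/39/53% (deforestation/maintenance/forest), an 8% annual decline in
expected detections, and drought multipliers of 1.1/1.8/2.2 — droughts
amplify understory and maintenance burning far more than clearing fires.
Landscape strata are disjoint by construction (clearing fronts with per-year
rates ≥ 5%, intact high-cover pixels, low-cover pasture), so a correct
classifier recovers truth labels exactly; overlapping-rule landscapes exist
only as explicit adversarial fixtures in the tests. FRP is lognormal per
type with a deliberately heavier deforestation tail (FRP90 roughly four
times the forest value), scaled by a V-shaped log-linear time signal with
its knot at 2013 (−5%/+5% per year) so the intensity breakpoint has ground
truth. [CO] is affine in annual totals plus Gaussian noise, resampled to
stay positive. One root seed drives fixed child streams (1 landscape, 2
seasons, 3 [CO]), making every product bit-reproducible.

What the generator does **not** emulate: cloud/overpass gaps, spatial
autocorrelation of weather, fire spread, a declining deforestation series
(the front is stationary by construction, so per-year clearing varies only
stochastically), or detection-confidence filtering. Passing tests therefore
demonstrate the correctness and calibration of the *methods*, not the
reproduction of archive-derived magnitudes; quantities that depend on those
archives (e.g. the absolute count trend, phase R² values) are reported as
computed on synthetic conditions.

## Numerical choices and degenerate inputs

* Grid indexing is 1-based, row-major, north-up (the R matrix idiom), with
  half-open cell membership.
* Constant series: Mann–Kendall returns S = 0, p = 1, flagged degenerate;
  OLS on zero-variance predictors errors rather than returning NaN; ratio
  series error on non-positive deforested area, naming the year.
* Zero-variance pixels are masked and counted, never silently dropped.
* Densities renormalize by the trapezoid rule; groups under 30 values fall
  back to a histogram estimate with a warning.
* Type-I calibration of the trend test is checked at n = 30, where the exact
  size of the continuity-corrected test is 0.0491 (by enumeration); at
  n = 17 the discreteness of S caps any valid test at size 0.0422, so a
  0.05-centered calibration band would be testing the wrong premise there.
* Simulation sizes in the test suite (500-seed slope recovery, 200-seed
  breakpoint and drought-separation checks on a 30 × 30 grid with 400
  expected detections per year) were fixed alongside the study conditions to
  keep the suite fast while leaving Monte-Carlo margins wide.

## Known limitations

* No prewhitened/autocorrelation-corrected trend variants; annual series of
  length ≤ 17 rarely justify them, but strongly autocorrelated inputs will
  inflate significance.
* The raster dialect is plain CSV matrices (long format); no
  GeoTIFF/NetCDF/CRS handling, and only block-aggregation with an integer
  factor is provided for fine-resolution products.
* The sensitivity scan explores proportional reductions of whole years only,
  exactly as the correction it operationalizes.
* No supervised fire-type classification; the rule-based typing is the
  object of study here.
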