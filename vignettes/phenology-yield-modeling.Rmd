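---
title: "Corn phenology metrics and county yield models from NDVI time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corn phenology metrics and county yield models from NDVI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoyield)
```

## The problem

County corn yields correlate with *when* and *how fast* the crop moves
through its growth stages, not only with how green it gets. This package
implements a satellite workflow that turns 8-day composite NDVI series into
county-level phenological predictors and yield regressions:

1. **Pixel preparation.** NDVI = (NIR − red)/(NIR + red) from 8-day
   maximum-value composites (MVC) is smoothed with a Savitzky–Golay filter,
   interpolated to daily resolution with a cubic spline, truncated to the
   growing season between the valley minima flanking the single seasonal
   peak (SD/ED), and re-indexed as days-since-SD ("phenological
   adjustment").
2. **County aggregation.** Pixels whose corn fraction exceeds 0.70 are
   averaged, weighted by that fraction, on the days-since-SD axis.
3. **Stage dates and metrics.** Five stage dates are extracted per
   county-year: V1 (emergence) and VT (tasseling) as the 10% and 90%
   dynamic-threshold crossings of the rising limb (relative to NDVI at SD
   and the maximum), R4 (dough) as the 10% drop below the maximum on the
   falling limb (relative to NDVI at ED), and V6 (jointing) / R6 (maturity)
   as the inflections −a/b of a piecewise logistic fit
   NDVI(t) = c/(1 + e^(a+bt)) + d to each limb. The four growth phases
   GP1 = V1–V6, …, GP4 = R4–R6 give eight metrics: durations
   (GPend − GPstart, days) and rates ((NDVI_end − NDVI_start)/duration,
   NDVI day⁻¹). A ninth predictor, Max-R², is the NDVI value at the
   days-since-SD index whose cross-sample correlation with yield is
   largest.
4. **Models.** Per region group (whole / semi-arid / non-semi-arid):
   best univariate fits (linear, quadratic, logarithmic), stepwise multiple
   linear regression with standardized coefficients and variance inflation
   factors (VIF = 1/(1 − R²ᵢ), < 4 read as non-collinear), and
   leave-one-year-out cross-validation (per-fold predictive R² and RMSE).

Everything is driven by a synthetic-data generator with analytic ground
truth, so each stage is tested by *recovery* rather than by fiat.

## The generator and what it emulates

Each pixel-year follows a double logistic,

NDVI(t) = base + A·[σ(k₁(t − m₁)) − σ(k₂(t − m₂))],

whose rising/descending inflections sit exactly at the midpoints m₁, m₂ —
so true V6 and R6 are analytic, and the remaining true dates come from
root-finding on the same curve (season onset is defined as the crossing of
base + 1% of A). Counties draw parameter means from uniform priors
(base 0.16–0.24, amplitude 0.45–0.68, green-up midpoint DOY 150–172 at
steepness 0.09–0.14 day⁻¹, senescence midpoint DOY 246–268 at 0.08–0.12
day⁻¹); years perturb them (midpoints sd 5 d, steepness sd 0.005,
amplitude sd 0.03, base sd 0.01); pixels within a county-year share the
curve up to a planting-date shift (sd 3 d) and carry a corn fraction
drawn from U(0.4, 1).

Observation model: additive Gaussian noise (sd 0.015 NDVI) on every daily
sample plus, with probability 0.15 per day, a cloud-like −0.3 NDVI bias.
The 8-day MVC keeps each window's maximum, which suppresses the negative
outliers — the mechanism under test — and records the acquisition day of
the retained maximum, as MODIS composites do in their day-of-year layer;
daily interpolation is anchored at those days, which removes the
window-start timing bias on the rising limb. The real noise magnitude is
not known from the study data; these values are **assumptions**, chosen
once as plausible for clear-sky 250-m reflectance with imperfect cloud
screening, and are exposed in `sim_config()`.

Yields are generated per county-year as a linear function of the *true*
metrics using the whole-region stepwise equation structure
(+GP2D, +GP2R, +GP3D, −GP4R, intercept −10084.25 kg ha⁻¹), with Gaussian
noise calibrated so the generating model explains about 65% of yield
variance at n = 300. The *realized* generating R² — the fit of the
generating model on the panel's true metrics — is recorded and is the
correct yardstick for end-to-end recovery, since sampling variation moves
it a few points around the target in any finite panel.

What the generator does **not** emulate: spatially correlated weather
shocks (the 2012-drought kind of year), mixed-pixel spectral
contamination beyond a scalar corn fraction, snow/soil background effects,
multi-modal seasons (double cropping), or any geography — the
semi-arid/non-semi-arid split is carried as a plain grouping column.
Passing recovery tests therefore shows the *estimator chain* is unbiased
and tight under the stated noise model, not that real MODIS series meet
those assumptions.

## Numerical and design choices

* **Savitzky–Golay defaults: window 5 composites, order 2.** The source
  study names the filter but not its parameters. Window 5 (40 days) is the
  smallest symmetric window that suppresses single-composite spikes without
  flattening the seasonal peak; order 2 preserves curvature. Larger windows
  (7+) visibly bias the peak and push noise-free threshold dates ~2 days
  off, so precision under noise is bought with pixel numbers instead.
* **Cubic spline: `stats::spline(method = "fmm")`**, which interpolates the
  knots exactly and reproduces cubic polynomials. A natural spline (zero
  end curvature) cannot reproduce a cubic and distorts the series ends
  where season detection operates.
* **Season detection.** The valley bottom on each side of the peak is the
  limb's deepest point; SD (ED) is the last (first) day still within 1% of
  the valley-to-peak range above the valley floor, checked against a
  near-zero second-difference band (|Δ²NDVI| ≤ 1e−4 day⁻², configurable).
  With noisy input the floor is the median of the near-bottom days and the
  band widens to 5× the noise scale estimated from the smoothing residuals
  — otherwise a single noise minimum defines the valley and the detected
  day wanders by a week or more. With zero noise the pure 1% rule applies,
  matching the ground-truth onset definition.
* **Threshold crossings** are linearly interpolated between days and
  rounded half-up to integer days; V6/R6 are likewise rounded, making all
  durations integers.
* **Logistic fits** (Levenberg–Marquardt, `minpack.lm`) are initialized at
  d = min, c = range, midpoint at the half-range crossing, slope from the
  steepest secant (peak logistic slope is −bc/4), with the sign of b fixed
  per branch; non-convergence or c ≈ 0 (flat limb) is an error that drops
  the county-year with a recorded reason.
* **Aggregation axis.** Pixels are averaged on days-since-SD (each pixel's
  own SD at index 0), the common length being the shortest pixel season;
  the county SD used to map back to calendar DOY is the weighted mean of
  pixel SDs. The source text adjusts per pixel before county computation
  but does not state the axis; this convention is ours, and ground truth
  for a county series is accordingly the county curve shifted by the
  selected pixels' weighted mean planting shift.
* **Stepwise regression**: forward–backward by partial-F p-values
  (p_enter = 0.05, p_remove = 0.10), with a VIF guard — a candidate whose
  entry would push any VIF above 4 never enters. The guard implements the
  study's pairing of stepwise selection with VIF < 4 non-collinearity and
  keeps aliased duration/rate twins from co-entering.
* **Predictive R² in CV** is the squared Pearson correlation between
  predicted and observed in the held-out year (`r2_method = "rsq"` gives
  1 − SSE/SST instead). Folds with fewer than 3 counties are skipped with
  a warning.
* **Max-R² scan** runs at daily resolution on the adjusted axis (stride
  configurable to 8 for composite resolution); ties go to the earliest day.
* **Multi-peak series** fail loudly by default; `allow_multiple = TRUE`
  brackets the highest peak (its ED is then the valley after that peak).

### A note on aliased metrics

Under the double-logistic family, GP1 and GP2 both span fixed quantiles of
the same rising branch, so GP1D ≡ GP2D and GP1R ≡ GP2R in truth; extraction
noise breaks the tie arbitrarily, and the stepwise model may retain either
twin. Recovery of coefficient *signs* is therefore judged on retained
variables that have a nonzero generating coefficient. This aliasing is a
property of the generator's curve family, not of real corn NDVI, where the
emergence and jointing phases are shaped by different processes.

## Problem sizes

The default panel is 30 counties × 10 years × 16 pixels (300 county-years),
matching the regression sample size the recovery analysis targets while
staying desk-scale; the phenology-recovery analysis uses 50 noise-free
single-year counties; the end-to-end recovery study repeats the full
pipeline over 50 independently seeded panels. Real counties contain
thousands of eligible 250-m pixels; 16 per county is a deliberate
down-sample, and county-series noise (hence metric attenuation) shrinks
roughly with its square root.

## Known limitations

* Detected SD is biased late by a few days under noise (the detection band
  sits above the 1% onset); stage dates inherit a consistent per-panel
  bias of −4…+3 days. Regression metrics are differences of dates, so the
  shared component cancels; absolute-date applications should calibrate.
* The extracted model R² sits 0.02–0.07 below the realized generating R²
  (errors-in-variables attenuation); the recovery study quantifies this
  gap rather than pretending it away.
* `GP3R` is ≈ 0 by construction (the phase straddles the peak), mirroring
  its negligible univariate R² in the source study; it carries no signal
  here.
* Season detection assumes a single-peaked season; winter cover crops or
  double cropping would need the multi-peak override plus manual review.
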