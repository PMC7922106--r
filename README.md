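# phenoyield

Corn-yield prediction from the *timing* of crop development, not just its
greenness. `phenoyield` implements a county-scale remote-sensing workflow:
8-day maximum-value-composite (MVC) NDVI series are smoothed
(Savitzky–Golay), splined to daily resolution, truncated to the growing
season and re-indexed from its start ("phenologically adjusted");
corn-dominated pixels (corn fraction > 0.70) are aggregated to county
series by fraction-weighted averaging; five stage dates are extracted —
emergence (V1), jointing (V6), tasseling (VT), dough (R4), maturity (R6) —
and turned into eight growth-phase metrics plus a maximum-correlation NDVI
predictor; finally, yields are modeled with univariate and stepwise
multiple regressions, standardized coefficients, variance inflation
factors, and leave-one-year-out cross-validation (LOYO-CV).

It is written for crop-monitoring and agro-remote-sensing researchers who
want the full estimator chain as tested, reusable functions, driven by a
synthetic landscape generator whose phenological ground truth is analytic.

## The model in brief

* NDVI = (NIR − red)/(NIR + red); 8-day MVC keeps each window's maximum
  (suppressing cloud-depressed values) and the day it was acquired.
* Stage dates on the county daily series: V1 and VT are the rising-limb
  crossings of NDVI_SD + 0.1·(NDVI_max − NDVI_SD) and + 0.9·(…); R4 is the
  falling-limb crossing of NDVI_max − 0.1·(NDVI_max − NDVI_ED); V6 and R6
  are the inflections t = −a/b of piecewise logistic fits
  NDVI(t) = c/(1 + e^(a+bt)) + d to the rising and falling limbs.
* Growth phases GP1 = [V1,V6], GP2 = [V6,VT], GP3 = [VT,R4], GP4 = [R4,R6];
  per phase, Duration = GPend − GPstart and
  Rate = (NDVI_GPend − NDVI_GPstart)/Duration.
* Max-R² = the NDVI value at the days-since-SD index maximizing the
  cross-sample R² with yield.
* Stepwise regression (p_enter 0.05 / p_remove 0.10, VIF-guarded at 4)
  with βᵢ* = βᵢ·sd(Xᵢ)/sd(Y); VIFᵢ = 1/(1 − Rᵢ²); LOYO-CV reports per-year
  predictive R² and RMSE (kg ha⁻¹).

## Worked example

```r
library(phenoyield)

cfg <- sim_config(n_counties = 10, pixels_per_county = 6,
                  years = 2010:2015, seed = 7)
res <- run_pipeline(cfg, groups = "whole")
m <- res$models$whole
print(m$pheno)
print(m$cv)
```

```
Stepwise linear model (n = 54)
  variables: gp4r, gp4d, gp2d, gp1r, gp3r, gp3d
  R^2 = 0.713
  standardized coefficients:
  gp4r   gp4d   gp2d   gp1r   gp3r   gp3d
-0.609  0.313  0.354  0.461  0.275  0.218
  VIF:
gp4r gp4d gp2d gp1r gp3r gp3d
3.43 2.42 1.57 2.70 1.35 1.33
Leave-one-year-out cross-validation (6 folds)
  median R^2 = 0.743  median RMSE = 1549.7
```

Reading this: six of the eight phenological metrics entered the stepwise
model; a faster early green-up (`gp1r`), longer jointing-to-tasseling and
dough phases (`gp2d`, `gp4d`) and a steeper senescence (`gp4r` is negative,
so a more negative rate raises yield) predict higher yields, together
explaining 71% of county-year yield variance (the panel's generating model
explains 69%, so the extraction chain loses little). All VIFs are below 4
(no collinearity problem) and held-out years are predicted with median
R² = 0.74 at a median error of ~1550 kg ha⁻¹.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the study flow end to end and
write their tables under `results/` (the simulated panel itself goes to
`scratch/panel/`):

```sh
Rscript analysis/01_simulate_panel.R     # synthetic landscape + yields
Rscript analysis/02_extract_phenology.R  # stage dates + metrics, recovery report
Rscript analysis/03_yield_models.R       # univariate table, stepwise models
Rscript analysis/04_cross_validation.R   # LOYO-CV, regional date agreement
```

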