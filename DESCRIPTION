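Package: phenoyield
Title: Corn Phenology Metrics and Yield Prediction from NDVI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts corn phenological stage dates (emergence, jointing,
    tasseling, dough, maturity) from 8-day NDVI composite time series via
    maximum-value compositing, Savitzky-Golay smoothing, cubic-spline daily
    interpolation, dynamic-threshold and piecewise-logistic inflection dating;
    computes per-phase duration and rate metrics plus a maximum-correlation
    NDVI predictor; and fits univariate and stepwise multivariate county-level
    yield regressions with standardized coefficients, variance inflation
    factors, and leave-one-year-out cross-validation. Includes a synthetic
    landscape generator with analytic phenological ground truth so every
    stage of the pipeline is testable by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
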