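#!/usr/bin/env Rscript
# Step 3 — yield regression models.
#
# From the modeling table of step 2: (a) the best univariate fit (linear /
# quadratic / logarithmic) of yield on each predictor, per region group;
# (b) stepwise multiple regressions on the eight phenological metrics and
# on metrics + Max-R^2, with standardized coefficients and VIFs. Writes
# results/univariate_r2.csv and results/stepwise_models.txt.

library(phenoyield)

metrics <- utils::read.csv("results/metrics.csv")
metric_names <- c("gp1d", "gp1r", "gp2d", "gp2r", "gp3d", "gp3r",
                  "gp4d", "gp4r")
groups <- c("whole", "semi_arid", "non_semi_arid")

uni <- do.call(rbind, lapply(groups, function(g) {
  tab <- if (g == "whole") metrics else metrics[metrics$region_group == g, ]
  do.call(rbind, lapply(c(metric_names, "maxr2_ndvi"), function(v) {
    f <- fit_univariate_best(tab[[v]], tab$yield_kg_ha)
    data.frame(region = g, predictor = v, family = f$family,
               r2 = round(f$r2, 3), significant = f$significant)
  }))
}))
utils::write.csv(uni, "results/univariate_r2.csv", row.names = FALSE)
cat("Best univariate R^2 by region (top 3 predictors):\n")
for (g in groups) {
  u <- uni[uni$region == g, ]
  u <- u[order(-u$r2), ][1:3, ]
  cat(" ", g, ":", paste(sprintf("%s %.2f (%s)", u$predictor, u$r2,
                                 u$family), collapse = ", "), "\n")
}

con <- file("results/stepwise_models.txt", "w")
for (g in groups) {
  tab <- if (g == "whole") metrics else metrics[metrics$region_group == g, ]
  m1 <- stepwise_regression(tab, metric_names)
  m2 <- stepwise_regression(tab, c(metric_names, "maxr2_ndvi"))
  for (lab_m in list(c("metrics only", "m1"), c("metrics + Max-R2", "m2"))) {
    m <- get(lab_m[2])
    writeLines(sprintf("[%s | %s] R^2 = %.2f; vars: %s", g, lab_m[1], m$r2,
                       paste(m$variables, collapse = ", ")), con)
    writeLines(sprintf("  standardized: %s",
                       paste(sprintf("%s=%.2f", names(m$standardized),
                                     m$standardized), collapse = ", ")), con)
    if (!is.null(m$vif))
      writeLines(sprintf("  VIFs < %.2f", max(m$vif) + 0.005), con)
  }
  cat(sprintf("%s: metrics-only R^2 = %.2f; with Max-R^2 R^2 = %.2f\n",
              g, m1$r2, m2$r2))
}
close(con)
cat("Wrote results/univariate_r2.csv and results/stepwise_models.txt\n")
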