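#!/usr/bin/env Rscript
# Step 4 — model evaluation.
#
# Leave-one-year-out cross-validation of the stepwise metrics model per
# region group (per-fold R^2 and RMSE with boxplot-style summaries), and
# agreement
# of the extracted stage dates with the generator's analytic truth
# aggregated to regional means (the satellite-vs-survey comparison of the
# real study). Writes results/cv_folds.csv and results/date_agreement.csv.

library(phenoyield)

metrics <- utils::read.csv("results/metrics.csv")
dates <- utils::read.csv("results/stage_dates.csv")
panel <- read_panel_csvs("scratch/panel")
truth <- county_truth_aligned(panel)
metric_names <- c("gp1d", "gp1r", "gp2d", "gp2r", "gp3d", "gp3r",
                  "gp4d", "gp4r")

folds <- list()
for (g in c("whole", "semi_arid", "non_semi_arid")) {
  tab <- if (g == "whole") metrics else metrics[metrics$region_group == g, ]
  mod <- stepwise_regression(tab, metric_names)
  cv <- loyo_cv(tab, mod$variables)
  f <- cv$folds
  f$region <- g
  folds[[g]] <- f
  cat(sprintf("%s: LOYO-CV median R^2 = %.2f (IQR %.2f-%.2f), median RMSE = %.0f kg/ha\n",
              g, cv$summary$r2[[2]], cv$summary$r2[[1]], cv$summary$r2[[3]],
              cv$summary$rmse[[2]]))
}
utils::write.csv(do.call(rbind, folds), "results/cv_folds.csv",
                 row.names = FALSE)

# regional-mean emergence (V1) and maturity (R6) vs analytic truth
m <- merge(dates, truth[, c("county_id", "year", "v1_true", "r6_true")],
           by = c("county_id", "year"))
rows <- list()
for (v in c("v1", "r6")) {
  est <- regional_mean_dates(m, v)
  ref <- regional_mean_dates(m, paste0(v, "_true"))
  j <- merge(est, ref, by = c("group", "year"))
  a <- date_agreement(j[[v]], j[[paste0(v, "_true")]])
  rows[[v]] <- data.frame(stage = toupper(v), r2 = a$r2,
                          rmse_days = a$rmse_days, bias_days = a$bias_days,
                          n = a$n)
  cat(sprintf("%s regional means vs truth: R^2 = %.2f, RMSE = %.2f days\n",
              toupper(v), a$r2, a$rmse_days))
}
utils::write.csv(do.call(rbind, rows), "results/date_agreement.csv",
                 row.names = FALSE)
cat("Wrote results/cv_folds.csv and results/date_agreement.csv\n")
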