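#' Write a simulated panel to long-format CSV files
#'
#' Emits `composites.csv` (county_id, pixel_id, year, doy, ndvi),
#' `fractions.csv` (county_id, pixel_id, corn_fraction),
#' `yields.csv` (county_id, year, region_group, yield_kg_ha),
#' `truth_counties.csv`, `truth_pixels.csv`, and the configuration as
#' `config.yaml`.
#'
#' @param panel a [simulate_panel()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_panel_csvs <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE)
  w(panel$composites, "composites.csv")
  w(panel$fractions, "fractions.csv")
  w(panel$yields, "yields.csv")
  w(panel$truth$counties, "truth_counties.csv")
  w(panel$truth$pixels, "truth_pixels.csv")
  write_sim_config(panel$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a panel written by [write_panel_csvs()]
#'
#' @param dir directory containing the CSV files.
#' @return a panel list usable by [run_pipeline()].
#' @export
read_panel_csvs <- function(dir) {
  r <- function(f) utils::read.csv(file.path(dir, f))
  truth_counties <- r("truth_counties.csv")
  cfg <- read_sim_config(file.path(dir, "config.yaml"))
  list(composites = r("composites.csv"),
       fractions = r("fractions.csv"),
       yields = r("yields.csv"),
       truth = list(counties = truth_counties,
                    pixels = r("truth_pixels.csv"),
                    gen_r2 = {
                      vs <- stats::var(truth_counties$yield_true)
                      ns <- stats::var(truth_counties$yield_kg_ha -
                                         truth_counties$yield_true)
                      vs / (vs + ns)
                    }),
       config = cfg)
}

#' Write / read the simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return the path (write) or a `sim_config` (read).
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$yield_betas <- as.list(x$yield_betas)  # keep names in the YAML map
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$yield_betas <- unlist(x$yield_betas)
  do.call(sim_config, x[setdiff(names(x), character(0))])
}

#' Write pipeline stage outputs as CSV plus a plain-text model summary
#'
#' @param result a [run_pipeline()] result.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$dates, file.path(outdir, "stage_dates.csv"),
                   row.names = FALSE)
  utils::write.csv(result$metrics, file.path(outdir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(result$manifest$dropped, file.path(outdir, "dropped.csv"),
                   row.names = FALSE)
  write_sim_config(result$panel$config, file.path(outdir, "config.yaml"))
  con <- file(file.path(outdir, "model_summary.txt"), "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("phenoyield run ", result$manifest$config_hash,
     " (seed ", result$manifest$seed, ")")
  wl("county-years modeled: ", result$manifest$counts$county_years_out,
     " of ", result$manifest$counts$county_years_in,
     " (", result$manifest$counts$dropped, " drops)")
  for (g in names(result$models)) {
    m <- result$models[[g]]
    wl("")
    wl("== region group: ", g, " ==")
    for (kind in intersect(c("pheno", "pheno_maxr2"), names(m))) {
      mod <- m[[kind]]
      eqn <- paste0(
        "Y = ", formatC(mod$coefficients[["(Intercept)"]], format = "f",
                        digits = 2),
        paste0(vapply(mod$variables, function(v) {
          b <- mod$coefficients[[v]]
          paste0(if (b >= 0) " + " else " - ",
                 formatC(abs(b), format = "f", digits = 2), toupper(v))
        }, character(1)), collapse = ""))
      wl("  [", kind, "] ", eqn)
      wl("    R^2 = ", formatC(mod$r2, format = "f", digits = 2),
         if (!is.null(mod$vif))
           paste0("  VIFs < ", formatC(max(mod$vif) + 0.005, format = "f",
                                       digits = 2)) else "")
      if (length(mod$standardized))
        wl("    standardized: ",
           paste(sprintf("%s=%.2f", toupper(names(mod$standardized)),
                         mod$standardized), collapse = ", "))
    }
    if (!is.null(m$cv))
      wl("  [loyo-cv] median R^2 = ",
         formatC(m$cv$summary$r2[[2]], format = "f", digits = 2),
         ", median RMSE = ",
         formatC(m$cv$summary$rmse[[2]], format = "f", digits = 0),
         " kg/ha over ", nrow(m$cv$folds), " folds")
    if (!is.null(m$maxr2))
      wl("  [max-R^2] selected day ", m$maxr2$selected_day,
         " since SD (profile max R^2 = ",
         formatC(max(m$maxr2$profile, na.rm = TRUE), format = "f",
                 digits = 2), ")")
  }
  invisible(outdir)
}
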