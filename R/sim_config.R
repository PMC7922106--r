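#' Configuration for the synthetic NDVI landscape generator
#'
#' Bundles all knobs of the synthetic corn landscape: panel dimensions,
#' per-county priors for the double-logistic seasonal NDVI curve, the
#' observation noise model (additive noise plus cloud-like negative dropout
#' suppressed by 8-day maximum-value compositing), and the yield-generating
#' linear model over the true phenological metrics.
#'
#' Curve priors are uniform ranges from which each county draws its mean
#' parameters; county-year parameters are the county means plus small
#' year-to-year Gaussian perturbations, and pixels within a county-year share
#' the curve up to a planting-date time shift.
#'
#' @param n_counties number of counties.
#' @param pixels_per_county pixels simulated per county.
#' @param years calendar years of the panel.
#' @param corn_fraction_range range of the uniform per-pixel corn fraction.
#' @param curve_priors list of length-2 numeric ranges: `base`, `amplitude`
#'   (NDVI units), `rise_mid`, `fall_mid` (DOY), `rise_steep`, `fall_steep`
#'   (day^-1).
#' @param year_sd list of year-to-year perturbation SDs: `mid` (days),
#'   `steep` (day^-1), `amplitude`, `base` (NDVI).
#' @param planting_shift_sd SD (days) of the within-county pixel planting
#'   shift applied to both logistic midpoints.
#' @param noise_sd additive daily NDVI noise SD.
#' @param dropout_prob probability a daily sample is cloud-degraded.
#' @param dropout_bias NDVI magnitude subtracted from a cloud-degraded sample.
#' @param yield_betas named vector: `intercept` plus coefficients
#'   (kg ha^-1 per metric unit) over a subset of
#'   `gp1d,gp1r,gp2d,gp2r,gp3d,gp3r,gp4d,gp4r`.
#' @param yield_noise_sd county-year yield noise SD (kg ha^-1); if `NULL` it
#'   is calibrated at simulation time so the generating R^2 of the yield
#'   model equals `target_gen_r2`.
#' @param target_gen_r2 target generating R^2 used when `yield_noise_sd` is
#'   `NULL`.
#' @param semi_arid_fraction fraction of counties labelled `semi_arid`
#'   (grouping column only; no climate is simulated).
#' @param seed integer master seed; all pixel/county/year random streams are
#'   derived from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_counties = 30,
                       pixels_per_county = 16,
                       years = 2009:2018,
                       corn_fraction_range = c(0.4, 1),
                       curve_priors = list(
                         base       = c(0.16, 0.24),
                         amplitude  = c(0.45, 0.68),
                         rise_mid   = c(150, 172),
                         rise_steep = c(0.09, 0.14),
                         fall_mid   = c(246, 268),
                         fall_steep = c(0.08, 0.12)
                       ),
                       year_sd = list(mid = 5, steep = 0.005,
                                      amplitude = 0.03, base = 0.01),
                       planting_shift_sd = 3,
                       noise_sd = 0.015,
                       dropout_prob = 0.15,
                       dropout_bias = 0.3,
                       yield_betas = c(intercept = -10084.25,
                                       gp2d = 360.58,
                                       gp2r = 953476.78,
                                       gp3d = 97.00,
                                       gp4r = -102453.38),
                       yield_noise_sd = NULL,
                       target_gen_r2 = 0.65,
                       semi_arid_fraction = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_counties = as.integer(n_counties),
    pixels_per_county = as.integer(pixels_per_county),
    years = as.integer(years),
    corn_fraction_range = as.numeric(corn_fraction_range),
    curve_priors = curve_priors,
    year_sd = year_sd,
    planting_shift_sd = planting_shift_sd,
    noise_sd = noise_sd,
    dropout_prob = dropout_prob,
    dropout_bias = dropout_bias,
    yield_betas = yield_betas,
    yield_noise_sd = yield_noise_sd,
    target_gen_r2 = target_gen_r2,
    semi_arid_fraction = semi_arid_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cp <- config$curve_priors
  needed <- c("base", "amplitude", "rise_mid", "rise_steep",
              "fall_mid", "fall_steep")
  if (!all(needed %in% names(cp)))
    stop("curve_priors must contain: ", paste(needed, collapse = ", "))
  if (config$n_counties < 1)
    stop("n_counties must be at least 1")
  if (config$pixels_per_county < 1)
    stop("pixels_per_county must be at least 1")
  if (length(config$years) < 1)
    stop("at least one year is required")
  fr <- config$corn_fraction_range
  if (length(fr) != 2 || fr[1] > fr[2] || fr[1] < 0 || fr[2] > 1)
    stop("corn_fraction_range must be an interval inside [0, 1]")
  if (any(cp$amplitude <= 0))
    stop("amplitude prior must be positive")
  if (max(cp$rise_mid) >= min(cp$fall_mid))
    stop("green-up midpoint prior must lie entirely before senescence midpoint prior")
  if (config$dropout_prob < 0 || config$dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)")
  if (config$noise_sd < 0) stop("noise_sd must be non-negative")
  if (!all(is.finite(config$yield_betas)))
    stop("yield_betas must be finite")
  if (!("intercept" %in% names(config$yield_betas)))
    stop("yield_betas must include an 'intercept' element")
  bad <- setdiff(names(config$yield_betas),
                 c("intercept", paste0("gp", 1:4, "d"), paste0("gp", 1:4, "r")))
  if (length(bad))
    stop("unknown yield_betas entries: ", paste(bad, collapse = ", "))
  invisible(config)
}

# Deterministic 31-bit sub-seed for the (county, pixel, year) stream.
# Injective for counties < 100, pixels < 100, years < 10007, seeds < 2^31,
# so panels can be extended without re-drawing existing history.
substream_seed <- function(seed, county = 0L, pixel = 0L, year = 0L) {
  h <- (as.double(seed) %% 2147483647) * 1000003 +
    county * 10007 + pixel * 101 + year
  as.integer(h %% 2147483629)
}

with_substream <- function(seed, county = 0L, pixel = 0L, year = 0L, code) {
  withr::with_seed(substream_seed(seed, county, pixel, year), code)
}
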