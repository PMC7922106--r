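#' Double-logistic seasonal NDVI curve
#'
#' The generator and the extractor share the same single-peaked curve family:
#' `NDVI(t) = base + amplitude * (plogis(k1 (t - m1)) - plogis(k2 (t - m2)))`
#' with green-up midpoint `m1 < m2` (senescence midpoint). Its rising and
#' descending inflections sit exactly at `m1` and `m2`, which is what makes
#' jointing (V6) and maturity (R6) ground truth analytic.
#'
#' @param params named list/vector with `base`, `amplitude`, `rise_mid`,
#'   `rise_steep`, `fall_mid`, `fall_steep`.
#' @param day_grid numeric vector of days (DOY) at which to evaluate.
#' @return numeric vector of true NDVI values on `day_grid`.
#' @export
simulate_pixel_curve <- function(params, day_grid) {
  p <- as.list(params)
  stopifnot(is.numeric(day_grid), length(day_grid) > 0)
  if (p$amplitude < 0) stop("amplitude must be non-negative")
  if (p$amplitude > 0 && p$rise_mid >= p$fall_mid)
    stop("rise midpoint must precede fall midpoint")
  if (p$amplitude > 0 &&
      (min(day_grid) > p$rise_mid - 60 || max(day_grid) < p$fall_mid + 60))
    stop("day_grid must cover [rise_mid - 60, fall_mid + 60]")
  v <- p$base + p$amplitude *
    (stats::plogis(p$rise_steep * (day_grid - p$rise_mid)) -
       stats::plogis(p$fall_steep * (day_grid - p$fall_mid)))
  if (any(v < -1 | v > 1))
    stop("curve leaves the NDVI range [-1, 1]; check base/amplitude")
  v
}

double_logistic <- function(t, p) {
  p$base + p$amplitude *
    (stats::plogis(p$rise_steep * (t - p$rise_mid)) -
       stats::plogis(p$fall_steep * (t - p$fall_mid)))
}

#' Analytic ground-truth stage dates of a double-logistic curve
#'
#' Computes the noise-free truth the extractor is judged against:
#' season start/end (SD/ED) as the first/last day the curve exceeds
#' `base + onset_frac * amplitude`; V1/VT as the rising 10%/90% dynamic
#' threshold crossings relative to NDVI at SD and the curve maximum; R4 as
#' the descending 10% drop below the maximum relative to NDVI at ED; and
#' V6/R6 as the logistic midpoints (inflections of each branch).
#'
#' @inheritParams simulate_pixel_curve
#' @param onset_frac fraction of the amplitude above base defining season
#'   onset/offset (default 0.01).
#' @return named list: `sd`, `v1`, `v6`, `vt`, `r4`, `r6`, `ed` (continuous
#'   days), plus `peak_day`, `peak_ndvi` and the boundary NDVI values.
#' @export
true_stage_dates <- function(params, onset_frac = 0.01) {
  p <- as.list(params)
  if (p$amplitude <= 0) stop("degenerate amplitude: no season exists")
  f <- function(t) double_logistic(t, p)
  lo <- p$rise_mid - 120
  hi <- p$fall_mid + 120
  opt <- stats::optimize(f, c(p$rise_mid, p$fall_mid), maximum = TRUE,
                         tol = 1e-8)
  peak_day <- opt$maximum
  peak <- opt$objective
  onset_level <- p$base + onset_frac * p$amplitude
  cross <- function(level, interval) {
    stats::uniroot(function(t) f(t) - level, interval, tol = 1e-8)$root
  }
  sd_day <- cross(onset_level, c(lo, peak_day))
  ed_day <- cross(onset_level, c(peak_day, hi))
  y_sd <- f(sd_day)
  y_ed <- f(ed_day)
  v1 <- cross(y_sd + 0.10 * (peak - y_sd), c(sd_day, peak_day))
  vt <- cross(y_sd + 0.90 * (peak - y_sd), c(sd_day, peak_day))
  r4 <- cross(peak - 0.10 * (peak - y_ed), c(peak_day, ed_day))
  out <- list(sd = sd_day, v1 = v1, v6 = p$rise_mid, vt = vt,
              r4 = r4, r6 = p$fall_mid, ed = ed_day,
              peak_day = peak_day, peak_ndvi = peak,
              ndvi_sd = y_sd, ndvi_ed = y_ed)
  ord <- unlist(out[c("sd", "v1", "v6", "vt", "r4", "r6", "ed")])
  if (is.unsorted(ord))
    stop("true stage dates out of order; curve parameters too degenerate")
  out
}

#' True per-phase metrics of a double-logistic curve
#'
#' Durations (days) and NDVI rates (NDVI day^-1) of the four growth phases
#' GP1 = V1..V6, GP2 = V6..VT, GP3 = VT..R4, GP4 = R4..R6, evaluated on the
#' analytic curve.
#'
#' @inheritParams true_stage_dates
#' @return named numeric vector `gp1d, gp1r, gp2d, gp2r, gp3d, gp3r, gp4d,
#'   gp4r`.
#' @export
true_metrics <- function(params, onset_frac = 0.01) {
  p <- as.list(params)
  d <- true_stage_dates(p, onset_frac)
  b <- c(d$v1, d$v6, d$vt, d$r4, d$r6)
  y <- double_logistic(b, p)
  dur <- diff(b)
  rate <- diff(y) / dur
  stats::setNames(as.numeric(rbind(dur, rate)),
                  c("gp1d", "gp1r", "gp2d", "gp2r", "gp3d", "gp3r",
                    "gp4d", "gp4r"))
}

#' 8-day maximum-value composites of a noisy daily NDVI series
#'
#' Emulates the MOD09Q1-style compositing: each daily sample gets additive
#' Gaussian noise; with probability `dropout_prob` it is additionally
#' cloud-degraded (a fixed negative bias, mimicking cloud-depressed NDVI);
#' each 8-day window starting at DOY 1, 9, 17, ... then keeps its maximum,
#' which is exactly the mechanism that suppresses the negatively biased
#' samples.
#'
#' @param daily data.frame with columns `doy` (contiguous integer days) and
#'   `ndvi` (true values), or a numeric vector of true NDVI on days
#'   `1:length(daily)`.
#' @param noise_sd additive noise SD (NDVI units).
#' @param dropout_prob per-day probability of cloud degradation in [0, 1].
#' @param dropout_bias magnitude of the cloud bias (default 0.3 NDVI).
#' @param dropout_symmetric if `TRUE` the degradation bias gets a random
#'   sign instead of being always negative (used to demonstrate that MVC
#'   specifically suppresses negatively biased outliers).
#' @param seed integer seed for this series' random stream.
#' @return data.frame with columns `doy` (window start DOY), `ndvi`
#'   (composite value) and `doy_obs` (the day whose observation was retained
#'   as the window maximum, as MODIS composites record in their day-of-year
#'   layer); class `composite_series`.
#' @export
simulate_composites <- function(daily, noise_sd = 0, dropout_prob = 0,
                                dropout_bias = 0.3,
                                dropout_symmetric = FALSE, seed = 1L) {
  if (is.numeric(daily) && is.null(dim(daily)))
    daily <- list(doy = seq_along(daily), ndvi = daily)
  stopifnot(all(c("doy", "ndvi") %in% names(daily)))
  core <- composite_core(daily$ndvi, daily$doy, noise_sd, dropout_prob,
                         dropout_bias, dropout_symmetric, seed)
  out <- quick_df(core)
  class(out) <- c("composite_series", "data.frame")
  out
}

composite_core <- function(true_ndvi, doy, noise_sd, dropout_prob,
                           dropout_bias, dropout_symmetric, seed) {
  if (any(diff(doy) != 1))
    stop("daily series must be on a contiguous DOY grid")
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("dropout_prob must be in [0, 1]")
  n <- length(doy)
  obs <- withr::with_seed(as.integer(seed), {
    v <- true_ndvi + stats::rnorm(n, 0, noise_sd)
    drop <- stats::runif(n) < dropout_prob
    if (any(drop)) {
      bias <- rep(-dropout_bias, sum(drop))
      if (dropout_symmetric)
        bias <- bias * sample(c(-1, 1), sum(drop), replace = TRUE)
      v[drop] <- v[drop] + bias
    }
    v
  })
  starts <- seq(min(doy), max(doy), by = 8L)
  nw <- length(starts)
  mm <- matrix(c(obs, rep(-Inf, 8L * nw - n)), nrow = 8L)
  w <- max.col(t(mm), ties.method = "first")
  list(doy = starts,
       ndvi = mm[cbind(w, seq_len(nw))],
       doy_obs = doy[(seq_len(nw) - 1L) * 8L + w])
}

#' County-year yields from true phenological metrics
#'
#' `yield = intercept + sum(beta_k * metric_k) + N(0, noise_sd)` over the
#' chosen subset of the eight true metrics, giving the downstream stepwise
#' regression a recoverable generating model.
#'
#' @param truth data.frame of true county-year metrics with columns
#'   `county_id`, `year` and the metric names used by `betas`.
#' @param betas named vector with `intercept` plus metric coefficients
#'   (kg ha^-1 per unit).
#' @param noise_sd yield noise SD (kg ha^-1).
#' @param seed integer seed.
#' @return `truth` with added columns `yield_true` (noise-free component)
#'   and `yield_kg_ha`; attribute `gen_r2` holds the realized generating R^2
#'   (the R^2 of the generating model refit on this panel's true metrics —
#'   the value a perfect extractor could attain), and `gen_r2_expected` the
#'   population value `var(signal) / (var(signal) + noise_sd^2)`.
#' @export
simulate_yields <- function(truth, betas, noise_sd, seed = 1L) {
  if (!all(is.finite(betas))) stop("yield betas must be finite")
  vars <- setdiff(names(betas), "intercept")
  if (!all(vars %in% names(truth)))
    stop("betas refer to metrics missing from truth: ",
         paste(setdiff(vars, names(truth)), collapse = ", "))
  lin <- rep(unname(betas["intercept"]), nrow(truth))
  for (v in vars) lin <- lin + betas[[v]] * truth[[v]]
  out <- truth
  out$yield_true <- lin
  out$yield_kg_ha <- withr::with_seed(
    as.integer(seed), lin + stats::rnorm(nrow(truth), 0, noise_sd))
  vs <- stats::var(lin)
  attr(out, "gen_r2") <- if (length(vars)) {
    summary(stats::lm(out$yield_kg_ha ~ as.matrix(out[vars])))$r.squared
  } else if (noise_sd > 0) 0 else NA_real_
  attr(out, "gen_r2_expected") <-
    if (vs + noise_sd^2 > 0) vs / (vs + noise_sd^2) else NA_real_
  attr(out, "yield_noise_sd") <- noise_sd
  out
}

#' County-year ground-truth dates aligned to the selected pixel set
#'
#' The county series aggregates the corn-dominated pixels, so its true stage
#' dates are the county-year curve dates shifted by the corn-fraction
#' weighted mean planting shift of the pixels that pass the purity
#' threshold. Durations and rates are shift-invariant and stay as in
#' `truth$counties`.
#'
#' @param panel a [simulate_panel()] result.
#' @param threshold corn-fraction purity threshold used downstream.
#' @return `panel$truth$counties` with the `*_true` date columns shifted and
#'   a `mean_shift` column; county-years with no pixel above the threshold
#'   are dropped.
#' @export
county_truth_aligned <- function(panel, threshold = 0.70) {
  sel <- select_corn_pixels(panel$fractions, threshold)
  px <- merge(panel$truth$pixels, sel, by = c("county_id", "pixel_id"))
  if (!nrow(px)) stop("no pixels pass the purity threshold")
  agg <- stats::aggregate(
    cbind(ws = px$corn_fraction * px$shift, w = px$corn_fraction),
    by = list(county_id = px$county_id, year = px$year), FUN = sum)
  agg$mean_shift <- agg$ws / agg$w
  out <- merge(panel$truth$counties, agg[, c("county_id", "year", "mean_shift")],
               by = c("county_id", "year"))
  for (v in c("sd_true", "v1_true", "v6_true", "vt_true", "r4_true",
              "r6_true", "ed_true"))
    out[[v]] <- out[[v]] + out$mean_shift
  out
}

draw_county_means <- function(cfg, county) {
  cp <- cfg$curve_priors
  with_substream(cfg$seed, county, 0L, 0L, {
    list(base       = stats::runif(1, cp$base[1], cp$base[2]),
         amplitude  = stats::runif(1, cp$amplitude[1], cp$amplitude[2]),
         rise_mid   = stats::runif(1, cp$rise_mid[1], cp$rise_mid[2]),
         rise_steep = stats::runif(1, cp$rise_steep[1], cp$rise_steep[2]),
         fall_mid   = stats::runif(1, cp$fall_mid[1], cp$fall_mid[2]),
         fall_steep = stats::runif(1, cp$fall_steep[1], cp$fall_steep[2]))
  })
}

draw_county_year_params <- function(cfg, county, year, means) {
  ys <- cfg$year_sd
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  with_substream(cfg$seed, county, 0L, year, {
    p <- list(
      base       = clamp(means$base + stats::rnorm(1, 0, ys$base), 0.05, 0.35),
      amplitude  = clamp(means$amplitude + stats::rnorm(1, 0, ys$amplitude),
                         0.25, 0.75),
      rise_mid   = means$rise_mid + stats::rnorm(1, 0, ys$mid),
      rise_steep = clamp(means$rise_steep + stats::rnorm(1, 0, ys$steep),
                         0.07, 0.16),
      fall_mid   = means$fall_mid + stats::rnorm(1, 0, ys$mid),
      fall_steep = clamp(means$fall_steep + stats::rnorm(1, 0, ys$steep),
                         0.06, 0.14)
    )
    if (p$fall_mid - p$rise_mid < 50) p$fall_mid <- p$rise_mid + 50
    p
  })
}

#' Simulate a full pixel/county/year panel with ground truth
#'
#' Draws per-county curve parameter means from the priors, perturbs them per
#' year, gives each pixel a planting-date time shift and a corn fraction,
#' generates noisy 8-day maximum-value composites for every pixel-year, and
#' generates county-year yields as a linear function of the true metrics.
#' Fully reproducible from `config$seed`; every pixel-year has its own
#' derived random stream.
#'
#' @param config a [sim_config()] object.
#' @return list with elements
#'   `composites` (county_id, pixel_id, year, doy, ndvi),
#'   `fractions` (county_id, pixel_id, corn_fraction),
#'   `yields` (county_id, year, region_group, yield_kg_ha),
#'   `truth` (list: `pixels` with per pixel-year parameters, shift and true
#'   dates; `counties` with per county-year parameters, true dates, true
#'   metrics and noise-free yield; `gen_r2`; `yield_noise_sd`),
#'   and `config`.
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  cfg <- config
  years <- cfg$years
  counties <- seq_len(cfg$n_counties)
  pixels <- seq_len(cfg$pixels_per_county)
  n_semi <- ceiling(cfg$n_counties * cfg$semi_arid_fraction)
  region <- ifelse(counties <= n_semi, "semi_arid", "non_semi_arid")
  day_grid <- 1:365

  fractions <- do.call(rbind, lapply(counties, function(cc) {
    fr <- vapply(pixels, function(pp) with_substream(
      cfg$seed, cc, pp, 0L,
      stats::runif(1, cfg$corn_fraction_range[1], cfg$corn_fraction_range[2])),
      numeric(1))
    data.frame(county_id = cc, pixel_id = pixels, corn_fraction = fr)
  }))

  n_pix <- cfg$n_counties * length(years) * cfg$pixels_per_county
  n_cty <- cfg$n_counties * length(years)
  n_win <- length(seq(1L, 365L, by = 8L))
  comp_ndvi <- matrix(NA_real_, n_pix, n_win)
  comp_dobs <- matrix(NA_real_, n_pix, n_win)
  pix_id <- matrix(NA_real_, n_pix, 4)  # county, pixel, year, shift
  cty_num <- matrix(NA_real_, n_cty, 21)
  cty_key <- matrix(NA_integer_, n_cty, 2)
  param_names <- c("base", "amplitude", "rise_mid", "rise_steep",
                   "fall_mid", "fall_steep")
  date_names <- c("sd_true", "v1_true", "v6_true", "vt_true", "r4_true",
                  "r6_true", "ed_true")
  metric_names <- c("gp1d", "gp1r", "gp2d", "gp2r", "gp3d", "gp3r",
                    "gp4d", "gp4r")
  k <- 0L; ck <- 0L
  for (cc in counties) {
    means <- draw_county_means(cfg, cc)
    for (yy in years) {
      p_cty <- draw_county_year_params(cfg, cc, yy, means)
      td <- true_stage_dates(p_cty)
      tm <- true_metrics(p_cty)
      ck <- ck + 1L
      cty_key[ck, ] <- c(cc, yy)
      cty_num[ck, ] <- c(unlist(p_cty[param_names]),
                         td$sd, td$v1, td$v6, td$vt, td$r4, td$r6, td$ed, tm)
      for (pp in pixels) {
        shift <- with_substream(cfg$seed, cc, pp, yy + 5000L,
                                stats::rnorm(1, 0, cfg$planting_shift_sd))
        p_pix <- p_cty
        p_pix$rise_mid <- p_pix$rise_mid + shift
        p_pix$fall_mid <- p_pix$fall_mid + shift
        truth_curve <- simulate_pixel_curve(p_pix, day_grid)
        comp <- composite_core(
          truth_curve, day_grid,
          noise_sd = cfg$noise_sd, dropout_prob = cfg$dropout_prob,
          dropout_bias = cfg$dropout_bias, dropout_symmetric = FALSE,
          seed = substream_seed(cfg$seed, cc, pp, yy))
        k <- k + 1L
        comp_ndvi[k, ] <- comp$ndvi
        comp_dobs[k, ] <- comp$doy_obs
        pix_id[k, ] <- c(cc, pp, yy, shift)
      }
    }
  }
  starts <- seq(1L, 365L, by = 8L)
  composites <- data.frame(
    county_id = rep(pix_id[, 1], each = n_win),
    pixel_id = rep(pix_id[, 2], each = n_win),
    year = rep(pix_id[, 3], each = n_win),
    doy = rep(starts, times = n_pix),
    ndvi = as.numeric(t(comp_ndvi)),
    doy_obs = as.numeric(t(comp_dobs)))
  truth_pixels <- data.frame(
    county_id = pix_id[, 1], pixel_id = pix_id[, 2], year = pix_id[, 3],
    shift = pix_id[, 4])
  ckey <- match(paste(pix_id[, 1], pix_id[, 3]),
                paste(cty_key[, 1], cty_key[, 2]))
  for (j in seq_along(date_names))
    truth_pixels[[date_names[j]]] <- cty_num[ckey, 6 + j] + pix_id[, 4]
  truth_counties <- data.frame(
    county_id = cty_key[, 1], year = cty_key[, 2],
    region_group = region[cty_key[, 1]])
  cn <- c(param_names, date_names, metric_names)
  for (j in seq_along(cn)) truth_counties[[cn[j]]] <- cty_num[, j]

  betas <- cfg$yield_betas
  noise_sd <- cfg$yield_noise_sd
  if (is.null(noise_sd)) {
    vars <- setdiff(names(betas), "intercept")
    lin <- rep(unname(betas["intercept"]), nrow(truth_counties))
    for (v in vars) lin <- lin + betas[[v]] * truth_counties[[v]]
    r2 <- cfg$target_gen_r2
    noise_sd <- stats::sd(lin) * sqrt((1 - r2) / r2)
  }
  truth_counties <- simulate_yields(truth_counties, betas, noise_sd,
                                    seed = substream_seed(cfg$seed, 0L, 0L, 1L))
  yields <- truth_counties[, c("county_id", "year", "region_group",
                               "yield_kg_ha")]
  rownames(yields) <- NULL

  list(composites = composites,
       fractions = fractions,
       yields = yields,
       truth = list(pixels = truth_pixels,
                    counties = truth_counties,
                    gen_r2 = attr(truth_counties, "gen_r2"),
                    yield_noise_sd = noise_sd),
       config = cfg)
}
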