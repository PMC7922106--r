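# cheap data.frame constructor for equal-length columns (hot path)
quick_df <- function(l) {
  structure(l, class = "data.frame",
            row.names = c(NA_integer_, -length(l[[1]])))
}

#' Normalized difference vegetation index
#'
#' `(nir - red) / (nir + red)` from surface reflectances in [0, 1].
#'
#' @param red red-band reflectance in [0, 1].
#' @param nir near-infrared reflectance in [0, 1].
#' @return NDVI in [-1, 1]; vectorized.
#' @export
compute_ndvi <- function(red, nir) {
  if (any(red < 0 | red > 1, na.rm = TRUE) ||
      any(nir < 0 | nir > 1, na.rm = TRUE))
    stop("reflectances must lie in [0, 1]")
  s <- red + nir
  if (any(s == 0, na.rm = TRUE))
    stop("red + nir must be positive: NDVI undefined where both bands are 0")
  (nir - red) / s
}

.sg_cache <- new.env(parent = emptyenv())

sg_filter_matrix <- function(polyorder, window) {
  key <- paste0("p", polyorder, "n", window)
  if (is.null(.sg_cache[[key]]))
    .sg_cache[[key]] <- signal::sgolay(p = polyorder, n = window)
  .sg_cache[[key]]
}

#' Savitzky-Golay smoothing of a composite NDVI series
#'
#' Least-squares local-polynomial smoothing on the 8-day grid. Endpoints are
#' handled by the polynomial fit of the edge windows (no shortening), so an
#' input that is exactly a polynomial of degree <= `polyorder` is reproduced.
#'
#' @param x numeric vector of composite NDVI values (evenly spaced).
#' @param window odd filter length in composites (default 5).
#' @param polyorder polynomial order, `< window` (default 2).
#' @return smoothed numeric vector, same length.
#' @export
sg_smooth <- function(x, window = 5, polyorder = 2) {
  n <- length(x)
  if (window %% 2 == 0) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  if (window > n) stop("window must not exceed the series length")
  as.numeric(signal::sgolayfilt(x, sg_filter_matrix(polyorder, window)))
}

#' Daily NDVI by cubic-spline interpolation of 8-day composites
#'
#' Fits a cubic interpolating spline through the composite points and
#' evaluates it at every integer DOY between the first and last composite.
#' The spline passes exactly through the knots and reproduces cubic
#' polynomials.
#'
#' @param doy composite window start DOYs (strictly increasing), or a
#'   data.frame with columns `doy` and `ndvi`.
#' @param ndvi composite NDVI values.
#' @return data.frame with columns `day` (consecutive DOYs) and `ndvi`.
#' @export
interpolate_daily <- function(doy, ndvi = NULL) {
  if (is.data.frame(doy)) {
    ndvi <- doy$ndvi
    doy <- doy$doy
  }
  if (length(doy) < 4) stop("need at least 4 composites to spline")
  if (is.unsorted(doy, strictly = TRUE)) stop("doy must be strictly increasing")
  days <- seq(min(doy), max(doy))
  sp <- stats::spline(doy, ndvi, xout = days, method = "fmm")
  quick_df(list(day = days, ndvi = sp$y))
}

local_minima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] <= y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}

#' Detect the growing season (SD/ED) of a daily NDVI series
#'
#' SD is the day the curve begins to increase at the bottom of the valley
#' before the single seasonal peak; ED the matching valley after it.
#' Operationally: on each limb the valley minimum is located, then SD (ED)
#' is the last (first) day at which the curve still lies within
#' `valley_frac` of the valley-to-peak range above the valley value; the
#' discrete second derivative there must fall inside the near-zero band
#' `curv_tol`, otherwise the nearest day in the valley where it does is
#' chosen.
#'
#' @param day integer days (spacing 1), or a data.frame with `day`, `ndvi`.
#' @param ndvi daily NDVI values.
#' @param curv_tol tolerance band for |second difference| at SD/ED
#'   (day^-2; default 1e-4).
#' @param valley_frac fraction of the valley-to-peak range treated as "still
#'   at the valley bottom" (default 0.01).
#' @param noise_scale estimated observation-noise SD of the series (NDVI
#'   units). When nonzero, the valley floor is taken as the median of the
#'   near-bottom days (robust to a single noise minimum) and the band is
#'   widened to `noise_mult * noise_scale` when that exceeds the
#'   `valley_frac` band, so the detected day sits where the limb slope
#'   dominates the noise. Zero (default) keeps the pure 1% rule for
#'   noise-free series.
#' @param noise_mult multiplier for `noise_scale` (default 5).
#' @param allow_multiple if `TRUE`, series with several comparable peaks use
#'   the highest instead of failing.
#' @return list with `sd` and `ed` (days), class `growing_season`.
#' @export
detect_growing_season <- function(day, ndvi = NULL, curv_tol = 1e-4,
                                  valley_frac = 0.01, noise_scale = 0,
                                  noise_mult = 5,
                                  allow_multiple = FALSE) {
  if (is.data.frame(day)) {
    ndvi <- day$ndvi
    day <- day$day
  }
  y <- as.numeric(ndvi)
  n <- length(y)
  if (n < 7) stop("series too short for season detection")
  rng <- max(y) - min(y)
  if (rng < 1e-6) stop("no peak detected: series is flat")
  pk <- which.max(y)
  if (pk <= 2 || pk >= n - 1)
    stop("no interior peak: series is monotone over its support")
  big <- local_maxima(y)
  big <- big[y[big] >= max(y) - 0.2 * rng]
  if (length(big) > 1) {
    gap_min <- min(y[min(big):max(big)])
    if (max(diff(sort(big))) > 16 && gap_min < max(y) - 0.5 * rng) {
      if (!allow_multiple)
        stop("multiple comparable NDVI peaks; set allow_multiple = TRUE to ",
             "use the highest")
    }
  }
  d2 <- c(NA, diff(y, differences = 2), NA)

  pick <- function(idx_range, from_left) {
    seg <- y[idx_range]
    # valley bottom = the limb's deepest point (on noisy series the shallow
    # wiggle minima near the peak are not the valley)
    w <- which(seg == min(seg))
    cand <- if (from_left) max(w) else min(w)
    vmin <- seg[cand]
    vfloor <- if (noise_scale > 0)
      stats::median(seg[seg <= vmin + 2 * noise_scale])
    else vmin
    thr <- vfloor + max(valley_frac * (max(y) - vfloor),
                        noise_mult * noise_scale)
    at_bottom <- which(seg <= thr)
    at_bottom <- at_bottom[if (from_left) at_bottom >= cand else at_bottom <= cand]
    sel <- if (from_left) max(at_bottom) else min(at_bottom)
    gidx <- idx_range[sel]
    if (!is.na(d2[gidx]) && abs(d2[gidx]) > curv_tol) {
      valley <- idx_range[if (from_left) seq(cand, sel) else seq(sel, cand)]
      ok <- valley[!is.na(d2[valley]) & abs(d2[valley]) <= curv_tol]
      if (length(ok)) gidx <- ok[which.min(abs(ok - gidx))]
    }
    gidx
  }

  sd_i <- pick(seq_len(pk), from_left = TRUE)
  ed_i <- pick(seq(pk, n), from_left = FALSE)
  if (!(sd_i < pk && pk < ed_i))
    stop("season detection failed: SD/ED do not bracket the peak")
  structure(list(sd = day[sd_i], ed = day[ed_i]), class = "growing_season")
}

#' Phenologically adjust a daily series to its growing season
#'
#' Truncates the daily series to [SD, ED] and re-indexes time as days since
#' SD (index 0 at SD). Days before SD and after ED are excluded. Applying
#' the adjustment to an already adjusted series with its full-span season is
#' a no-op.
#'
#' @param daily data.frame with columns `day` (or `adj_day`) and `ndvi`.
#' @param season a [detect_growing_season()] result or list with `sd`, `ed`.
#' @return data.frame with columns `adj_day` (0-based) and `ndvi`; attribute
#'   `sd_day` carries the calendar SD.
#' @export
phenologically_adjust <- function(daily, season) {
  dcol <- if ("adj_day" %in% names(daily)) "adj_day" else "day"
  day <- daily[[dcol]]
  if (season$sd < min(day) || season$ed > max(day) || season$sd >= season$ed)
    stop("season must lie inside the daily series with sd < ed")
  keep <- day >= season$sd & day <= season$ed
  base_sd <- attr(daily, "sd_day")
  out <- quick_df(list(adj_day = day[keep] - season$sd,
                       ndvi = daily$ndvi[keep]))
  attr(out, "sd_day") <- if (is.null(base_sd)) season$sd else base_sd + season$sd
  out
}

#' Prepare one pixel-year: smooth, spline to daily, detect season, adjust
#'
#' The per-pixel chain of the preprocessing step: Savitzky-Golay smoothing on
#' the 8-day composite grid, cubic-spline interpolation to daily, growing
#' season detection, and phenological adjustment.
#'
#' @param composite data.frame with `doy`, `ndvi` for one pixel-year;
#'   when a `doy_obs` column (acquisition day of the retained window
#'   maximum) is present, the daily spline is anchored at those days rather
#'   than at the window starts, removing the composite timing bias.
#' @param window,polyorder Savitzky-Golay parameters (see [sg_smooth()]).
#' @param ... passed to [detect_growing_season()].
#' @return adjusted daily data.frame (see [phenologically_adjust()]) with
#'   attributes `sd_day` and `ed_day`.
#' @export
prep_pixel <- function(composite, window = 5, polyorder = 2, ...) {
  sm <- sg_smooth(composite$ndvi, window = window, polyorder = polyorder)
  x <- if ("doy_obs" %in% names(composite)) composite$doy_obs else composite$doy
  daily <- interpolate_daily(x, sm)
  # smoothing residuals estimate the composite-scale observation noise,
  # which sets how wide the valley-bottom band must be during detection
  noise_scale <- stats::mad(composite$ndvi - sm)
  season <- detect_growing_season(daily$day, daily$ndvi,
                                  noise_scale = noise_scale, ...)
  out <- phenologically_adjust(daily, season)
  attr(out, "ed_day") <- season$ed
  out
}
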