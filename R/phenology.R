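round_half_up <- function(x) floor(x + 0.5)

# First upward crossing of `level` on y[i..j]; linear interpolation between
# adjacent days gives a fractional day, reported rounded half-up.
cross_up <- function(x, y, level) {
  if (y[1] >= level) return(x[1])
  i <- which(y >= level)
  i <- i[i > 1]
  if (!length(i)) return(NA_real_)
  i <- i[1]
  frac <- x[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1])
  round_half_up(frac)
}

cross_down <- function(x, y, level) {
  if (y[1] <= level) return(x[1])
  i <- which(y <= level)
  i <- i[i > 1]
  if (!length(i)) return(NA_real_)
  i <- i[1]
  frac <- x[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1])
  round_half_up(frac)
}

#' Dynamic-threshold stage dates V1, VT, R4
#'
#' On the rising limb, V1 (emergence) is the first day NDVI exceeds the
#' season minimum (value at SD) by 10% of the minimum-to-maximum distance,
#' and VT (tasseling) the first day it exceeds it by 90%. On the descending
#' limb, R4 (dough) is the first day NDVI has dropped below the maximum by
#' 10% of the maximum-to-minimum (value at ED) distance. Crossings are
#' linearly interpolated between days and rounded half-up.
#'
#' @param series adjusted county daily data.frame (`adj_day`, `ndvi`) spanning
#'   the growing season (day 0 = SD, last day = ED).
#' @return named list `v1`, `vt`, `r4` (adjusted days).
#' @export
extract_threshold_dates <- function(series) {
  x <- series$adj_day
  y <- series$ndvi
  pk <- which.max(y)
  y_sd <- y[1]
  y_ed <- y[length(y)]
  ymax <- y[pk]
  if (ymax - y_sd < 1e-6 || ymax - y_ed < 1e-6)
    stop("degenerate amplitude: dynamic thresholds never crossed")
  v1 <- cross_up(x[1:pk], y[1:pk], y_sd + 0.10 * (ymax - y_sd))
  vt <- cross_up(x[1:pk], y[1:pk], y_sd + 0.90 * (ymax - y_sd))
  r4 <- cross_down(x[pk:length(x)], y[pk:length(y)],
                   ymax - 0.10 * (ymax - y_ed))
  if (anyNA(c(v1, vt, r4)))
    stop("dynamic threshold not crossed on one limb")
  list(v1 = v1, vt = vt, r4 = r4)
}

#' Fit a single logistic branch NDVI(t) = c / (1 + exp(a + b t)) + d
#'
#' Nonlinear least squares with data-driven initialization: `d` at the branch
#' minimum, `c` at the range, the midpoint at the half-range crossing, and
#' the slope from the steepest observed secant; the sign of `b` is fixed per
#' branch (negative for a rising branch, positive for a descending one).
#'
#' @param t,y branch data (time in days, NDVI).
#' @param branch `"rising"` or `"descending"`.
#' @return list of class `logistic_fit`: `branch`, `a`, `b`, `c`, `d`,
#'   `rmse`, `window` (range of `t`), `midpoint` (= -a/b).
#' @export
fit_logistic_branch <- function(t, y, branch = c("rising", "descending")) {
  branch <- match.arg(branch)
  if (length(t) < 6) stop("need at least 6 points on the ", branch, " branch")
  d0 <- min(y)
  c0 <- max(y) - d0
  if (c0 < 1e-4)
    stop("logistic fit failed on the ", branch, " branch: flat data (c ~ 0)")
  half <- d0 + c0 / 2
  mid0 <- if (branch == "rising") t[which(y >= half)[1]] else t[which(y <= half)[1]]
  if (is.na(mid0)) mid0 <- stats::median(t)
  slopes <- diff(y) / diff(t)
  smax <- if (branch == "rising") max(slopes) else min(slopes)
  # logistic peak slope is -b c / 4
  b0 <- -4 * smax / c0
  b0 <- if (branch == "rising") min(b0, -1e-3) else max(b0, 1e-3)
  a0 <- -b0 * mid0
  lower <- if (branch == "rising") c(a = -Inf, b = -5, c = 1e-4, d = -1)
           else c(a = -Inf, b = 1e-4, c = 1e-4, d = -1)
  upper <- if (branch == "rising") c(a = Inf, b = -1e-4, c = 2, d = 1)
           else c(a = Inf, b = 5, c = 2, d = 1)
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ c / (1 + exp(a + b * t)) + d, data = df,
                      start = list(a = a0, b = b0, c = c0, d = d0),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("logistic fit did not converge on the ", branch, " branch: ",
         conditionMessage(fit))
  p <- as.list(stats::coef(fit))
  rmse <- sqrt(mean(stats::resid(fit)^2))
  structure(list(branch = branch, a = p$a, b = p$b, c = p$c, d = p$d,
                 rmse = rmse, window = range(t), midpoint = -p$a / p$b),
            class = "logistic_fit")
}

#' Piecewise-logistic fit of a county growing-season NDVI series
#'
#' Splits the series at its peak and fits one logistic branch to each side:
#' the rising branch over [SD, peak] and the descending branch over
#' [peak, ED].
#'
#' @param series adjusted county daily data.frame (`adj_day`, `ndvi`).
#' @return list with elements `rising` and `descending` (class
#'   `logistic_fit`) and `peak_day`.
#' @export
fit_piecewise_logistic <- function(series) {
  x <- series$adj_day
  y <- series$ndvi
  pk <- which.max(y)
  if (pk < 6 || length(x) - pk < 6)
    stop("need at least 6 points on each side of the peak")
  list(rising = fit_logistic_branch(x[1:pk], y[1:pk], "rising"),
       descending = fit_logistic_branch(x[pk:length(x)], y[pk:length(y)],
                                        "descending"),
       peak_day = x[pk])
}

#' Inflection stage dates V6 and R6 from the piecewise-logistic fit
#'
#' The jointing date V6 is the day of the maximum first derivative of the
#' rising logistic and the maturity date R6 the day of the steepest descent
#' of the descending logistic; both are the logistic inflections at
#' `t = -a/b`. Dates are rounded half-up to integer days and must fall
#' inside the season.
#'
#' @param rising,descending `logistic_fit` objects (see
#'   [fit_piecewise_logistic()]).
#' @param season_range length-2 numeric, the series' day span (SD, ED) used
#'   for the containment check.
#' @return list `v6`, `r6` (adjusted days).
#' @export
extract_inflection_dates <- function(rising, descending,
                                     season_range = NULL) {
  v6 <- -rising$a / rising$b
  r6 <- -descending$a / descending$b
  if (!is.null(season_range)) {
    if (v6 < season_range[1] - 1 || v6 > season_range[2] + 1)
      stop("rising inflection (V6) falls outside the growing season")
    if (r6 < season_range[1] - 1 || r6 > season_range[2] + 1)
      stop("descending inflection (R6) falls outside the growing season")
    v6 <- min(max(v6, season_range[1]), season_range[2])
    r6 <- min(max(r6, season_range[1]), season_range[2])
  }
  list(v6 = round_half_up(v6), r6 = round_half_up(r6))
}

#' Assemble and validate the five stage dates
#'
#' @param v1,v6,vt,r4,r6 stage dates (same axis).
#' @return list of class `pheno_dates`; errors (naming the offending pair) if
#'   the order V1 <= V6 <= VT <= R4 <= R6 is violated.
#' @export
pheno_dates <- function(v1, v6, vt, r4, r6) {
  d <- c(v1 = v1, v6 = v6, vt = vt, r4 = r4, r6 = r6)
  if (anyNA(d)) stop("stage dates contain NA")
  bad <- which(diff(d) < 0)
  if (length(bad))
    stop("stage dates out of order: ", names(d)[bad[1]], " > ",
         names(d)[bad[1] + 1])
  structure(as.list(d), class = "pheno_dates")
}

#' Growth phases GP1-GP4 between consecutive stage dates
#'
#' GP1 = [V1, V6], GP2 = [V6, VT], GP3 = [VT, R4], GP4 = [R4, R6], each with
#' the NDVI values of the series at its boundary days.
#'
#' @param dates a [pheno_dates()] object.
#' @param series adjusted county daily data.frame (`adj_day`, `ndvi`).
#' @return list of four `growth_phase` lists (`label`, `gp_start`, `gp_end`,
#'   `ndvi_start`, `ndvi_end`).
#' @export
build_growth_phases <- function(dates, series) {
  stopifnot(inherits(dates, "pheno_dates"))
  b <- c(dates$v1, dates$v6, dates$vt, dates$r4, dates$r6)
  nm <- c("V1", "V6", "VT", "R4", "R6")
  if (any(diff(b) == 0)) {
    i <- which(diff(b) == 0)[1]
    stop("zero-length growth phase: ", nm[i], " equals ", nm[i + 1])
  }
  ndvi_at <- function(d) {
    i <- match(d, series$adj_day)
    if (is.na(i)) stop("stage date ", d, " not on the series day grid")
    series$ndvi[i]
  }
  lapply(1:4, function(i) {
    structure(list(label = paste0("GP", i),
                   gp_start = b[i], gp_end = b[i + 1],
                   ndvi_start = ndvi_at(b[i]), ndvi_end = ndvi_at(b[i + 1])),
              class = "growth_phase")
  })
}

#' Full stage-date extraction for one county-year series
#'
#' Dynamic-threshold dates (V1, VT, R4) plus piecewise-logistic inflection
#' dates (V6, R6), validated for ordering, with the four growth phases.
#'
#' @param series adjusted county daily data.frame (`adj_day`, `ndvi`), e.g.
#'   from [county_weighted_ndvi()].
#' @return list: `dates` (`pheno_dates`, adjusted days), `phases`, `fits`
#'   (piecewise logistic), `sd_day` (calendar SD if carried by the series,
#'   for mapping back to DOY).
#' @export
county_phenology <- function(series) {
  thr <- extract_threshold_dates(series)
  fits <- fit_piecewise_logistic(series)
  infl <- extract_inflection_dates(fits$rising, fits$descending,
                                   range(series$adj_day))
  dates <- pheno_dates(thr$v1, infl$v6, thr$vt, thr$r4, infl$r6)
  phases <- build_growth_phases(dates, series)
  list(dates = dates, phases = phases, fits = fits,
       sd_day = attr(series, "sd_day"))
}
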