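#' Growth-phase duration (days)
#'
#' `Duration = GPend - GPstart`, strictly positive.
#'
#' @param phase a `growth_phase` (see [build_growth_phases()]) or list with
#'   `gp_start`, `gp_end`.
#' @return duration in days.
#' @export
phase_duration <- function(phase) {
  d <- phase$gp_end - phase$gp_start
  if (!is.finite(d) || d <= 0)
    stop("phase duration must be strictly positive")
  d
}

#' Growth-phase NDVI rate (NDVI day^-1)
#'
#' `Rate = (NDVI_GPend - NDVI_GPstart) / Duration`: the average change rate
#' of NDVI across the phase. Positive during green-up phases, negative in
#' senescence.
#'
#' @param phase a `growth_phase` with boundary NDVI values.
#' @return rate in NDVI day^-1.
#' @export
phase_rate <- function(phase) {
  (phase$ndvi_end - phase$ndvi_start) / phase_duration(phase)
}

#' Eight phenological metrics of one county-year
#'
#' @param phases list of four growth phases (see [build_growth_phases()]).
#' @return named numeric vector `gp1d, gp1r, ..., gp4d, gp4r`.
#' @export
phase_metrics <- function(phases) {
  stopifnot(length(phases) == 4)
  out <- numeric(0)
  for (i in 1:4) {
    out[paste0("gp", i, "d")] <- phase_duration(phases[[i]])
    out[paste0("gp", i, "r")] <- phase_rate(phases[[i]])
  }
  out
}

#' Maximum-correlation NDVI predictor (Max-R^2) selection
#'
#' Scans the days-since-SD axis: at each adjusted day present in every
#' sample, the yield is regressed on NDVI at that day across county-years,
#' and the day with the largest R^2 (squared Pearson correlation) is
#' selected; ties go to the earliest day (favoring earlier in-season
#' prediction). The per-row predictor is the NDVI value at the selected day.
#'
#' @param series_list list of adjusted county daily data.frames (`adj_day`,
#'   `ndvi`), one per county-year.
#' @param yields numeric vector of yields aligned with `series_list`.
#' @param stride scan step in days along the adjusted axis (default 1; use 8
#'   for a composite-resolution scan).
#' @return list of class `maxr2_selection`: `selected_day`, `profile`
#'   (named vector of per-day R^2), `n_samples`, `ndvi` (per-row predictor
#'   values at the selected day).
#' @export
select_max_r2 <- function(series_list, yields, stride = 1) {
  n <- length(series_list)
  if (n != length(yields)) stop("one yield per series is required")
  if (n < 3) stop("need at least 3 county-year samples")
  len <- min(vapply(series_list, nrow, integer(1)))
  if (len < 1) stop("empty common adjusted-day grid")
  days <- as.integer(seq(0, len - 1, by = stride))
  mat <- vapply(series_list, function(s) s$ndvi[seq_len(len)], numeric(len))
  mat <- matrix(mat, nrow = len)
  r2 <- vapply(days, function(d) {
    v <- mat[d + 1, ]
    if (stats::sd(v) < 1e-12) return(NA_real_)
    stats::cor(v, yields)^2
  }, numeric(1))
  if (all(is.na(r2))) stop("no NDVI variance at any candidate day")
  sel <- days[which.max(r2)]  # which.max takes the first (earliest) maximum
  structure(list(selected_day = sel,
                 profile = stats::setNames(r2, days),
                 n_samples = n,
                 ndvi = mat[sel + 1, ]),
            class = "maxr2_selection")
}
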