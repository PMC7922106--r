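#' Select corn-dominated pixels
#'
#' Keeps pixels whose corn area fraction is strictly greater than the purity
#' threshold (default 0.70, i.e. "more than 70%" of the pixel is corn).
#'
#' @param weights data.frame with at least `pixel_id` and `corn_fraction`
#'   (optionally `county_id`, `year`).
#' @param threshold purity threshold in (0, 1); strict inequality. The
#'   degenerate value 0 keeps every pixel with positive fraction.
#' @return the rows of `weights` passing the filter.
#' @export
select_corn_pixels <- function(weights, threshold = 0.70) {
  stopifnot(is.data.frame(weights), "corn_fraction" %in% names(weights))
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  if (any(weights$corn_fraction < 0 | weights$corn_fraction > 1))
    stop("corn fractions must lie in [0, 1]")
  weights[weights$corn_fraction > threshold, , drop = FALSE]
}

#' County-level NDVI as the corn-fraction-weighted pixel average
#'
#' Averages phenologically adjusted pixel series on the days-since-SD axis
#' (each pixel's own season start at index 0), weighting each pixel by its
#' corn fraction: `NDVI_county(d) = sum(w_i NDVI_i(d)) / sum(w_i)`. The
#' common season length is the shortest contributing pixel season. The
#' county-level season start, used to map adjusted days back to calendar
#' DOY, is the weighted mean of the pixel SDs.
#'
#' @param pixel_series list of adjusted daily data.frames (`adj_day`,
#'   `ndvi`), each carrying attribute `sd_day`.
#' @param weights positive numeric vector, one per series (corn fractions).
#' @return data.frame (`adj_day`, `ndvi`) with attributes `sd_day` (weighted
#'   mean pixel SD) and `n_pixels`.
#' @export
county_weighted_ndvi <- function(pixel_series, weights) {
  if (length(pixel_series) == 0) stop("no selected pixels to aggregate")
  if (length(weights) != length(pixel_series))
    stop("one weight per pixel series is required")
  if (any(weights <= 0)) stop("weights must be positive")
  len <- min(vapply(pixel_series, nrow, integer(1)))
  mat <- vapply(pixel_series, function(s) s$ndvi[seq_len(len)], numeric(len))
  mat <- matrix(mat, nrow = len)
  w <- weights / sum(weights)
  out <- data.frame(adj_day = 0:(len - 1), ndvi = as.numeric(mat %*% w))
  sds <- vapply(pixel_series, function(s) {
    v <- attr(s, "sd_day")
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  attr(out, "sd_day") <- if (all(is.finite(sds))) sum(w * sds) else NA_real_
  attr(out, "n_pixels") <- length(pixel_series)
  out
}
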