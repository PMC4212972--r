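# Ultrasonic detection-range summaries, infrared peak-wavelength summaries
# with t-based confidence intervals, and spherical spreading loss.

#' Summarise ultrasonic detection ranges for one model and orientation
#'
#' A trial with a zero upper bound is a non-detection (the bat detector
#' registered nothing usable) and is excluded before any statistic is
#' computed; rows are otherwise used verbatim. Reports the median and sample
#' SD (n - 1) of the upper detection frequencies, plus the extreme band
#' bounds, over the detections only.
#'
#' @param detections Data frame as returned by [load_ultrasonic()].
#' @param model Model label to summarise.
#' @param orientation `"front"` or `"offset45"`.
#' @return List with `model`, `orientation`, `n_units`, `n_detections`,
#'   `median_upper_khz`, `sd_upper_khz` (NA when fewer than 2 detections),
#'   `min_lower_khz`, `max_upper_khz` (NA when no detections).
#' @export
ultrasonic_summary <- function(detections, model,
                               orientation = c("front", "offset45")) {
  orientation <- match.arg(orientation)
  rows <- detections[detections$model == model &
                       detections$orientation == orientation, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no ultrasonic records for model '", model, "' at orientation '",
         orientation, "'", call. = FALSE)
  }
  det <- rows[rows$upper_khz > 0, , drop = FALSE]
  nd <- nrow(det)
  list(
    model = model, orientation = orientation,
    n_units = nrow(rows), n_detections = nd,
    median_upper_khz = if (nd >= 1L) stats::median(det$upper_khz) else NA_real_,
    sd_upper_khz = if (nd >= 2L) stats::sd(det$upper_khz) else NA_real_,
    min_lower_khz = if (nd >= 1L) min(det$lower_khz[det$lower_khz > 0])
                    else NA_real_,
    max_upper_khz = if (nd >= 1L) max(det$upper_khz) else NA_real_
  )
}

#' Student-t confidence-interval half-width
#'
#' `t_{(1+conf)/2, n-1} * sd / sqrt(n)` -- the half-width of the usual
#' t-based confidence interval for a mean.
#'
#' @param sd Sample standard deviation (>= 0).
#' @param n Sample size (>= 2).
#' @param conf_level Confidence level in (0, 1); default 0.95.
#' @return Half-width, same units as `sd`.
#' @export
ci_halfwidth <- function(sd, n, conf_level = 0.95) {
  if (n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  if (conf_level <= 0 || conf_level >= 1) {
    stop("`conf_level` must be in (0, 1)", call. = FALSE)
  }
  stats::qt((1 + conf_level) / 2, df = n - 1) * sd / sqrt(n)
}

#' Summarise infrared peak-wavelength readings for one model
#'
#' Mean, sample SD, and t-based confidence-interval half-width of repeated
#' peak-wavelength readings (nm) from a spectrometer.
#'
#' @param readings_nm Numeric vector of at least two wavelength readings, nm.
#' @param conf_level Confidence level (default 0.95).
#' @param model Optional model label carried into the result.
#' @return List with `model`, `n`, `mean_nm`, `sd_nm`, `ci_halfwidth_nm`,
#'   `conf_level`.
#' @export
ir_summary <- function(readings_nm, conf_level = 0.95, model = "unknown") {
  readings_nm <- as.numeric(readings_nm)
  n <- length(readings_nm)
  if (n < 2L) stop("need at least 2 readings", call. = FALSE)
  if (anyNA(readings_nm)) stop("readings must be non-missing", call. = FALSE)
  s <- stats::sd(readings_nm)
  list(model = model, n = n, mean_nm = mean(readings_nm), sd_nm = s,
       ci_halfwidth_nm = ci_halfwidth(s, n, conf_level),
       conf_level = conf_level)
}

#' Spherical spreading loss between two distances
#'
#' Free-field attenuation of sound level with distance from a point source:
#' `20 * log10(d / d_ref)` dB, i.e. 6 dB per doubling of distance. Emission
#' levels measured at a reference distance `d_ref` (e.g. the 50 cm bench
#' distance) are reduced by this amount at distance `d`; the value is
#' negative when `d < d_ref` (gain toward the source).
#'
#' @param d_ref Reference (measurement) distance in metres, > 0.
#' @param d Listener distance in metres, > 0.
#' @return Loss in dB.
#' @export
spreading_loss <- function(d_ref, d) {
  if (!is.numeric(d_ref) || !is.numeric(d) || any(d_ref <= 0) || any(d <= 0)) {
    stop("distances must be positive", call. = FALSE)
  }
  20 * log10(d / d_ref)
}
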