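# Comparison of emission spectra with what animals can hear: interval
# overlap with published hearing ranges, audibility margins against audiogram
# threshold curves, a paired nonparametric test, and a proxy hearing range
# estimated from recorded call frequencies.

#' Construct an audiogram threshold curve
#'
#' An audiogram gives a species' minimum audible level (dB) as a function of
#' frequency; emission levels above the threshold are audible.
#'
#' @param species Species label.
#' @param frequencies Strictly increasing frequencies, Hz.
#' @param thresholds Threshold levels in dB, one per frequency.
#' @param source Free-text provenance note.
#' @return An `audiogram` object.
#' @export
audiogram <- function(species, frequencies, thresholds, source = "") {
  frequencies <- as.numeric(frequencies)
  thresholds <- as.numeric(thresholds)
  if (length(frequencies) != length(thresholds) || length(frequencies) < 2L) {
    stop("need matching frequency/threshold vectors of length >= 2",
         call. = FALSE)
  }
  if (any(frequencies <= 0) || is.unsorted(frequencies, strictly = TRUE)) {
    stop("audiogram frequencies must be positive and strictly increasing",
         call. = FALSE)
  }
  structure(list(species = as.character(species), frequencies = frequencies,
                 thresholds = thresholds, source = as.character(source)),
            class = "audiogram")
}

#' Read an audiogram CSV (species, frequency_hz, threshold_db)
#'
#' @param path CSV file path; may hold several species.
#' @return A list of `audiogram` objects named by species (a single
#'   `audiogram` when the file holds one species).
#' @export
load_audiograms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "frequency_hz", "threshold_db")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("audiogram file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$species), function(d) {
    d <- d[order(d$frequency_hz), ]
    audiogram(d$species[1L], d$frequency_hz, d$threshold_db, source = path)
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Overlap of a species hearing range with an emission band
#'
#' Intersects the species' audible interval with `[band_lo, band_hi]`. When
#' the species' lower bound is unknown the interval is conservatively taken
#' to start at `band_lo` and the result is flagged.
#'
#' @param range One row of [load_hearing_ranges()] output (or any list with
#'   `low_hz`, `high_hz`, `low_known`).
#' @param band_lo,band_hi Emission band bounds in Hz, `band_lo < band_hi`.
#' @return `NULL` when the intervals are disjoint, else a list with `low_hz`,
#'   `high_hz`, `assumed_low` (TRUE when the species low bound was unknown).
#' @export
hearing_overlap <- function(range, band_lo = 12.5, band_hi = 20000) {
  if (band_lo >= band_hi) stop("`band_lo` must be < `band_hi`", call. = FALSE)
  low_known <- isTRUE(range$low_known) ||
    (is.null(range$low_known) && !is.na(range$low_hz))
  lo <- if (low_known) as.numeric(range$low_hz) else band_lo
  hi <- as.numeric(range$high_hz)
  o_lo <- max(lo, band_lo)
  o_hi <- min(hi, band_hi)
  if (o_lo >= o_hi) return(NULL)
  list(low_hz = o_lo, high_hz = o_hi, assumed_low = !low_known)
}

# Interpolate an audiogram onto grid centers, linear in log10 frequency,
# clamped to the audiogram's support (no extrapolation outside it).
.interp_audiogram <- function(aud, gfreq) {
  inside <- gfreq >= min(aud$frequencies) & gfreq <= max(aud$frequencies)
  thr <- rep(NA_real_, length(gfreq))
  if (any(inside)) {
    thr[inside] <- stats::approx(log10(aud$frequencies), aud$thresholds,
                                 xout = log10(gfreq[inside]))$y
  }
  thr
}

#' Audibility margin of an emission envelope against an audiogram
#'
#' Interpolates the audiogram threshold (linearly in log10 frequency) onto
#' the envelope's band grid and reports `margin(f) = level(f) -
#' threshold(f)` wherever the audiogram covers the grid. A band is audible
#' when its margin is strictly positive; bands where the emission exactly
#' meets the threshold count as inaudible.
#'
#' @param envelope A [bootstrap_envelope()] result (or a [curve_set()], whose
#'   functional mean is then used).
#' @param aud An [audiogram()].
#' @param use_upper If `TRUE`, compare the envelope's upper confidence curve
#'   instead of the mean curve (a conservative audibility variant). Default
#'   `FALSE`: the mean curve.
#' @return An `audibility_report`: list with `species`, `frequency_hz`,
#'   `margin_db` (NA outside audiogram support), `audible_bands` (Hz) and
#'   `any_audible`.
#' @export
audibility_margin <- function(envelope, aud, use_upper = FALSE) {
  stopifnot(inherits(aud, "audiogram"))
  if (inherits(envelope, "curve_set")) {
    envelope <- list(grid = envelope$grid,
                     mean_curve = functional_mean(envelope),
                     upper_curve = functional_mean(envelope))
  }
  gfreq <- as.numeric(envelope$grid)
  level <- if (use_upper) envelope$upper_curve else envelope$mean_curve
  thr <- .interp_audiogram(aud, gfreq)
  if (all(is.na(thr))) {
    stop("audiogram for ", aud$species,
         " does not overlap the band grid", call. = FALSE)
  }
  margin <- level - thr
  audible <- !is.na(margin) & margin > 0
  structure(
    list(species = aud$species, frequency_hz = gfreq, margin_db = margin,
         audible_bands = gfreq[audible], any_audible = any(audible)),
    class = "audibility_report"
  )
}

#' @export
print.audibility_report <- function(x, ...) {
  cat("audibility_report '", x$species, "': ", length(x$audible_bands),
      " audible band(s)", if (x$any_audible) "" else " (inaudible)",
      "\n", sep = "")
  invisible(x)
}

#' Paired Wilcoxon test of emission levels against hearing thresholds
#'
#' Two-sided Wilcoxon signed-rank test on the paired (emission level,
#' threshold) values at the grid bands covered by the audiogram. Zero
#' differences are dropped, as is standard for the signed-rank statistic.
#'
#' @param camera_mean Numeric vector of emission levels (dB) on `grid`.
#' @param aud An [audiogram()].
#' @param grid The band grid of `camera_mean`.
#' @return List with `statistic` (V), `p_value` and `n_pairs` used.
#' @export
wilcoxon_camera_vs_hearing <- function(camera_mean, aud,
                                       grid = third_octave_centers()) {
  stopifnot(inherits(aud, "audiogram"))
  gfreq <- as.numeric(grid)
  if (length(camera_mean) != length(gfreq)) {
    stop("`camera_mean` must have one level per grid band", call. = FALSE)
  }
  thr <- .interp_audiogram(aud, gfreq)
  keep <- !is.na(thr)
  if (sum(keep) < 5L) {
    stop("need at least 5 shared frequencies between the spectrum and the ",
         "audiogram", call. = FALSE)
  }
  d <- camera_mean[keep] - thr[keep]
  if (all(d == 0)) {
    stop("all paired differences are zero; the signed-rank test is degenerate",
         call. = FALSE)
  }
  res <- suppressWarnings(
    stats::wilcox.test(camera_mean[keep], thr[keep], paired = TRUE,
                       alternative = "two.sided")
  )
  list(statistic = unname(res$statistic), p_value = res$p.value,
       n_pairs = sum(d != 0))
}

#' Proxy hearing range from recorded call frequencies
#'
#' For species with no measured audiogram, the frequencies of their own
#' vocalisations bound the hearing range from inside: an animal is assumed
#' to hear at least the frequencies it calls at. The full range is the span
#' of the call sample; the optimum band is the shortest interval containing
#' a given fraction of the calls (a highest-density style interval on order
#' statistics).
#'
#' @param call_hz Numeric vector of at least 10 recorded call frequencies,
#'   Hz, all positive.
#' @param coverage Fraction of calls the optimum band must contain, in
#'   (0, 1); default 0.5.
#' @return List with `full_range` (c(min, max)) and `optimum_band` (c(lo,
#'   hi)), both in Hz.
#' @export
proxy_hearing_range <- function(call_hz, coverage = 0.5) {
  call_hz <- as.numeric(call_hz)
  if (length(call_hz) < 10L) {
    stop("need at least 10 call frequencies", call. = FALSE)
  }
  if (anyNA(call_hz) || any(call_hz <= 0)) {
    stop("call frequencies must be positive", call. = FALSE)
  }
  if (coverage <= 0 || coverage >= 1) {
    stop("`coverage` must be in (0, 1)", call. = FALSE)
  }
  x <- sort(call_hz)
  n <- length(x)
  m <- max(2L, ceiling(coverage * n))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)  # ties: earliest (lowest-frequency) window
  list(full_range = c(x[1L], x[n]),
       optimum_band = c(x[i], x[i + m - 1L]))
}
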