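# One-third-octave band grids on the nominal (renard) preferred-number series.

# Nominal mantissas of the one-third-octave preferred series, one decade.
.third_octave_mantissas <- c(1, 1.25, 1.6, 2, 2.5, 3.15, 4, 5, 6.3, 8)

#' One-third-octave band centers between two frequencies
#'
#' Returns the nominal one-third-octave center frequencies (the acoustician's
#' preferred-number series ... 12.5, 16, 20, 25, 31.5, 40, 50, 63, 80, 100 ...)
#' lying in `[fmin, fmax]` inclusive. Nominal values are used throughout, not
#' exact base-ten centers (12.5, not 12.589), because sound analysers and the
#' acoustics literature label bands by their nominal centers.
#'
#' The default span 12.5 Hz to 20 kHz contains exactly 33 centers, the grid of
#' a hand-held sound analyser covering the audible range.
#'
#' @param fmin,fmax Lower and upper bounds in Hz; `0 < fmin <= fmax`.
#' @return A `band_grid` object: a numeric vector of ascending center
#'   frequencies in Hz with class `"band_grid"`.
#' @examples
#' third_octave_centers()          # 33 centers, 12.5 Hz .. 20 kHz
#' third_octave_centers(12.5, 100) # 10 centers
#' @export
third_octave_centers <- function(fmin = 12.5, fmax = 20000) {
  if (!is.numeric(fmin) || !is.numeric(fmax) || length(fmin) != 1L ||
      length(fmax) != 1L || !is.finite(fmin) || !is.finite(fmax)) {
    stop("`fmin` and `fmax` must be single finite numbers", call. = FALSE)
  }
  if (fmin <= 0) stop("`fmin` must be positive", call. = FALSE)
  if (fmax < fmin) stop("`fmax` must be >= `fmin`", call. = FALSE)
  decades <- seq.int(floor(log10(fmin)) - 1L, ceiling(log10(fmax)) + 1L)
  centers <- as.vector(outer(.third_octave_mantissas, 10^decades))
  centers <- sort(centers[centers >= fmin & centers <= fmax])
  if (length(centers) == 0L) {
    stop("no one-third-octave centers fall in [", fmin, ", ", fmax, "] Hz",
         call. = FALSE)
  }
  band_grid(centers)
}

#' Construct a band grid from explicit center frequencies
#'
#' @param centers Strictly increasing positive frequencies in Hz.
#' @return A `band_grid` object.
#' @export
band_grid <- function(centers) {
  centers <- as.numeric(centers)
  if (length(centers) == 0L || anyNA(centers) || any(centers <= 0)) {
    stop("band centers must be positive and non-missing", call. = FALSE)
  }
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("band centers must be strictly increasing", call. = FALSE)
  }
  structure(centers, class = "band_grid")
}

#' @export
print.band_grid <- function(x, ...) {
  cat("band_grid:", length(x), "one-third-octave centers,",
      min(x), "Hz -", max(x), "Hz\n")
  invisible(x)
}

# Internal: check two grids are the same frequencies.
same_grid <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(as.numeric(a) - as.numeric(b)) <= tol)
}
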