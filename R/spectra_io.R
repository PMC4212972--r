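# Spectral curve containers and delimited-text readers/writers.
#
# A "curve" is one unit's maximum unweighted level (L_ZFmax, dB re 20 uPa) as a
# function of one-third-octave band center frequency. A curve_set holds the
# replicate curves of one group (a camera model in one mode, or the background
# envelope recordings) as a units x bands matrix on a shared band grid.

.valid_modes <- c("still", "video", "background")

#' Construct a set of spectral curves
#'
#' @param levels Numeric matrix of sound levels in dB re 20 uPa, one row per
#'   unit, one column per band of `grid`. A single curve may be given as a
#'   vector.
#' @param grid A [band_grid()] whose length matches `ncol(levels)`.
#' @param unit_id Character vector of unit identifiers (recycled default
#'   `unit_1 ...`).
#' @param model Camera model label (single string or one per unit).
#' @param mode Recording mode: `"still"`, `"video"` or `"background"`.
#' @param group_label Label for the group; defaults to the common model name.
#' @return An object of class `curve_set`.
#' @export
curve_set <- function(levels, grid, unit_id = NULL, model = "unknown",
                      mode = "still", group_label = NULL) {
  if (is.vector(levels) && is.numeric(levels)) {
    levels <- matrix(levels, nrow = 1L)
  }
  levels <- as.matrix(levels)
  storage.mode(levels) <- "double"
  if (!inherits(grid, "band_grid")) grid <- band_grid(grid)
  if (ncol(levels) != length(grid)) {
    stop("`levels` must have one column per band (", length(grid), ")",
         call. = FALSE)
  }
  if (nrow(levels) < 1L) stop("need at least one curve", call. = FALSE)
  if (!all(is.finite(levels))) {
    stop("all levels must be finite dB values", call. = FALSE)
  }
  n <- nrow(levels)
  if (is.null(unit_id)) unit_id <- paste0("unit_", seq_len(n))
  unit_id <- as.character(rep_len(unit_id, n))
  if (anyDuplicated(unit_id)) {
    stop("unit ids must be unique within a curve set", call. = FALSE)
  }
  model <- as.character(rep_len(model, n))
  mode <- match.arg(mode, .valid_modes)
  if (is.null(group_label)) group_label <- model[1L]
  rownames(levels) <- unit_id
  colnames(levels) <- as.numeric(grid)
  structure(
    list(grid = grid, levels = levels, unit_id = unit_id, model = model,
         mode = mode, group_label = as.character(group_label)),
    class = "curve_set"
  )
}

#' @export
print.curve_set <- function(x, ...) {
  cat("curve_set '", x$group_label, "': ", nrow(x$levels), " curve(s) x ",
      length(x$grid), " bands (", min(x$grid), "-", max(x$grid), " Hz), mode ",
      x$mode, "\n", sep = "")
  invisible(x)
}

#' Number of curves in a curve set
#' @param cs A `curve_set`.
#' @return Integer count of curves (units).
#' @export
n_curves <- function(cs) {
  stopifnot(inherits(cs, "curve_set"))
  nrow(cs$levels)
}

#' Read spectral measurements from a delimited text file
#'
#' Expects a comma-separated file with header columns `unit_id`, `model`,
#' `mode`, `frequency_hz`, `level_db`; one row per (unit, band). Every unit
#' must cover every grid frequency exactly once.
#'
#' @param path CSV file path.
#' @param grid Band grid the file must cover; defaults to the 33-band
#'   12.5 Hz - 20 kHz grid.
#' @return A list of `curve_set` objects, one per (model, mode) group, named
#'   `model:mode` (a single `curve_set` when the file holds one group).
#' @export
load_spectra <- function(path, grid = third_octave_centers()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "model", "mode", "frequency_hz", "level_db")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("spectra file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_mode <- setdiff(unique(df$mode), .valid_modes)
  if (length(bad_mode)) {
    stop("unknown mode(s): ", paste(bad_mode, collapse = ", "), call. = FALSE)
  }
  gfreq <- as.numeric(grid)
  groups <- split(df, paste(df$model, df$mode, sep = ":"))
  out <- lapply(groups, function(g) {
    units <- split(g, g$unit_id)
    lev <- t(vapply(units, function(u) {
      f <- u$frequency_hz
      if (anyDuplicated(f)) {
        stop("unit ", u$unit_id[1L], ": duplicate band at ",
             f[duplicated(f)][1L], " Hz", call. = FALSE)
      }
      missing_f <- setdiff(gfreq, f)
      extra_f <- setdiff(f, gfreq)
      if (length(extra_f)) {
        stop("unit ", u$unit_id[1L], ": frequency ", extra_f[1L],
             " Hz not on the grid", call. = FALSE)
      }
      if (length(missing_f)) {
        stop("unit ", u$unit_id[1L], ": missing band at ", missing_f[1L],
             " Hz", call. = FALSE)
      }
      u$level_db[match(gfreq, f)]
    }, numeric(length(gfreq))))
    curve_set(lev, grid, unit_id = names(units), model = g$model[1L],
              mode = g$mode[1L])
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Write a curve set (or list of curve sets) to a spectra CSV
#'
#' Inverse of [load_spectra()]: `save_spectra()` then `load_spectra()` is the
#' identity on any valid curve set.
#'
#' @param x A `curve_set` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_spectra <- function(x, path) {
  if (inherits(x, "curve_set")) x <- list(x)
  rows <- do.call(rbind, lapply(x, function(cs) {
    gfreq <- as.numeric(cs$grid)
    data.frame(
      unit_id = rep(cs$unit_id, each = length(gfreq)),
      model = rep(cs$model, each = length(gfreq)),
      mode = cs$mode,
      frequency_hz = rep(gfreq, times = nrow(cs$levels)),
      level_db = as.vector(t(cs$levels)),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a species hearing-range table
#'
#' Expects columns `species`, `scientific_name`, `low_hz`, `high_hz`. A blank
#' or missing `low_hz` marks a species whose lower audible bound is unknown;
#' the record is kept and flagged (`low_known = FALSE`). The fixture shipped
#' in `inst/extdata/hearing_ranges.csv` holds published approximate hearing
#' ranges of 24 animals.
#'
#' @param path CSV file path; defaults to the bundled fixture.
#' @return A data frame with columns `species`, `scientific_name`, `low_hz`,
#'   `high_hz`, `low_known`.
#' @export
load_hearing_ranges <- function(path = system.file("extdata",
                                                   "hearing_ranges.csv",
                                                   package = "camtrapemit")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "scientific_name", "low_hz", "high_hz")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("hearing-range file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$low_hz <- suppressWarnings(as.numeric(df$low_hz))
  df$high_hz <- as.numeric(df$high_hz)
  df$low_known <- !is.na(df$low_hz)
  if (any(!is.finite(df$high_hz)) || any(df$high_hz <= 0)) {
    stop("`high_hz` must be positive for every species", call. = FALSE)
  }
  bad <- df$low_known & df$high_hz <= df$low_hz
  if (any(bad)) {
    stop("inverted hearing interval for: ",
         paste(df$species[bad], collapse = ", "), call. = FALSE)
  }
  df[, c("species", "scientific_name", "low_hz", "high_hz", "low_known")]
}

#' Read an ultrasonic detection-range table
#'
#' Expects columns `model`, `unit_code`, `orientation` (`front` or
#' `offset45`), `lower_khz`, `upper_khz`. A `(0, 0)` row records a trial in
#' which the bat detector registered nothing; rows are kept verbatim, and
#' non-detections are excluded only inside [ultrasonic_summary()]. The
#' bundled fixture holds the detection bands measured for five camera models
#' (plus two no-camera controls) at two detector orientations.
#'
#' @param path CSV file path; defaults to the bundled fixture.
#' @return A data frame with the five columns above.
#' @export
load_ultrasonic <- function(path = system.file("extdata",
                                               "ultrasonic_ranges.csv",
                                               package = "camtrapemit")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("model", "unit_code", "orientation", "lower_khz", "upper_khz")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("ultrasonic file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$orientation), c("front", "offset45"))
  if (length(bad)) {
    stop("unknown orientation(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$lower_khz <- as.numeric(df$lower_khz)
  df$upper_khz <- as.numeric(df$upper_khz)
  if (anyNA(df$lower_khz) || anyNA(df$upper_khz)) {
    stop("detection bounds must be numeric", call. = FALSE)
  }
  df
}
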