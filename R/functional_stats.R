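# Functional statistics on band spectra: pointwise means/SDs, bootstrap
# confidence envelopes for the mean curve, two-sample permutation t-max tests
# with per-frequency critical curves, and FDR-corrected pairwise contrasts.
#
# The unit of observation is the whole spectral curve; resampling and label
# permutation always act on curves, never on individual bands.

#' Functional mean of a curve set
#'
#' Pointwise arithmetic mean of the replicate curves at each band.
#'
#' @param curves A [curve_set()] with at least one curve.
#' @return Numeric vector of mean levels (dB), one per band.
#' @export
functional_mean <- function(curves) {
  stopifnot(inherits(curves, "curve_set"))
  colMeans(curves$levels)
}

#' Functional standard deviation of a curve set
#'
#' Pointwise sample standard deviation (n - 1 denominator) at each band.
#'
#' @param curves A [curve_set()] with at least two curves.
#' @return Numeric vector of SDs (dB), one per band.
#' @export
functional_sd <- function(curves) {
  stopifnot(inherits(curves, "curve_set"))
  if (nrow(curves$levels) < 2L) {
    stop("functional SD needs at least 2 curves", call. = FALSE)
  }
  apply(curves$levels, 2L, stats::sd)
}

# Column sample variances, clamped at zero against cancellation error.
.col_vars <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  pmax(0, (colSums(m * m) - n * mu * mu) / (n - 1))
}

# Welch |t| per band for rows ia vs rows ib of the stacked level matrix.
# Zero-variance bands: t = 0 when the means agree; otherwise the infinite
# statistic is capped at the largest finite |t| in the same curve (a large
# sentinel when no band is finite).
.welch_t_curve <- function(Z, ia, ib) {
  A <- Z[ia, , drop = FALSE]
  B <- Z[ib, , drop = FALSE]
  d <- abs(colMeans(A) - colMeans(B))
  se2 <- .col_vars(A) / nrow(A) + .col_vars(B) / nrow(B)
  t <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d > 0, Inf, 0))
  if (any(!is.finite(t))) {
    fin <- t[is.finite(t)]
    t[!is.finite(t)] <- if (length(fin)) max(fin) else 1e6
  }
  t
}

#' Bootstrap confidence envelope for the functional mean
#'
#' Resamples whole curves with replacement `n_boot` times; the envelope is
#' formed from pointwise `alpha/2` and `1 - alpha/2` empirical quantiles of
#' the bootstrap mean curves around the sample functional mean. Bands are the
#' percentile kind (per-frequency), not sup-norm simultaneous bands.
#'
#' @param curves A [curve_set()].
#' @param n_boot Number of bootstrap resamples (default 9999).
#' @param alpha One minus the envelope coverage (default 0.05 for 95%).
#' @param seed Optional integer seed for reproducibility.
#' @return A `functional_envelope`: list with `grid`, `mean_curve`,
#'   `lower_curve`, `upper_curve`, `n_boot`, `alpha`, `seed`.
#' @export
bootstrap_envelope <- function(curves, n_boot = 9999, alpha = 0.05,
                               seed = NULL) {
  stopifnot(inherits(curves, "curve_set"))
  if (n_boot < 1L) stop("`n_boot` must be at least 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0,1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  X <- curves$levels
  n <- nrow(X)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  boot_means <- t(apply(idx, 1L, function(i) colMeans(X[i, , drop = FALSE])))
  mean_curve <- colMeans(X)
  qs <- apply(boot_means, 2L, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  # guard the pointwise ordering lower <= mean <= upper in degenerate samples
  lower <- pmin(qs[1L, ], mean_curve)
  upper <- pmax(qs[2L, ], mean_curve)
  structure(
    list(grid = curves$grid, mean_curve = unname(mean_curve),
         lower_curve = unname(lower), upper_curve = unname(upper),
         n_boot = as.integer(n_boot), alpha = alpha,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         group_label = curves$group_label),
    class = "functional_envelope"
  )
}

#' @export
print.functional_envelope <- function(x, ...) {
  cat("functional_envelope '", x$group_label, "': ", length(x$grid),
      " bands, ", 100 * (1 - x$alpha), "% pointwise, n_boot = ", x$n_boot,
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.functional_envelope <- function(x, ...) {
  data.frame(frequency_hz = as.numeric(x$grid), mean_db = x$mean_curve,
             lower_db = x$lower_curve, upper_db = x$upper_curve)
}

#' Two-sample functional permutation t-test
#'
#' Computes the Welch (unpooled) absolute t statistic at every band,
#' `|t(f)| = |mean_a(f) - mean_b(f)| / sqrt(s2_a(f)/n_a + s2_b(f)/n_b)`,
#' and its maximum over frequency, `t_max`. Group labels are randomly
#' permuted `n_perm` times; the per-frequency critical curve is the
#' `1 - alpha` empirical quantile of the permuted `|t(f)|`, and the global
#' p-value uses the add-one convention
#' `p = (1 + #\{permutations with max |t| >= observed t_max\}) / (n_perm + 1)`,
#' so its smallest attainable value is `1/(n_perm + 1)`.
#'
#' @param a,b Two [curve_set()] objects on the same grid, each with at least
#'   two curves.
#' @param n_perm Number of random label permutations (default 999).
#' @param alpha Level of the per-frequency critical curve (default 0.05).
#' @param seed Optional integer seed.
#' @return A `functional_test`: list with `grid`, `t_curve`,
#'   `critical_curve`, `t_max`, `p_global`, `n_perm`, `alpha`, `seed`,
#'   `groups`.
#' @export
functional_t_test <- function(a, b, n_perm = 999, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(a, "curve_set"), inherits(b, "curve_set"))
  if (!same_grid(a$grid, b$grid)) {
    stop("the two curve sets must share a band grid", call. = FALSE)
  }
  na <- nrow(a$levels)
  nb <- nrow(b$levels)
  if (na < 2L || nb < 2L) {
    stop("each group needs at least 2 curves", call. = FALSE)
  }
  if (n_perm < 1L) stop("`n_perm` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # canonical within-group row order, so the result does not depend on how
  # the replicate units happen to be listed (same seed, same answer)
  canon <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]
  Z <- rbind(canon(a$levels), canon(b$levels))
  n <- na + nb
  t_obs <- .welch_t_curve(Z, seq_len(na), na + seq_len(nb))
  perm_t <- matrix(0, nrow = n_perm, ncol = ncol(Z))
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    perm_t[k, ] <- .welch_t_curve(Z, idx[seq_len(na)], idx[na + seq_len(nb)])
  }
  critical <- apply(perm_t, 2L, stats::quantile, probs = 1 - alpha,
                    names = FALSE)
  t_max <- max(t_obs)
  p_global <- (1 + sum(apply(perm_t, 1L, max) >= t_max)) / (n_perm + 1)
  structure(
    list(grid = a$grid, t_curve = unname(t_obs),
         critical_curve = unname(critical), t_max = t_max,
         p_global = p_global, n_perm = as.integer(n_perm), alpha = alpha,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         groups = c(a$group_label, b$group_label)),
    class = "functional_test"
  )
}

#' @export
print.functional_test <- function(x, ...) {
  cat("functional t-test: ", x$groups[1L], " vs ", x$groups[2L],
      "\n  t_max = ", format(x$t_max, digits = 4),
      ", p = ", format(x$p_global, digits = 3),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.functional_test <- function(x, ...) {
  data.frame(frequency_hz = as.numeric(x$grid), t_abs = x$t_curve,
             critical = x$critical_curve)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (independence form), order-preserving and capped
#' at one.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_fdr <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' All pairwise functional contrasts with FDR correction
#'
#' Runs [functional_t_test()] on every unordered pair of groups (input
#' order, first-listed group as `group_a`) and adjusts the global p-values
#' across all rows with [adjust_fdr()]. For `k` groups the table has
#' `k (k - 1) / 2` rows. Per-pair seeds are derived deterministically from
#' `seed` so the full table is reproducible.
#'
#' @param groups A list of [curve_set()] objects on a common grid (at least
#'   two), each with at least two curves.
#' @param n_perm,alpha,seed As in [functional_t_test()].
#' @return A data frame with columns `group_a`, `group_b`, `t_max`, `p_raw`,
#'   `p_adjusted`; the underlying `functional_test` objects are attached as
#'   attribute `"tests"`.
#' @export
run_pairwise_contrasts <- function(groups, n_perm = 999, alpha = 0.05,
                                   seed = NULL) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  lab <- vapply(groups, function(g) g$group_label, character(1))
  pairs <- utils::combn(length(groups), 2L)
  tests <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]
    i2 <- pairs[2L, j]
    sj <- if (is.null(seed)) NULL else seed + j - 1L
    tests[[j]] <- functional_t_test(groups[[i1]], groups[[i2]],
                                    n_perm = n_perm, alpha = alpha, seed = sj)
  }
  out <- data.frame(
    group_a = lab[pairs[1L, ]],
    group_b = lab[pairs[2L, ]],
    t_max = vapply(tests, `[[`, numeric(1), "t_max"),
    p_raw = vapply(tests, `[[`, numeric(1), "p_global"),
    stringsAsFactors = FALSE
  )
  out$p_adjusted <- adjust_fdr(out$p_raw)
  attr(out, "tests") <- tests
  out
}

#' Summary features of a group's functional mean and SD
#'
#' Reports the range of the functional mean and the `k` band frequencies with
#' the largest mean level and the largest pointwise SD. Ties are broken
#' toward the lower frequency.
#'
#' @param curves A [curve_set()] with at least two curves.
#' @param k Number of top frequencies to report (default 3).
#' @return List with `min_mean`, `max_mean`, `top_frequencies` (Hz, length
#'   `k`) and `top_sd_frequencies` (Hz, length `k`).
#' @export
curve_summary <- function(curves, k = 3L) {
  stopifnot(inherits(curves, "curve_set"))
  m <- functional_mean(curves)
  s <- functional_sd(curves)
  p <- length(m)
  if (k < 1L || k > p) {
    stop("`k` must be between 1 and the number of bands (", p, ")",
         call. = FALSE)
  }
  gfreq <- as.numeric(curves$grid)
  ord_m <- order(-m, seq_len(p))[seq_len(k)]
  ord_s <- order(-s, seq_len(p))[seq_len(k)]
  list(min_mean = min(m), max_mean = max(m),
       top_frequencies = gfreq[ord_m], top_sd_frequencies = gfreq[ord_s])
}
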