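# Shared fixtures and independent oracles, kept deliberately naive so they
# never share code with the implementation they check.

default_grid <- third_octave_centers()

# n flat (constant-level) curves at the given per-unit levels
flat_set <- function(levels_per_unit, label = "flat", grid = default_grid,
                     mode = "still") {
  lev <- do.call(rbind, lapply(levels_per_unit,
                               function(v) rep(v, length(grid))))
  curve_set(lev, grid, model = label, mode = mode, group_label = label)
}

# brute-force per-column mean/SD by explicit looping
col_stat_loop <- function(m, fun) {
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) out[j] <- fun(m[, j])
  out
}

# Welch |t| for two numeric vectors (scalar, used on flat curve sets)
welch_abs_t <- function(x, y) {
  abs(mean(x) - mean(y)) /
    sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
}

# exact permutation p for flat 3v3 sets: enumerate all choose(6,3)
# assignments of the pooled per-unit levels to group A
exact_perm_p_3v3 <- function(a_levels, b_levels) {
  pool <- c(a_levels, b_levels)
  t_obs <- welch_abs_t(a_levels, b_levels)
  combos <- utils::combn(6L, 3L)
  ts <- apply(combos, 2L, function(ia) {
    welch_abs_t(pool[ia], pool[-ia])
  })
  mean(ts >= t_obs - 1e-12)
}

# independent Benjamini-Hochberg: sort, p * m / rank, cumulative min from the
# largest p down, cap at 1, restore input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
# (no ties, no zeros assumed)
signed_rank_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  p <- mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-12)
  min(1, p)
}
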