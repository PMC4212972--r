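test_that("functional mean and SD match brute-force column statistics", {
  sig <- default_signatures()$background
  cs <- generate_curve_set(sig, 10, seed = 5)
  expect_equal(unname(functional_mean(cs)),
               col_stat_loop(cs$levels, mean))
  expect_equal(unname(functional_sd(cs)),
               col_stat_loop(cs$levels, sd))

  one <- curve_set(rep(3, 33), default_grid)
  expect_equal(unname(functional_mean(one)), rep(3, 33))
  two <- flat_set(c(0, 2))
  expect_equal(unname(functional_mean(two)), rep(1, 33))
  expect_equal(unname(functional_sd(two)), rep(sqrt(2), 33))
  expect_error(functional_sd(one), "at least 2")
})

test_that("bootstrap envelopes collapse in degenerate cases", {
  one <- curve_set(sin(seq_len(33)), default_grid)
  env1 <- bootstrap_envelope(one, n_boot = 50, seed = 1)
  expect_equal(env1$lower_curve, env1$mean_curve)
  expect_equal(env1$upper_curve, env1$mean_curve)

  same <- flat_set(rep(7, 5))
  env2 <- bootstrap_envelope(same, n_boot = 100, seed = 2)
  expect_equal(env2$upper_curve - env2$lower_curve, rep(0, 33))
})

test_that("envelopes are pointwise ordered, seeded, and nested across alpha", {
  cs <- generate_curve_set(default_signatures()$camera_quiet, 8, seed = 3)
  e1 <- bootstrap_envelope(cs, n_boot = 500, alpha = 0.05, seed = 9)
  e2 <- bootstrap_envelope(cs, n_boot = 500, alpha = 0.05, seed = 9)
  expect_equal(e1$lower_curve, e2$lower_curve)
  expect_equal(e1$upper_curve, e2$upper_curve)
  expect_true(all(e1$lower_curve <= e1$mean_curve))
  expect_true(all(e1$mean_curve <= e1$upper_curve))

  wide <- bootstrap_envelope(cs, n_boot = 500, alpha = 0.05, seed = 9)
  narrow <- bootstrap_envelope(cs, n_boot = 500, alpha = 0.2, seed = 9)
  expect_true(all(narrow$lower_curve >= wide$lower_curve))
  expect_true(all(narrow$upper_curve <= wide$upper_curve))
})

test_that("identical groups give a flat zero t-curve and p of one", {
  a <- flat_set(c(5, 5, 5), "a")
  b <- flat_set(c(5, 5, 5), "b")
  tt <- functional_t_test(a, b, n_perm = 99, seed = 1)
  expect_equal(tt$t_curve, rep(0, 33))
  expect_equal(tt$t_max, 0)
  expect_equal(tt$p_global, 1)
})

test_that("permutation p agrees with the exhaustive 3v3 enumeration oracle", {
  cases <- list(list(a = c(1, 2, 3), b = c(7, 8, 9)),
                list(a = c(1, 5, 9), b = c(2, 6, 10)),
                list(a = c(4, 5, 9), b = c(1, 6, 8)))
  for (cs in cases) {
    p_exact <- exact_perm_p_3v3(cs$a, cs$b)
    tt <- functional_t_test(flat_set(cs$a, "a"), flat_set(cs$b, "b"),
                            n_perm = 4999, seed = 21)
    expect_lt(abs(tt$p_global - p_exact), 0.03)
  }
})

test_that("overwhelming separation reaches the minimum attainable p", {
  sig <- default_signatures()$camera_quiet
  a <- generate_curve_set(sig, 6, seed = 31)
  shifted <- model_signature("b", sig$mean_curve + 10 * sig$sd_curve,
                             sig$sd_curve, sig$band_correlation, sig$grid)
  b <- generate_curve_set(shifted, 6, seed = 32)
  tt <- functional_t_test(a, b, n_perm = 999, seed = 33)
  # random permutations may re-draw the original labelling, so p can sit a
  # notch above the 1/(n_perm+1) floor even under total separation
  expect_lte(tt$p_global, 0.005)
})

test_that("the test is invariant to within-group unit order", {
  sig <- default_signatures()$background
  a <- generate_curve_set(sig, 5, seed = 41)
  b <- generate_curve_set(sig, 5, seed = 42)
  a_shuffled <- curve_set(a$levels[c(3, 1, 5, 2, 4), ], a$grid,
                          model = "a", group_label = "a")
  t1 <- functional_t_test(a, b, n_perm = 199, seed = 7)
  t2 <- functional_t_test(a_shuffled, b, n_perm = 199, seed = 7)
  expect_equal(t1$t_curve, t2$t_curve)
  expect_equal(t1$critical_curve, t2$critical_curve)
  expect_equal(t1$p_global, t2$p_global)
})

test_that("group-size and grid preconditions are enforced", {
  a <- flat_set(c(1, 2))
  b <- flat_set(c(3, 4))
  tiny <- curve_set(matrix(1:20, 2), band_grid(as.numeric(
    third_octave_centers(12.5, 100))), model = "tiny")
  expect_error(functional_t_test(curve_set(rep(1, 33), default_grid), b),
               "at least 2")
  expect_error(functional_t_test(a, tiny), "share a band grid")
})

test_that("zero-variance bands degrade gracefully instead of exploding", {
  # identical within groups, different between: |t| infinite at every band,
  # capped to a common finite value; p comes out at the add-one floor only
  # if no permutation separates as well, which label swaps do, so p < 1
  a <- flat_set(c(2, 2, 2), "a")
  b <- flat_set(c(8, 8, 8), "b")
  tt <- functional_t_test(a, b, n_perm = 199, seed = 3)
  expect_true(all(is.finite(tt$t_curve)))
  expect_true(all(tt$t_curve >= 0))
  expect_true(tt$p_global >= 1 / 200 && tt$p_global <= 1)
})

test_that("BH adjustment matches hand values and the sort-cummin oracle", {
  expect_equal(adjust_fdr(0.04), 0.04)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_fdr(c(-0.1)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    adj <- adjust_fdr(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  }
})

test_that("pairwise contrasts have k(k-1)/2 rows in input order", {
  sig <- default_signatures()$background
  mk <- function(lab, seed) {
    cs <- generate_curve_set(sig, 3, seed = seed)
    cs$group_label <- lab
    cs
  }
  for (k in c(2L, 5L)) {
    groups <- lapply(seq_len(k), function(i) mk(LETTERS[i], 100 + i))
    tab <- run_pairwise_contrasts(groups, n_perm = 29, seed = 1)
    expect_equal(nrow(tab), k * (k - 1L) / 2L)
    expect_equal(tab$group_a[1], "A")
    expect_equal(tab$p_adjusted, adjust_fdr(tab$p_raw))
    expect_true(all(tab$p_adjusted >= tab$p_raw))
  }
})

test_that("curve summaries find injected peaks and respect tie-breaks", {
  flat <- flat_set(c(4, 4, 4))
  s <- curve_summary(flat, k = 3)
  expect_equal(s$min_mean, s$max_mean)
  expect_equal(s$top_frequencies, as.numeric(default_grid)[1:3])

  base <- rep(10, 33)
  base[as.numeric(default_grid) == 2500] <- 30
  cs <- curve_set(rbind(base, base + 0.1), default_grid)
  s2 <- curve_summary(cs, k = 1)
  expect_equal(s2$top_frequencies, 2500)
  expect_error(curve_summary(cs, k = 34), "between 1 and")
})
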