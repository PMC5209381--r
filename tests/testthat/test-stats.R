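# Per-animal aggregation, t-tests, bootstrap spectra, weight correlations.

test_that("aggregation averages within animal first and applies inclusion", {
  mk_rec <- function(id, durs, geno = "WT") {
    n <- length(durs)
    onsets <- cumsum(c(0.5, rep(0.2, n - 1))) + cumsum(c(0, durs[-n]))
    list(calls = data.frame(recording_id = id, call = seq_len(n),
                            onset = onsets, offset = onsets + durs,
                            duration = durs),
         features = data.frame(recording_id = id, call = seq_len(n),
                               max_jump = rep(1e4, n),
                               jump_pos_5000 = rep(1, n),
                               jump_neg_5000 = rep(0, n)),
         bouts = data.frame(recording_id = id, call = seq_len(n),
                            bout = seq_len(n), cutoff = 0.239),
         labels = data.frame(recording_id = id, call = seq_len(n),
                             label = rep(c("flat", "down-FM"), length.out = n)),
         meta = data.frame(recording_id = id, genotype = geno, day = 8,
                           weight = 4.3, sex = "F"))
  }
  a <- mk_rec("r1", rep(c(0.04, 0.06), 6))       # 12 calls
  b <- mk_rec("r2", rep(0.05, 9))                # 9 calls: excluded
  tabs <- lapply(names(a), function(nm) rbind(a[[nm]], b[[nm]]))
  names(tabs) <- names(a)
  out <- aggregate_cohort(tabs$calls, tabs$features, tabs$bouts, tabs$labels,
                          tabs$meta)
  expect_identical(nrow(out), 1L)
  expect_identical(out$recording_id, "r1")
  expect_equal(out$mean_duration, 0.05)
  expect_equal(out$jump_pos_5000, 1)
  expect_error(aggregate_cohort(tabs$calls[0, ], tabs$features, tabs$bouts,
                                tabs$labels, tabs$meta), "calls")
})

test_that("pooled t-test matches the hand-computed oracle", {
  res <- ttest_two_tailed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.02131, tolerance = 1e-3)
  same <- ttest_two_tailed(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  swap <- ttest_two_tailed(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$t, -res$t)
})

test_that("pooled t at the published P8 intra-pause summaries lands near 2.84", {
  # groups constructed to match mean/SEM exactly: 0.133 +/- 0.002 (n = 41)
  # vs 0.144 +/- 0.003 (n = 15)
  set.seed(181)
  match_group <- function(n, m, sem) {
    x <- rnorm(n)
    m + (x - mean(x)) / sd(x) * sem * sqrt(n)
  }
  wt <- match_group(41, 0.133, 0.002)
  ko <- match_group(15, 0.144, 0.003)
  res <- ttest_two_tailed(ko, wt)
  expect_lt(abs(abs(res$t) - 2.841), 0.3)
  expect_lt(res$p, 0.05)
})

test_that("t-test agrees with a permutation oracle on small groups", {
  set.seed(191)
  a <- rnorm(6, 1); b <- rnorm(6, 0)
  res <- ttest_two_tailed(a, b)
  pooled <- c(a, b)
  perm_p <- mean(replicate(4000, {
    s <- sample(12, 6)
    abs(mean(pooled[s]) - mean(pooled[-s])) >= abs(mean(a) - mean(b))
  }))
  expect_lt(abs(res$p - perm_p), 0.05)
})

test_that("call-level comparison gives t-based intervals and sign symmetry", {
  set.seed(201)
  a <- rnorm(400, 0.052, 0.012); b <- rnorm(300, 0.046, 0.012)
  pc <- per_call_comparison(a, b)
  expect_lt(pc$ci_a[1], pc$mean_a); expect_gt(pc$ci_a[2], pc$mean_a)
  expect_gt(pc$t, 0)
  pc_swap <- per_call_comparison(b, a)
  expect_equal(pc_swap$t, -pc$t)
  same <- per_call_comparison(rep(1, 5), c(1, 1, 1, 1, 1))
  expect_equal(diff(same$ci_a), 0)
})

test_that("animal- and call-level comparisons agree in sign on homogeneous cohorts", {
  set.seed(211)
  wt_calls <- lapply(1:8, function(i) rnorm(60, 0.052, 0.01))
  ko_calls <- lapply(1:8, function(i) rnorm(60, 0.044, 0.01))
  t_animal <- ttest_two_tailed(sapply(wt_calls, mean), sapply(ko_calls, mean))
  t_call <- per_call_comparison(unlist(wt_calls), unlist(ko_calls))
  expect_identical(sign(t_animal$t), sign(t_call$t))
})

test_that("bootstrap spectrum bands honour the adjacency rule", {
  set.seed(221)
  nb <- 40
  base <- exp(-seq_len(nb) / 15)
  mk <- function(n, scale) t(replicate(n, base * scale * runif(nb, 0.9, 1.1)))
  # identical subjects: zero-width intervals
  same <- matrix(rep(base, 5), 5, byrow = TRUE)
  bs <- bootstrap_spectra(same, same + 0, reps = 200, seed = 1)
  expect_true(all(bs$group_a$upper - bs$group_a$lower < 1e-12))
  # a high-band attenuation produces contiguous reported-significant bins
  a <- mk(10, 1); b <- mk(10, 1); b[, 25:40] <- b[, 25:40] * 0.4
  bs2 <- bootstrap_spectra(a, b, reps = 400, seed = 2)
  expect_gt(sum(bs2$reported[25:40]), 8)
  expect_true(all(!bs2$reported[1:20]))
  # an isolated significant bin is suppressed
  sig <- c(rep(FALSE, 5), TRUE, rep(FALSE, 5))
  neighbour <- c(sig[-1], FALSE) | c(FALSE, sig[-11])
  expect_true(all(!(sig & neighbour)))
  expect_error(bootstrap_spectra(a[1:2, ], b, reps = 10), "3 subjects")
})

test_that("bootstrap intervals are stable across seeds at n = 20", {
  set.seed(231)
  m <- t(replicate(20, exp(-seq_len(30) / 10) * runif(30, 0.8, 1.2)))
  b1 <- bootstrap_spectra(m, m * 0.9, reps = 1000, seed = 10)
  b2 <- bootstrap_spectra(m, m * 0.9, reps = 1000, seed = 20)
  rel <- abs(b1$group_a$lower - b2$group_a$lower) / b1$group_a$mean
  expect_lt(max(rel), 0.02)
})

test_that("weight correlations recover couplings and flag degenerate input", {
  set.seed(241)
  n <- 40
  s <- data.frame(genotype = "WT", day = 8, weight = rnorm(n, 4.3, 0.6))
  s$intra_pause <- 0.2 - 0.01 * s$weight + rnorm(n, 0, 0.005)
  s$noise_metric <- rnorm(n)
  s$self <- s$weight
  expect_lt(weight_correlation(s, "intra_pause")$r, -0.3)
  expect_equal(weight_correlation(s, "self")$r, 1)
  expect_lt(abs(weight_correlation(s, "noise_metric")$r), 0.35)
  s$flat <- 1
  expect_warning(res <- weight_correlation(s, "flat"), "constant")
  expect_true(is.na(res$r))
})
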