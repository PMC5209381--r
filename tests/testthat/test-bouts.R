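# Pause extraction, histogram-trough cutoff estimation, bout partitioning.

calls_at <- function(onsets, dur = 0.05)
  data.frame(onset = onsets, offset = onsets + dur, duration = dur)

test_that("pause_lengths returns consecutive offset-to-onset gaps", {
  cl <- data.frame(onset = c(0, 0.25), offset = c(0.05, 0.30))
  expect_equal(pause_lengths(cl), 0.20)
  cl5 <- calls_at(c(0, 1, 2, 3, 4))
  expect_length(pause_lengths(cl5), 4L)
  expect_length(pause_lengths(cl5[1, ]), 0L)
})

test_that("generated gaps match the generator's drawn event stream", {
  p <- usv_presets("WT", 8)
  ann <- synth_annotation(p, quick_meta(60), seed = 101)
  gaps <- pause_lengths(ann$calls)
  expect_length(gaps, nrow(ann$calls) - 1L)
  expect_true(all(gaps > 0))
  # gaps between bouts all exceed the inter-pause floor; within-bout gaps
  # stay below the intra truncation
  same_bout <- diff(ann$calls$bout) == 0
  expect_true(all(gaps[same_bout] < 0.22))
  expect_true(all(gaps[!same_bout] >= 0.33))
})

test_that("cutoff estimation recovers a planted trough at 0.25 s", {
  set.seed(111)
  # bimodal gaps: intra mode ~0.12 s, inter mode ~2 s, trough near 0.25 s
  gaps <- c(rgamma(4000, shape = 36, rate = 300),
            0.35 + rexp(800, 1 / 1.65))
  est <- estimate_bout_cutoff(gaps)
  expect_lt(abs(est - 0.25), 0.03)
  # brute-force oracle: same algorithm written independently
  oracle <- local({
    cs <- sapply(seq(0.05, 0.30, by = 0.01), function(b) {
      h <- hist(gaps, breaks = seq(0, max(gaps) + b, by = b), plot = FALSE)
      m <- h$mids[h$mids >= 0.15 & h$mids <= 0.32]
      ct <- h$counts[h$mids >= 0.15 & h$mids <= 0.32]
      if (!length(m)) return(NA_real_)
      m[which.min(ct)]
    })
    mean(cs, na.rm = TRUE)
  })
  expect_equal(est, oracle, tolerance = 1e-12)
})

test_that("degenerate gap sets cannot produce a cutoff", {
  expect_error(suppressWarnings(estimate_bout_cutoff(rep(0.05, 200),
                                                     bin_sizes = 0.29)))
  expect_warning(estimate_bout_cutoff(c(rep(0.1, 50), rep(2, 20))), "100")
})

test_that("cohort-level cutoffs land inside the search range by construction", {
  coh <- sample_cohort(c(WT = 6), day = 8, seed = 121, duration = 120,
                       detail = "timing")
  gaps <- unlist(lapply(coh, function(r) pause_lengths(r$calls)))
  est <- suppressWarnings(estimate_bout_cutoff(gaps))
  expect_gte(est, 0.15); expect_lte(est, 0.32)
})

test_that("bout partitioning splits exactly at the cutoff", {
  cl <- calls_at(c(0, 0.15, 0.70, 0.85))     # gaps 0.10, 0.50, 0.10
  part <- partition_bouts(cl, 0.239)
  expect_equal(part$sizes, c(2L, 2L))
  expect_equal(max(part$bout), 2L)
  part1 <- partition_bouts(calls_at(c(0, 0.1, 0.2)), 1)
  expect_equal(part1$sizes, 3L)
  part_iso <- partition_bouts(calls_at(c(0, 1, 2)), 0.2)
  expect_equal(part_iso$sizes, c(1L, 1L, 1L))
  # boundary: a gap exactly at the cutoff separates bouts
  cl_b <- calls_at(c(0, 0.289))              # gap exactly 0.239
  expect_equal(max(partition_bouts(cl_b, 0.239)$bout), 2L)
})

test_that("bout metrics count isolated calls and pause classes correctly", {
  # bout sizes 1, 4, 5 over ten calls
  onsets <- c(0, 1.0, 1.1, 1.2, 1.3, 3.0, 3.1, 3.2, 3.3, 3.4)
  part <- partition_bouts(calls_at(onsets, dur = 0.04), 0.25)
  m <- bout_metrics(part)
  expect_equal(m$n_bouts, 3)
  expect_equal(m$calls_per_bout, 10 / 3)
  expect_equal(m$percent_isolated, 10)
  expect_equal(sum(part$intra) + sum(!part$intra), length(part$gaps))
  single <- bout_metrics(partition_bouts(calls_at(seq(0, 0.6, by = 0.1),
                                                  dur = 0.04), 0.25))
  expect_equal(single$percent_isolated, 0)
})

test_that("the long-pause curve is a survival function", {
  set.seed(131)
  gaps <- rexp(4000, rate = 2)
  grid <- seq(0, 3, by = 0.1)
  curve <- long_pause_curve(gaps, grid)
  expect_equal(curve[1], 1)
  expect_equal(long_pause_curve(gaps, max(gaps) + 1), 0)
  expect_true(all(diff(curve) <= 0))
  # closed-form exponential survival within binomial error
  expect_lt(max(abs(curve - exp(-2 * grid))), 3 * sqrt(0.25 / 4000) + 0.01)
})
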