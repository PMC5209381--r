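# Synthetic-cohort generator: validity, determinism, ground-truth geometry
# and convergence of group means to the configured values.

test_that("parameter validation rejects inconsistent settings", {
  expect_error(usv_params(inter_bout_pause_mean = 0.1,
                          intra_bout_pause_mean = 0.2),
               "inter_bout_pause_mean")
  expect_error(usv_params(base_freq_range = c(95e3, 55e3)), "base_freq_range")
  expect_error(usv_params(base_freq_range = c(10e3, 95e3)), "base_freq_range")
  expect_error(usv_params(isolated_call_prob = 1.2), "isolated_call_prob")
  expect_error(usv_params(amplitude = 0), "amplitude")
  expect_error(recording_meta("x", "WT", 8, duration = -1), "duration")
  expect_error(recording_meta("x", "WT", day = 6), "day")
})

test_that("a zero call rate yields an empty, call-free truth", {
  p <- usv_params(calls_per_bout_mean = 0)
  ann <- synth_annotation(p, quick_meta(30), seed = 1)
  expect_identical(nrow(ann$calls), 0L)
  rec <- synth_recording(p, quick_meta(2), seed = 1)
  expect_identical(nrow(rec$truth$calls), 0L)
  expect_length(rec$wave, 2 * 250e3)
})

test_that("a recording too short for any call errors", {
  p <- usv_presets("WT", 8)
  expect_error(synth_annotation(p, quick_meta(0.2), seed = 1), "too short")
})

test_that("the event process is deterministic given a seed and shared by both paths", {
  p <- usv_presets("WT", 8)
  a1 <- synth_annotation(p, quick_meta(20), seed = 42)
  a2 <- synth_annotation(p, quick_meta(20), seed = 42)
  expect_identical(a1$calls, a2$calls)
  expect_identical(a1$jumps, a2$jumps)
  rec <- synth_recording(p, quick_meta(20), seed = 42)
  expect_identical(rec$truth$calls[, c("onset", "offset")],
                   a1$calls[, c("onset", "offset")])
  expect_length(rec$wave, 20 * 250e3)
})

test_that("ground-truth intervals are disjoint, increasing, with positive gaps", {
  p <- usv_presets("KO", 5)
  for (s in 1:5) {
    ann <- synth_annotation(p, quick_meta(60), seed = s)
    cl <- ann$calls
    expect_true(all(diff(cl$onset) > 0))
    expect_true(all(cl$onset[-1] - cl$offset[-nrow(cl)] > 0))
    expect_true(all(cl$duration > 0))
    expect_true(all(ann$jumps$call %in% cl$call))
    expect_true(all(abs(ann$jumps$size) > 0))
    # pitch stays inside the detection band
    fr <- unlist(lapply(ann$pitch, function(x) x$freq))
    expect_true(all(fr > 25e3 & fr < 110e3))
  }
})

test_that("isolated_call_prob = 1 makes every bout a single call", {
  p <- usv_params(calls_per_bout_mean = 1, isolated_call_prob = 1)
  ann <- synth_annotation(p, quick_meta(30), seed = 3, animal_jitter = FALSE)
  expect_true(all(table(ann$calls$bout) == 1))
})

test_that("group means of duration, pause and calls/bout converge to the presets", {
  p8 <- usv_presets("WT", 8)
  set.seed(5)
  nrec <- 150
  stats <- t(replicate(nrec, {
    ann <- synth_annotation(p8, quick_meta(210), detail = "timing")
    gaps <- pause_lengths(ann$calls)
    intra <- gaps[gaps < 0.25]
    c(dur = mean(ann$calls$duration), intra = mean(intra),
      cpb = nrow(ann$calls) / max(ann$calls$bout))
  }))
  # within 3 standard errors of the configured group values
  for (nm in c("dur", "intra", "cpb")) {
    target <- switch(nm, dur = 0.052, intra = 0.133, cpb = 5.28)
    se <- sd(stats[, nm]) / sqrt(nrec)
    expect_lt(abs(mean(stats[, nm]) - target), 3 * se + 0.01 * target)
  }
})

test_that("WT and KO presets reproduce the published P8 duration contrast", {
  set.seed(17)
  mean_dur <- function(g) {
    p <- usv_presets(g, 8)
    mean(replicate(120, {
      ann <- synth_annotation(p, quick_meta(210), detail = "timing")
      mean(ann$calls$duration)
    }))
  }
  # published per-animal group means: WT 0.052 s, KO 0.046 s (SEM 0.002)
  expect_lt(abs(mean_dur("WT") - 0.052), 0.004)
  expect_lt(abs(mean_dur("KO") - 0.046), 0.004)
})

test_that("mean calls per bout matches the configured 5.28 within 5%", {
  set.seed(23)
  p <- usv_presets("WT", 8)
  cpb <- replicate(200, {
    ann <- synth_annotation(p, quick_meta(210), detail = "timing")
    nrow(ann$calls) / max(ann$calls$bout)
  })
  expect_lt(abs(mean(cpb) - 5.28) / 5.28, 0.05)
})

test_that("cohort sampling respects group sizes, drops empty groups, and is reproducible", {
  coh <- sample_cohort(c(WT = 5, HET = 0, KO = 3), day = 8, seed = 9,
                       duration = 20, detail = "timing")
  meta <- attr(coh, "meta")
  expect_identical(nrow(meta), 8L)
  expect_identical(sum(meta$genotype == "WT"), 5L)
  expect_identical(sum(meta$genotype == "KO"), 3L)
  expect_false(any(meta$genotype == "HET"))
  coh2 <- sample_cohort(c(WT = 5, HET = 0, KO = 3), day = 8, seed = 9,
                        duration = 20, detail = "timing")
  expect_identical(attr(coh2, "meta"), meta)
  expect_identical(coh2[[1]]$calls, coh[[1]]$calls)
})

test_that("per-genotype weights reproduce the configured model", {
  set.seed(31)
  coh <- sample_cohort(c(WT = 120), day = 8, seed = 40, duration = 20,
                       detail = "timing")
  w <- attr(coh, "meta")$weight
  expect_lt(abs(mean(w) - 4.34), 3 * 0.70 / sqrt(120))
  expect_lt(abs(sd(w) - 0.70), 0.25)
})

test_that("rendered waveforms are 16-bit quantised and carry the stated SNR", {
  p <- usv_presets("WT", 8)
  rec <- synth_recording(p, quick_meta(5), seed = 2, snr_db = 20)
  expect_true(all(abs(rec$wave * 32767 - round(rec$wave * 32767)) < 1e-6))
  # noise floor: samples outside calls
  mask <- rep(TRUE, length(rec$wave))
  for (i in seq_len(nrow(rec$truth$calls))) {
    i0 <- round(rec$truth$calls$onset[i] * rec$fs)
    i1 <- round(rec$truth$calls$offset[i] * rec$fs)
    mask[max(1, i0 - 500):min(length(mask), i1 + 500)] <- FALSE
  }
  for (tc in rec$truth$clicks) {
    i0 <- round(tc * rec$fs)
    mask[max(1, i0 - 200):min(length(mask), i0 + 800)] <- FALSE
  }
  sigma_obs <- sd(rec$wave[mask])
  band_frac <- (110e3 - 25e3) / (rec$fs / 2)
  sigma_exp <- 0.25 * 10^(-1) / sqrt(2 * band_frac)
  expect_lt(abs(sigma_obs - sigma_exp) / sigma_exp, 0.05)
})
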