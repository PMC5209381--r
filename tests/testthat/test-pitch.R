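# Pitch tracking, jump detection over the threshold grid, call spectra.

make_track <- function(freq, dt = 256 / 250e3) {
  structure(data.frame(time = seq_along(freq) * dt, freq = freq),
            class = c("usv_pitch", "data.frame"))
}

test_that("pitch tracks follow constant tones and ramps, marking dropouts", {
  st <- single_tone(freq = 70e3, onset = 0.05, dur = 0.04, total = 0.15,
                    seed = 61)
  fr <- frame_features(compute_sonogram(st$wave, st$fs))
  calls <- detect_calls(fr)
  tr <- pitch_track(fr, calls[1, ])
  expect_true(all(abs(tr$freq - 70e3) < 1000, na.rm = TRUE))
  expect_lt(mean(is.na(tr$freq)), 0.1)

  # ramp 60 -> 80 kHz tracked within one bin of truth
  st2 <- single_tone(freq = c(60e3, 80e3), onset = 0.05, dur = 0.04,
                     total = 0.15, seed = 62)
  fr2 <- frame_features(compute_sonogram(st2$wave, st2$fs))
  calls2 <- detect_calls(fr2)
  tr2 <- pitch_track(fr2, calls2[1, ])
  ok <- !is.na(tr2$freq)
  truth <- approx(c(st2$onset, st2$offset), c(60e3, 80e3),
                  tr2$time[ok], rule = 2)$y
  expect_lt(max(abs(tr2$freq[ok] - truth)), 250e3 / 512 + 300)
  expect_true(all(diff(tr2$freq[ok]) > -600))

  # a silent gap inside the call shows up as dropouts
  st3 <- single_tone(freq = 70e3, onset = 0.05, dur = 0.015, total = 0.15,
                     seed = 63)
  st3b <- single_tone(freq = 70e3, onset = 0.075, dur = 0.015, total = 0.15,
                      seed = 63)
  wave <- st3$wave + st3b$wave - rnorm(length(st3$wave)) * 0   # two bursts
  fr3 <- frame_features(compute_sonogram(wave, st3$fs))
  calls3 <- detect_calls(fr3, merge_gap = 0.02)
  expect_identical(nrow(calls3), 1L)
  tr3 <- pitch_track(fr3, calls3[1, ])
  expect_gt(sum(is.na(tr3$freq)), 2)
})

test_that("jump detection applies the signed threshold rule", {
  tr <- make_track(c(80e3, 80e3, 92e3, 92e3))
  j5 <- detect_jumps(tr, 5000)
  expect_identical(nrow(j5), 1L)
  expect_equal(j5$size, 12e3)
  expect_identical(nrow(detect_jumps(tr, 15000)), 0L)
  expect_error(detect_jumps(tr, -1))
})

test_that("jump counts are monotone in threshold and split by sign", {
  set.seed(71)
  for (i in 1:20) {
    tr <- make_track(runif(30, 40e3, 100e3))
    counts <- jump_count_grid(tr)
    pos <- counts[grep("pos", names(counts))]
    neg <- counts[grep("neg", names(counts))]
    expect_true(all(diff(pos) <= 0))
    expect_true(all(diff(neg) <= 0))
    thr <- jump_threshold_grid()[3]
    expect_equal(unname(pos[3] + neg[3]), nrow(detect_jumps(tr, thr)))
  }
})

test_that("max_jump takes the largest absolute step and survives reversal", {
  tr <- make_track(c(70e3, 73e3, 61e3))       # steps +3k, -12k
  expect_equal(max_jump(tr), 12e3)
  rev_tr <- make_track(rev(tr$freq))
  expect_equal(max_jump(rev_tr), 12e3)
  expect_equal(max_jump(make_track(rep(70e3, 5))), 0)
  expect_true(is.na(max_jump(make_track(c(70e3, NA, NA)))))
})

test_that("jumps bridge brief dropouts but not long ones", {
  f <- c(80e3, 80e3, NA, NA, 92e3)            # 2 dropout frames ~ 2 ms
  expect_identical(nrow(detect_jumps(make_track(f), 5000)), 1L)
  f2 <- c(80e3, 80e3, rep(NA, 15), 92e3)      # ~15 ms gap: not bridged
  expect_identical(nrow(detect_jumps(make_track(f2), 5000)), 0L)
})

test_that("planted jumps are recovered exactly at sub-jump thresholds", {
  p <- usv_presets("WT", 8)
  for (s in 81:83) {
    ann <- synth_annotation(p, quick_meta(30), seed = s)
    planted <- nrow(ann$jumps)
    found <- sum(vapply(ann$pitch, function(tr)
      nrow(detect_jumps(tr, 5000)), integer(1)))
    expect_identical(found, planted)
  }
})

test_that("call spectra peak at the tone and scale as amplitude squared", {
  st <- single_tone(freq = 70e3, onset = 0.05, dur = 0.04, total = 0.15,
                    amp = 0.2, seed = 91)
  s1 <- compute_sonogram(st$wave, st$fs)
  calls <- detect_calls(frame_features(s1))
  sp1 <- call_power_spectrum(s1, calls)
  expect_lt(abs(sp1$freq[which.max(sp1$power)] - 70e3), 1000)
  expect_true(all(sp1$power >= 0))
  expect_equal(sp1$total, sum(sp1$power))

  st2 <- single_tone(freq = 70e3, onset = 0.05, dur = 0.04, total = 0.15,
                     amp = 0.4, snr_db = 40, seed = 91)
  s2 <- compute_sonogram(st2$wave, st2$fs)
  sp2 <- call_power_spectrum(s2, detect_calls(frame_features(s2)))
  expect_equal(max(sp2$power) / max(sp1$power), 4, tolerance = 0.1)
  expect_error(call_power_spectrum(s1, calls[0, ]), "no calls")
})
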