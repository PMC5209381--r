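# Synthetic pup isolation-call cohorts with full ground truth.
#
# The event process is shared between the annotation-only and the audio path:
# bouts alternate with inter-bout pauses, calls within a bout are separated by
# gamma-distributed intra-bout pauses, and each call carries a piecewise-linear
# frequency contour on which pitch jumps are planted as instantaneous steps.

usv_hop <- function(fs = 250e3, block = 512L) (block / 2) / fs

# vectorised truncated-normal draw by rejection
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (n == 0) return(numeric(0))
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- pmin(pmax(x[bad], lo), hi)
  x
}

# gamma draw with fixed mean, truncated above
rtgamma <- function(n, mean, shape, hi) {
  if (n == 0) return(numeric(0))
  x <- stats::rgamma(n, shape = shape, rate = shape / mean)
  bad <- which(x >= hi)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    x[bad] <- stats::rgamma(length(bad), shape = shape, rate = shape / mean)
    bad <- bad[x[bad] >= hi]
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- hi * 0.99
  x
}

# Draw animal-level parameter means around the group means. Truncation windows
# are centred on the group value and intersected with legal ranges so that
# degenerate settings (e.g. isolated_call_prob = 1) survive unchanged.
draw_animal_params <- function(p) {
  b <- p$between
  tn <- function(m, sd, lo, hi) rtnorm(1, m, sd, max(lo, m - 4 * sd), min(hi, m + 4 * sd))
  list(
    duration  = tn(p$mean_call_duration, b$duration, 0.020, 0.150),
    intra     = tn(p$intra_bout_pause_mean, b$intra_pause, 0.060,
                   p$intra_pause_max - 0.015),
    inter     = tn(p$inter_bout_pause_mean, b$inter_pause,
                   p$inter_pause_min + 0.10, 12),
    cpb       = if (p$calls_per_bout_mean == 0) 0 else
                tn(p$calls_per_bout_mean, b$calls_per_bout, 1.0, 20),
    iso       = tn(p$isolated_call_prob, b$isolated, 0.002, 1),
    jump_prob = tn(p$jump_prob_per_call, b$jump_prob, 0.02, 0.98),
    jump_size = tn(p$jump_size_mean, b$jump_size, p$jump_size_min + 2000, 3.2e4)
  )
}

# Build one call's frequency contour. Returns knots of the piecewise-linear
# base contour (absolute times/Hz), planted jumps, and the shape label.
make_contour <- function(p, onset, dur, a) {
  harmonic <- stats::runif(1) < p$harmonic_prob
  shp <- if (harmonic) "flat" else
    sample(names(p$shape_weights), 1, prob = p$shape_weights)
  if (shp == "flat") {
    kt <- c(0, dur); kf <- c(0, stats::runif(1, -1200, 1200))
  } else if (shp == "up") {
    kt <- c(0, dur); kf <- c(0, stats::runif(1, 5e3, 14e3))
  } else if (shp == "down") {
    kt <- c(0, dur); kf <- c(0, -stats::runif(1, 5e3, 14e3))
  } else { # chevron
    rise <- stats::runif(1, 5e3, 12e3); fall <- stats::runif(1, 5e3, 12e3)
    kt <- c(0, stats::runif(1, 0.35, 0.65) * dur, dur)
    kf <- c(0, rise, rise - fall)
  }

  # pitch jumps: instantaneous steps at interior positions, >= 8 ms apart;
  # signs chosen so the cumulative offset never leaves +/-25 kHz, keeping the
  # whole contour placeable inside the analysis band
  jt <- numeric(0); js <- numeric(0)
  if (!harmonic && stats::runif(1) < p$jump_prob_per_call) {
    kmax <- max(1L, floor(0.6 * dur / 0.008))
    nj <- min(1L + stats::rpois(1, p$jump_extra_rate), kmax)
    for (tries in 1:25) {
      jt <- sort(stats::runif(nj, 0.2 * dur, 0.8 * dur))
      if (nj == 1L || min(diff(jt)) >= 0.008) break
      if (tries == 25L) { nj <- 1L; jt <- jt[1] }
    }
    sz <- rtnorm(nj, a$jump_size, p$jump_size_sd, p$jump_size_min, 32e3)
    js <- numeric(nj); cum <- 0
    for (i in seq_len(nj)) {
      sgn <- sample(c(-1, 1), 1)
      if (abs(cum + sgn * sz[i]) > 32e3) sgn <- -sgn
      js[i] <- sgn * sz[i]
      cum <- cum + js[i]
    }
  }

  # place the base frequency: the contour must stay inside 28-107 kHz, and
  # should start inside the preferred base range when feasible
  band <- if (harmonic) c(30e3, 48e3) else p$base_freq_range
  tt <- seq(0, dur, length.out = 64)
  g <- stats::approx(kt, kf, tt, rule = 2)$y
  for (i in seq_along(jt)) g <- g + js[i] * (tt >= jt[i])
  glo <- min(g); ghi <- max(g)
  flo <- 28e3 - glo; fhi <- 107e3 - ghi
  plo <- max(flo, band[1]); phi <- min(fhi, band[2])
  f0 <- if (plo <= phi) stats::runif(1, plo, phi)
  else if (flo <= fhi) stats::runif(1, flo, fhi)
  else 67.5e3 - (glo + ghi) / 2

  label <- if (harmonic) "harmonic"
  else if (length(js) >= 2) "multi-jump"
  else if (length(js) == 1 && js > 0) "one-jump-up"
  else if (length(js) == 1) "one-jump-down"
  else switch(shp, flat = "flat", up = "up-FM", down = "down-FM",
              chevron = "chevron")

  list(knot_t = onset + kt, knot_f = f0 + kf, jump_t = onset + jt,
       jump_size = js, harmonic = harmonic, label = label)
}

# evaluate a contour at absolute times
contour_freq <- function(ct, t) {
  f <- stats::approx(ct$knot_t, ct$knot_f, t, rule = 2)$y
  for (i in seq_along(ct$jump_t)) f <- f + ct$jump_size[i] * (t >= ct$jump_t[i])
  f
}

#' Generate the annotation-level event stream of one synthetic recording
#'
#' Runs the bout/call/pitch event process without rendering audio. The same
#' process underlies [synth_recording()], so for a given seed both produce
#' identical ground truth.
#'
#' @param params A [usv_params()] object (group-level parameters).
#' @param meta A [recording_meta()] object.
#' @param seed Optional integer seed; when given, output is reproducible.
#' @param detail `"full"` generates pitch contours, jumps, labels and clicks;
#'   `"timing"` generates call intervals and bout structure only (fast path
#'   for pause/bout statistics at scale).
#' @param animal_jitter Draw animal-level parameter means around the group
#'   means using `params$between` (default). Disable to generate directly at
#'   the group means.
#'
#' @return An object of class `usv_annotation`: a list with `calls` (data
#'   frame: `call`, `onset`, `offset`, `duration`, `bout`, `label`), `pitch`
#'   (list of per-call data frames `time`/`freq`, sampled on the 1.024 ms
#'   sonogram frame grid), `jumps` (data frame: `call`, `time`, `size` signed
#'   Hz), `clicks` (numeric times), `meta`, and `animal` (the drawn
#'   animal-level means). The full-detail path also carries the exact
#'   contour breakpoints in element `contours`, used for audio rendering.
#' @export
synth_annotation <- function(params, meta, seed = NULL,
                             detail = c("full", "timing"),
                             animal_jitter = TRUE) {
  validate_usv_params(params)
  stopifnot(inherits(meta, "usv_meta"))
  detail <- match.arg(detail)
  if (!is.null(seed)) set.seed(seed)

  a <- if (animal_jitter) draw_animal_params(params) else
    list(duration = params$mean_call_duration,
         intra = params$intra_bout_pause_mean,
         inter = params$inter_bout_pause_mean,
         cpb = params$calls_per_bout_mean,
         iso = params$isolated_call_prob,
         jump_prob = params$jump_prob_per_call,
         jump_size = params$jump_size_mean)

  dur_rec <- meta$duration
  hop <- usv_hop()
  empty <- function() {
    calls <- data.frame(call = integer(0), onset = numeric(0),
                        offset = numeric(0), duration = numeric(0),
                        bout = integer(0), label = character(0))
    structure(list(calls = calls, pitch = list(),
                   jumps = data.frame(call = integer(0), time = numeric(0),
                                      size = numeric(0)),
                   clicks = numeric(0), meta = meta, animal = a),
              class = "usv_annotation")
  }
  if (a$cpb == 0) return(empty())

  m <- a$cpb
  # P(bout is a single isolated call); capped so that jointly extreme draws
  # of isolated fraction and calls/bout cannot degenerate into all-singleton
  # recordings with absurd rare-bout sizes
  q <- min(a$iso * m, if (a$iso >= 1) 1 else 0.8)
  m2 <- min(max((m - q) / max(1 - q, 1e-9), 2), 30) # mean multi-bout size
  cycle <- m * a$duration + max(m - 1, 0) * a$intra + a$inter
  nb_max <- ceiling(dur_rec / cycle * 1.6) + 15L

  sizes <- ifelse(stats::runif(nb_max) < q, 1L,
                  2L + stats::rpois(nb_max, max(m2 - 2, 0.01)))
  n <- sum(sizes)
  durs <- rtnorm(n, a$duration, params$call_duration_sd, 0.018, 0.200)
  bout_id <- rep(seq_len(nb_max), sizes)
  within <- sequence(sizes)
  gap_before <- numeric(n)
  gap_before[within > 1] <- rtgamma(sum(within > 1), a$intra,
                                    params$intra_pause_shape,
                                    params$intra_pause_max)
  first_of_bout <- which(within == 1L)
  inter_mean_ex <- max(a$inter - params$inter_pause_min, 0.05)
  gap_before[first_of_bout[-1]] <-
    params$inter_pause_min + stats::rexp(nb_max - 1L, 1 / inter_mean_ex)
  t0 <- stats::runif(1, params$start_window[1], params$start_window[2])

  onsets <- t0 + cumsum(c(0, durs[-n] + gap_before[-1]))
  offsets <- onsets + durs
  keep_n <- suppressWarnings(max(which(offsets <= dur_rec - 0.05)))
  if (!is.finite(keep_n) || keep_n < 1)
    stop("recording too short for the configured call process")
  idx <- seq_len(keep_n)
  onsets <- onsets[idx]; offsets <- offsets[idx]; durs <- durs[idx]
  bout <- match(bout_id[idx], unique(bout_id[idx]))

  calls <- data.frame(call = idx, onset = onsets, offset = offsets,
                      duration = durs, bout = bout,
                      label = NA_character_)

  if (detail == "timing") {
    return(structure(list(calls = calls, pitch = NULL,
                          jumps = data.frame(call = integer(0),
                                             time = numeric(0),
                                             size = numeric(0)),
                          clicks = numeric(0), meta = meta, animal = a),
                     class = "usv_annotation"))
  }

  contours <- vector("list", keep_n)
  pitch <- vector("list", keep_n)
  jl <- vector("list", keep_n)
  for (i in idx) {
    ct <- make_contour(params, onsets[i], durs[i], a)
    contours[[i]] <- ct
    calls$label[i] <- ct$label
    ft <- seq(onsets[i] + hop / 2, offsets[i] - hop / 4, by = hop)
    pitch[[i]] <- data.frame(time = ft, freq = contour_freq(ct, ft))
    if (length(ct$jump_t))
      jl[[i]] <- data.frame(call = i, time = ct$jump_t, size = ct$jump_size)
  }
  jumps <- if (any(!vapply(jl, is.null, logical(1))))
    do.call(rbind, jl[!vapply(jl, is.null, logical(1))])
  else data.frame(call = integer(0), time = numeric(0), size = numeric(0))

  n_clicks <- stats::rpois(1, params$click_rate * dur_rec)
  clicks <- sort(stats::runif(n_clicks, 0.2, dur_rec - 0.2))
  if (length(clicks) && keep_n) {
    near_call <- vapply(clicks, function(tc)
      any(tc > onsets - 0.01 & tc < offsets + 0.01), logical(1))
    clicks <- clicks[!near_call]
  }

  structure(list(calls = calls, pitch = pitch, jumps = jumps,
                 clicks = clicks, meta = meta, animal = a,
                 contours = contours),
            class = "usv_annotation")
}

#' Render one synthetic recording to a waveform
#'
#' Generates the event stream with [synth_annotation()] and renders it:
#' frequency-modulated tones (phase-continuous across pitch jumps) with 2 ms
#' raised-cosine on/off ramps, riding on Gaussian background noise; harmonic
#' calls carry one overtone at 0.35 relative amplitude; clicks are 1.5 ms
#' broadband noise bursts. Power above 65 kHz is attenuated by
#' `params$high_band_power_scale`. Samples are quantised to 16-bit
#' resolution.
#'
#' @inheritParams synth_annotation
#' @param snr_db Tonal signal-to-noise ratio in dB, defined as peak call
#'   power over total in-band (25-110 kHz) noise power.
#' @param fs Sampling rate in Hz (default 250 kHz).
#' @return An object of class `usv_recording`: list with `wave` (double
#'   samples in `[-1, 1]`, 16-bit quantised), `fs`, `meta`, `truth` (the
#'   `usv_annotation`).
#' @export
synth_recording <- function(params, meta, seed = NULL, snr_db = 20,
                            fs = 250e3, animal_jitter = TRUE) {
  truth <- synth_annotation(params, meta, seed = seed, detail = "full",
                            animal_jitter = animal_jitter)
  n <- round(meta$duration * fs)
  band_frac <- (110e3 - 25e3) / (fs / 2)
  sigma <- params$amplitude * 10^(-snr_db / 20) / sqrt(2 * band_frac)
  wave <- stats::rnorm(n, sd = sigma)

  hb <- sqrt(params$high_band_power_scale)
  for (i in seq_len(nrow(truth$calls))) {
    on <- truth$calls$onset[i]; off <- truth$calls$offset[i]
    i0 <- max(1L, round(on * fs) + 1L); i1 <- min(n, round(off * fs))
    if (i1 - i0 < 16L) next
    tt <- (seq(i0, i1) - 1) / fs
    f <- contour_freq(truth$contours[[i]], tt)
    phase <- 2 * pi * cumsum(f) / fs
    m <- length(tt)
    nr <- min(round(0.002 * fs), floor(m / 2))
    env <- rep(1, m)
    if (nr > 0) {
      ramp <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
      env[seq_len(nr)] <- ramp
      env[m - nr + seq_len(nr)] <- rev(ramp)
    }
    gain <- params$amplitude * (1 + (hb - 1) * stats::plogis((f - 65e3) / 2e3))
    cw <- gain * env * sin(phase)
    if (truth$contours[[i]]$harmonic) cw <- cw + 0.35 * gain * env * sin(2 * phase)
    wave[i0:i1] <- wave[i0:i1] + cw
  }

  for (tc in truth$clicks) {
    nb <- round(0.0015 * fs)
    i0 <- round(tc * fs) + 1L; i1 <- min(n, i0 + nb - 1L)
    env <- 0.5 - 0.5 * cos(2 * pi * seq_len(i1 - i0 + 1L) / (i1 - i0 + 1L))
    wave[i0:i1] <- wave[i0:i1] +
      stats::rnorm(i1 - i0 + 1L, sd = 0.5 * params$amplitude) * env
  }

  wave <- pmin(pmax(wave, -1), 1)
  wave <- round(wave * 32767) / 32767
  structure(list(wave = wave, fs = fs, meta = meta, truth = truth),
            class = "usv_recording")
}

#' Generate a synthetic cohort of recordings
#'
#' Draws `n[g]` animals per genotype at the given postnatal day, each with its
#' own metadata (id, sex, body weight from the genotype weight model) and an
#' annotation-only event stream or a rendered waveform.
#'
#' @param n Named integer vector of group sizes, e.g. `c(WT = 41, KO = 15)`.
#'   Defaults mirror the study cohort (P5: 40/13, P8: 41/15).
#' @param day Postnatal day (5 or 8); selects the [usv_presets()] defaults.
#' @param params Optional named list of `usv_params` per genotype, overriding
#'   the presets.
#' @param seed Optional integer seed for the whole cohort.
#' @param audio If `TRUE` render waveforms with [synth_recording()];
#'   otherwise annotation-only.
#' @param duration Recording duration in seconds.
#' @param snr_db Tonal SNR for rendered audio.
#' @param detail Passed to [synth_annotation()] when `audio = FALSE`.
#' @return A list of class `usv_cohort`: elements are `usv_recording` or
#'   `usv_annotation` objects; the per-recording metadata table is attached
#'   as attribute `"meta"` (data frame with `animal_id`, `genotype`, `day`,
#'   `weight`, `sex`, `duration`).
#' @export
sample_cohort <- function(n = NULL, day = 8, params = NULL, seed = NULL,
                          audio = FALSE, duration = 210, snr_db = 20,
                          detail = "full") {
  day <- as.integer(day)
  if (is.null(n)) n <- if (day == 8L) c(WT = 41L, KO = 15L) else c(WT = 40L, KO = 13L)
  if (is.null(names(n)) || !all(names(n) %in% c("WT", "HET", "KO")))
    stop("n must be a named vector with names among WT, HET, KO")
  if (!is.null(seed)) set.seed(seed)

  out <- list()
  meta_rows <- list()
  for (g in names(n)) {
    if (n[[g]] < 1) next
    p <- if (!is.null(params) && !is.null(params[[g]])) params[[g]] else
      usv_presets(g, day)
    for (i in seq_len(n[[g]])) {
      w <- rtnorm(1, p$between$weight_mean, p$between$weight_sd, 1.2, 9)
      meta <- recording_meta(sprintf("%s_%02d", g, i), genotype = g, day = day,
                             weight = w, sex = sample(c("M", "F"), 1),
                             duration = duration)
      rec <- if (audio)
        synth_recording(p, meta, snr_db = snr_db)
      else
        synth_annotation(p, meta, detail = detail)
      out[[meta$animal_id]] <- rec
      meta_rows[[meta$animal_id]] <-
        data.frame(animal_id = meta$animal_id, genotype = g, day = day,
                   weight = w, sex = meta$sex, duration = duration)
    }
  }
  attr(out, "meta") <- do.call(rbind, c(meta_rows, list(make.row.names = FALSE)))
  class(out) <- "usv_cohort"
  out
}
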