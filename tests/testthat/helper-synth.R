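# Shared fixtures: small synthetic recordings and call-matching utilities.

quick_meta <- function(duration = 20, genotype = "WT", day = 8,
                       id = "test") {
  recording_meta(id, genotype, day, duration = duration)
}

# match detected segments to ground-truth calls by >50% overlap of the true
# call; returns recall, precision and signed boundary errors (seconds)
match_calls <- function(truth, det) {
  if (nrow(det) == 0)
    return(list(recall = 0, precision = NA_real_,
                onset_err = numeric(0), offset_err = numeric(0),
                map = rep(NA_integer_, nrow(truth))))
  used <- rep(FALSE, nrow(det))
  map <- rep(NA_integer_, nrow(truth))
  oerr <- ferr <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    ov <- pmin(det$offset, truth$offset[i]) - pmax(det$onset, truth$onset[i])
    j <- which(ov > 0.5 * truth$duration[i] & !used)
    if (length(j)) {
      j <- j[1]; used[j] <- TRUE; map[i] <- j
      oerr <- c(oerr, det$onset[j] - truth$onset[i])
      ferr <- c(ferr, det$offset[j] - truth$offset[i])
    }
  }
  list(recall = mean(!is.na(map)), precision = sum(used) / nrow(det),
       onset_err = oerr, offset_err = ferr, map = map)
}

# render a single frequency-modulated tone in noise; returns wave + truth
single_tone <- function(freq = 70e3, onset = 0.1, dur = 0.05,
                        total = 0.3, amp = 0.25, snr_db = 20,
                        fs = 250e3, seed = 1) {
  set.seed(seed)
  n <- round(total * fs)
  band_frac <- (110e3 - 25e3) / (fs / 2)
  sigma <- amp * 10^(-snr_db / 20) / sqrt(2 * band_frac)
  wave <- rnorm(n, sd = sigma)
  i0 <- round(onset * fs) + 1L
  i1 <- round((onset + dur) * fs)
  tt <- seq(i0, i1)
  f <- if (length(freq) == 1) rep(freq, length(tt)) else
    approx(seq(0, 1, length.out = length(freq)), freq,
           seq(0, 1, length.out = length(tt)))$y
  phase <- 2 * pi * cumsum(f) / fs
  nr <- round(0.002 * fs)
  env <- rep(1, length(tt))
  env[seq_len(nr)] <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
  env[length(tt) - nr + seq_len(nr)] <- rev(env[seq_len(nr)])
  wave[tt] <- wave[tt] + amp * env * sin(phase)
  list(wave = wave, fs = fs, onset = onset, offset = onset + dur)
}
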