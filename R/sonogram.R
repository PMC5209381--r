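# Short-time spectral analysis: band-pass filtering, sonogram computation and
# the per-frame features (spectral purity, mean frequency, discontinuity) that
# drive call detection.

#' Zero-phase band-pass filter
#'
#' Filters a waveform with the squared magnitude response of a 4th-order
#' Butterworth band-pass (the frequency-domain equivalent of forward-backward
#' filtering, hence exactly zero-phase: onsets are not shifted). Applied by
#' overlap-save FFT convolution on power-of-two blocks, so long recordings
#' filter in a few seconds.
#'
#' @param wave Numeric waveform.
#' @param fs Sampling rate (Hz); must exceed `2 * high`.
#' @param low,high Band edges in Hz (defaults 25 and 110 kHz).
#' @param order Butterworth order of the underlying one-pass response.
#' @return Filtered waveform, same length as the input.
#' @export
bandpass <- function(wave, fs, low = 25e3, high = 110e3, order = 4) {
  if (fs <= 2 * high) stop("sampling rate too low for the requested band")
  n <- length(wave)
  nfft <- 2^ceiling(log2(min(max(n, 1024), 2^22)))
  hopb <- nfft %/% 2
  freq <- (seq_len(nfft) - 1) / nfft * fs
  freq <- pmin(freq, fs - freq)
  # |H|^2 of a Butterworth band-pass: zero-phase two-pass response
  H2 <- 1 / (1 + (low / pmax(freq, 1e-6))^(2 * order)) /
    (1 + (freq / high)^(2 * order))
  out <- numeric(n)
  pos <- 1L
  while (pos <= n) {
    i0 <- max(1L, pos - hopb %/% 2L)
    i1 <- min(n, pos + hopb - 1L + hopb %/% 2L)
    seg <- wave[i0:i1]
    seg <- c(seg, numeric(nfft - length(seg)))
    y <- Re(stats::fft(stats::fft(seg) * H2, inverse = TRUE)) / nfft
    j0 <- pos; j1 <- min(n, pos + hopb - 1L)
    out[j0:j1] <- y[(j0 - i0 + 1L):(j1 - i0 + 1L)]
    pos <- pos + hopb
  }
  out
}

#' Compute the sonogram of a waveform
#'
#' Short-time power spectrogram with the analysis conventions used throughout
#' the package: 512-sample Hann-windowed blocks with half overlap, giving a
#' time step of `256/fs` (1.024 ms at 250 kHz, conventionally reported as
#' 1.02 ms) and a reported frequency resolution of `fs/(block/2)` (0.98 kHz
#' at 250 kHz; the bin spacing itself is `fs/block`).
#'
#' @param wave Numeric waveform (length at least `block`).
#' @param fs Sampling rate in Hz.
#' @param block Samples per block (default 512).
#' @return Object of class `usv_sonogram`: list with `power` (time x
#'   frequency matrix of squared magnitudes), `time` (frame centres, s),
#'   `freq` (bin centres, Hz, 0 to fs/2), `fs`, `block`.
#' @export
compute_sonogram <- function(wave, fs, block = 512L) {
  n <- length(wave)
  if (n < block) stop("waveform shorter than one block")
  hop <- block %/% 2L
  nfr <- (n - block) %/% hop + 1L
  nbin <- block %/% 2L + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(block) / block)
  power <- matrix(0, nfr, nbin)
  chunk <- 20000L
  for (c0 in seq(1L, nfr, by = chunk)) {
    c1 <- min(c0 + chunk - 1L, nfr)
    nf <- c1 - c0 + 1L
    idx <- rep(seq_len(block), nf) + rep((seq(c0, c1) - 1L) * hop, each = block)
    Z <- stats::mvfft(matrix(wave[idx], block) * w)
    re <- Re(Z); im <- Im(Z)
    p <- re * re + im * im
    power[c0:c1, ] <- t(p[seq_len(nbin), , drop = FALSE])
  }
  structure(list(power = power,
                 time = ((seq_len(nfr) - 1L) * hop + block / 2) / fs,
                 freq = (seq_len(nbin) - 1L) * fs / block,
                 fs = fs, block = as.integer(block)),
            class = "usv_sonogram")
}

#' Reported time and frequency resolution of a sonogram
#'
#' `time_resolution` is the frame step `block/2 / fs`; `freq_resolution`
#' follows the `fs / (block/2)` reporting convention.
#'
#' @param x A `usv_sonogram`, or a list with `fs` and `block`.
#' @return Resolution in seconds (time) or Hz (frequency).
#' @export
time_resolution <- function(x) (x$block / 2) / x$fs

#' @rdname time_resolution
#' @export
freq_resolution <- function(x) x$fs / (x$block / 2)

#' Per-frame spectral features
#'
#' Computes, for every sonogram frame restricted to the analysis band:
#' spectral purity (fraction of the frame's total power concentrated in its
#' single strongest frequency bin), power-weighted mean frequency, total
#' power, and spectral discontinuity between adjacent frames (1 minus the
#' cosine similarity of their power allocations). All-zero frames have purity
#' 0 and an undefined (NA) mean frequency.
#'
#' @param sono A `usv_sonogram`.
#' @param band Length-2 numeric, analysis band in Hz.
#' @return Object of class `usv_frames`: list with `time`, `purity`,
#'   `mean_freq`, `total_power`, `discontinuity` (length `nframes`, first
#'   element NA), `peak_bin` (band-relative argmax index), `band_freq` (bin
#'   centres within the band), `hop_s` (frame step, s).
#' @export
frame_features <- function(sono, band = c(25e3, 110e3)) {
  stopifnot(inherits(sono, "usv_sonogram"))
  sel <- which(sono$freq >= band[1] & sono$freq <= band[2])
  pw <- sono$power[, sel, drop = FALSE]
  tot <- rowSums(pw)
  pk <- max.col(pw, ties.method = "first")
  pkpow <- pw[cbind(seq_len(nrow(pw)), pk)]
  purity <- ifelse(tot > 0, pkpow / tot, 0)
  mf <- ifelse(tot > 0, as.vector(pw %*% sono$freq[sel]) / tot, NA_real_)
  # discontinuity: 1 - cosine similarity of adjacent normalised power vectors
  nrm <- sqrt(rowSums(pw^2))
  num <- rowSums(pw[-1, , drop = FALSE] * pw[-nrow(pw), , drop = FALSE])
  den <- nrm[-1] * nrm[-length(nrm)]
  disc <- c(NA_real_, ifelse(den > 0, pmax(0, 1 - num / den), NA_real_))
  structure(list(time = sono$time, purity = purity, mean_freq = mf,
                 total_power = tot, discontinuity = disc, peak_bin = pk,
                 band_freq = sono$freq[sel],
                 hop_s = time_resolution(sono)),
            class = "usv_frames")
}
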