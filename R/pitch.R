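# Per-call pitch tracks, pitch-jump detection over a threshold grid, and
# call power spectra.

#' The standard pitch-jump threshold grid (Hz)
#'
#' Minimum jump magnitudes at which jump counts are reported:
#' 500, 1000, 3000, 5000, 10000, 15000 and 20000 Hz.
#' @export
jump_threshold_grid <- function() c(500, 1000, 3000, 5000, 10000, 15000, 20000)

#' Track the pitch of one call
#'
#' Pitch is the dominant (argmax) frequency of each sonogram frame within the
#' call; frames whose spectral purity falls below `dropout_purity` are
#' dropouts and carry `NA`.
#'
#' @param frames A `usv_frames` object from [frame_features()].
#' @param call One row of a `usv_calls` data frame (needs `first_frame`,
#'   `last_frame`).
#' @param dropout_purity Purity below which a frame is a dropout.
#' @return Data frame of class `usv_pitch` with `time` (s) and `freq` (Hz,
#'   `NA` at dropouts).
#' @export
pitch_track <- function(frames, call, dropout_purity = 0.15) {
  stopifnot(inherits(frames, "usv_frames"))
  idx <- call$first_frame:call$last_frame
  if (any(idx < 1L | idx > length(frames$time)))
    stop("call extends beyond the sonogram")
  freq <- frames$band_freq[frames$peak_bin[idx]]
  freq[frames$purity[idx] < dropout_purity] <- NA_real_
  out <- data.frame(time = frames$time[idx], freq = freq)
  class(out) <- c("usv_pitch", "data.frame")
  out
}

# adjacent sample pairs of a track, bridging dropouts up to bridge seconds
track_pairs <- function(track, bridge = 0.010) {
  ok <- which(!is.na(track$freq))
  if (length(ok) < 2) return(NULL)
  a <- ok[-length(ok)]; b <- ok[-1]
  keep <- (track$time[b] - track$time[a]) <= bridge
  if (!any(keep)) return(NULL)
  cbind(a[keep], b[keep])
}

#' Detect pitch jumps in a track
#'
#' A jump occurs between two consecutive non-dropout pitch samples (dropout
#' gaps up to `bridge` seconds are bridged) whose frequency difference
#' exceeds `threshold` in magnitude; the sign is the direction of the change.
#'
#' @param track A `usv_pitch` data frame.
#' @param threshold Minimum jump magnitude (Hz), > 0.
#' @param bridge Maximum dropout gap (s) bridged when pairing samples.
#' @return Data frame with `index` (position of the later sample), `time`
#'   (s) and `size` (signed Hz). Zero rows when no jump exceeds the
#'   threshold.
#' @export
detect_jumps <- function(track, threshold, bridge = 0.010) {
  stopifnot(threshold > 0)
  pr <- track_pairs(track, bridge)
  if (is.null(pr))
    return(data.frame(index = integer(0), time = numeric(0), size = numeric(0)))
  df <- track$freq[pr[, 2]] - track$freq[pr[, 1]]
  hit <- which(abs(df) > threshold)
  data.frame(index = pr[hit, 2], time = track$time[pr[hit, 2]],
             size = df[hit])
}

#' Largest pitch jump of a track
#'
#' Maximum absolute frequency step over the same adjacent-pair rule as
#' [detect_jumps()], with no threshold.
#'
#' @inheritParams detect_jumps
#' @return Magnitude in Hz; `NA` when fewer than two trackable samples.
#' @export
max_jump <- function(track, bridge = 0.010) {
  pr <- track_pairs(track, bridge)
  if (is.null(pr)) return(NA_real_)
  max(abs(track$freq[pr[, 2]] - track$freq[pr[, 1]]))
}

#' Signed jump counts over a threshold grid
#'
#' @param track A `usv_pitch` data frame.
#' @param grid Thresholds in Hz (default [jump_threshold_grid()]).
#' @param bridge Dropout-bridging window (s).
#' @return Named numeric vector `jump_pos_<thr>`, `jump_neg_<thr>` for each
#'   threshold.
#' @export
jump_count_grid <- function(track, grid = jump_threshold_grid(),
                            bridge = 0.010) {
  pr <- track_pairs(track, bridge)
  df <- if (is.null(pr)) numeric(0) else
    track$freq[pr[, 2]] - track$freq[pr[, 1]]
  pos <- vapply(grid, function(th) sum(df > th), numeric(1))
  neg <- vapply(grid, function(th) sum(df < -th), numeric(1))
  stats::setNames(c(pos, neg),
                  c(paste0("jump_pos_", grid), paste0("jump_neg_", grid)))
}

#' Per-subject call power spectrum
#'
#' Groups all sonogram frames belonging to calls and averages their power
#' vectors, yielding one spectrum per subject; total power is the sum over
#' frequency bins.
#'
#' @param sono A `usv_sonogram`.
#' @param calls A `usv_calls` data frame with at least one row.
#' @param band Analysis band (Hz); bins outside it are dropped.
#' @return List with `freq` (Hz), `power` (mean power per bin), `total`
#'   (sum of `power`) and `n_frames`.
#' @export
call_power_spectrum <- function(sono, calls, band = c(25e3, 110e3)) {
  stopifnot(inherits(sono, "usv_sonogram"))
  if (nrow(calls) < 1) stop("no calls: subject excluded from spectra")
  sel <- which(sono$freq >= band[1] & sono$freq <= band[2])
  fr <- unlist(mapply(seq, calls$first_frame, calls$last_frame,
                      SIMPLIFY = FALSE))
  pw <- colMeans(sono$power[fr, sel, drop = FALSE])
  list(freq = sono$freq[sel], power = pw, total = sum(pw),
       n_frames = length(fr))
}
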