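# Call and click detection from per-frame sonogram features.

#' Detect ultrasonic calls from frame features
#'
#' A frame is voiced when its spectral purity reaches `purity_threshold` and
#' its mean frequency lies inside the analysis band. Runs of voiced frames
#' separated by gaps of at most `merge_gap` are merged; merged runs shorter
#' than `min_duration` are dropped. Frames listed in `exclude` (e.g. click
#' frames) are never voiced. Optionally, merged runs are split where the
#' spectral discontinuity exceeds `split_discontinuity` while pitch is
#' untrackable (purity below `dropout_purity`), which separates abutting
#' calls bridged by a noisy frame.
#'
#' Call onsets/offsets are placed half a frame step outside the first/last
#' voiced frame centre, which is unbiased for symmetric amplitude ramps.
#'
#' @param frames A `usv_frames` object from [frame_features()].
#' @param purity_threshold Minimum spectral purity of a voiced frame.
#' @param min_duration Minimum call duration in seconds.
#' @param merge_gap Maximum silent gap (s) merged into one call.
#' @param band Analysis band (Hz) for the mean-frequency criterion.
#' @param exclude Integer frame indices to force unvoiced.
#' @param split_discontinuity Optional threshold in `[0, 2]`; `NULL` (default)
#'   disables discontinuity splitting.
#' @param dropout_purity Purity below which pitch is considered untrackable.
#' @return Data frame of class `usv_calls`: `call`, `onset`, `offset`,
#'   `duration` (s), `first_frame`, `last_frame`. Segments are sorted and
#'   disjoint; zero rows when nothing is detected.
#' @export
detect_calls <- function(frames, purity_threshold = 0.25,
                         min_duration = 0.005, merge_gap = 0.010,
                         band = c(25e3, 110e3), exclude = integer(0),
                         split_discontinuity = NULL,
                         dropout_purity = 0.15) {
  stopifnot(inherits(frames, "usv_frames"),
            purity_threshold > 0, min_duration > 0, merge_gap >= 0)
  hop <- frames$hop_s
  voiced <- frames$purity >= purity_threshold &
    !is.na(frames$mean_freq) &
    frames$mean_freq >= band[1] & frames$mean_freq <= band[2]
  if (length(exclude)) voiced[exclude] <- FALSE

  r <- rle(voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (!is.null(dim(seg)) && nrow(seg) > 1) {
    gap_frames <- max(0L, floor(merge_gap / hop))
    merged <- list(seg[1, ])
    for (i in 2:nrow(seg)) {
      last <- merged[[length(merged)]]
      if (seg[i, 1] - last[2] - 1L <= gap_frames)
        merged[[length(merged)]][2] <- seg[i, 2]
      else merged[[length(merged) + 1L]] <- seg[i, ]
    }
    seg <- do.call(rbind, merged)
  }
  if (is.null(dim(seg)) || nrow(seg) == 0) {
    seg <- matrix(integer(0), 0, 2)
  }

  if (!is.null(split_discontinuity) && nrow(seg)) {
    out <- list()
    for (i in seq_len(nrow(seg))) {
      a <- seg[i, 1]; b <- seg[i, 2]
      if (b - a < 3) { out[[length(out) + 1L]] <- c(a, b); next }
      inner <- (a + 1L):b
      cut <- inner[!is.na(frames$discontinuity[inner]) &
                     frames$discontinuity[inner] > split_discontinuity &
                     frames$purity[inner] < dropout_purity]
      bounds <- unique(c(a, cut, b + 1L))
      for (j in seq_len(length(bounds) - 1L))
        out[[length(out) + 1L]] <- c(bounds[j], bounds[j + 1L] - 1L)
    }
    seg <- do.call(rbind, out)
  }

  if (nrow(seg)) {
    onset <- frames$time[seg[, 1]] - hop / 2
    offset <- frames$time[seg[, 2]] + hop / 2
    keep <- (offset - onset) >= min_duration
    seg <- seg[keep, , drop = FALSE]
    onset <- onset[keep]; offset <- offset[keep]
  } else onset <- offset <- numeric(0)

  out <- data.frame(call = seq_len(nrow(seg)),
                    onset = onset, offset = offset,
                    duration = offset - onset,
                    first_frame = seg[, 1], last_frame = seg[, 2])
  class(out) <- c("usv_calls", "data.frame")
  out
}

#' Detect broadband clicks
#'
#' A frame is a click candidate when fewer than `max_empty_frac` of its
#' spectral cells are empty, a cell being empty when its power lies below
#' `empty_factor` times the sonogram-wide median cell power (the noise
#' floor). Cells are counted with the two-sided block convention (2 cells per
#' in-band frequency bin), so the default `200/512` reproduces the
#' fewer-than-200-of-512 rule on a 512-sample block when the full band is
#' analysed, and scales proportionally when it is not. Consecutive click
#' frames are clustered into one event.
#'
#' @param sono A `usv_sonogram`.
#' @param empty_factor Noise-floor multiplier defining an empty cell.
#' @param max_empty_frac A frame counts as a click when its fraction of
#'   empty cells falls below this value (default `200/512`).
#' @param band Analysis band in Hz.
#' @return Data frame of class `usv_clicks`: `click`, `time` (cluster centre,
#'   s), `frames` (cluster width), `occupied_bins` (max over the cluster),
#'   plus attribute `"frame_index"` with all click frame indices.
#' @export
detect_clicks <- function(sono, empty_factor = 2, max_empty_frac = 200 / 512,
                          band = c(25e3, 110e3)) {
  stopifnot(inherits(sono, "usv_sonogram"))
  sel <- which(sono$freq >= band[1] & sono$freq <= band[2])
  pw <- sono$power[, sel, drop = FALSE]
  thr <- empty_factor * stats::median(pw)
  n_cells <- 2L * length(sel)
  empty <- 2L * rowSums(pw < thr)
  is_click <- empty < max_empty_frac * n_cells
  idx <- which(is_click)
  if (!length(idx)) {
    out <- data.frame(click = integer(0), time = numeric(0),
                      frames = integer(0), occupied_bins = integer(0))
  } else {
    grp <- cumsum(c(1L, diff(idx) > 1L))
    time <- tapply(sono$time[idx], grp, mean)
    width <- tapply(idx, grp, length)
    occ <- tapply(n_cells - empty[idx], grp, max)
    out <- data.frame(click = seq_along(time), time = as.numeric(time),
                      frames = as.integer(width),
                      occupied_bins = as.integer(occ))
  }
  attr(out, "frame_index") <- idx
  class(out) <- c("usv_clicks", "data.frame")
  out
}

#' Recording inclusion rule
#'
#' Recordings with fewer than `min_calls` detected calls are excluded from
#' all cohort analyses (default 10).
#'
#' @param calls A `usv_calls` data frame (or anything with a row count).
#' @param min_calls Minimum number of calls.
#' @return `TRUE` if the recording is analysable.
#' @export
include_recording <- function(calls, min_calls = 10) {
  nrow(as.data.frame(calls)) >= min_calls
}
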