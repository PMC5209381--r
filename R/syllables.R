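# Rule-based syllable classification and the two entropy measures
# (type usage; first-order Markov sequence).

#' Syllable type labels
#'
#' The nine categories used by the rule-based classifier: `flat`, `up-FM`,
#' `down-FM`, `chevron`, `one-jump-up`, `one-jump-down`, `multi-jump`,
#' `harmonic`, `other`.
#' @export
syllable_types <- function() {
  c("flat", "up-FM", "down-FM", "chevron", "one-jump-up", "one-jump-down",
    "multi-jump", "harmonic", "other")
}

#' Classify one call from its pitch track
#'
#' Deterministic rules driven by the pitch-jump pattern and the contour
#' shape, checked in order: a harmonic call (flagged by the caller from
#' overtone energy) is `harmonic`; two or more jumps give `multi-jump`; a
#' single jump gives `one-jump-up`/`one-jump-down` by its sign. Jump-free
#' calls are classified by shape: total pitch range below `flat_range` is
#' `flat`; an interior maximum with rise and fall both above `rise_min` is
#' `chevron`; otherwise a net change beyond `slope_min` gives `up-FM` or
#' `down-FM`, and anything left (e.g. U-shaped contours) is `other`.
#'
#' @param track A `usv_pitch` data frame.
#' @param jumps Data frame of detected jumps for this call (from
#'   [detect_jumps()]); if `NULL`, jumps are detected at `jump_threshold`.
#' @param jump_threshold Jump magnitude (Hz) defining a jump syllable.
#' @param flat_range Maximum pitch range (Hz) of a flat call.
#' @param rise_min Minimum rise and fall (Hz) of a chevron.
#' @param slope_min Minimum net pitch change (Hz) of an FM call.
#' @param edge_frac Fraction of samples at each end excluded when requiring
#'   an interior chevron peak.
#' @param harmonic Logical: the call carries overtone energy.
#' @return A single label from [syllable_types()]; `"other"` when the track
#'   has no trackable samples.
#' @export
classify_call <- function(track, jumps = NULL, jump_threshold = 5000,
                          flat_range = 3000, rise_min = 3000,
                          slope_min = 2000, edge_frac = 0.1,
                          harmonic = FALSE) {
  f <- track$freq[!is.na(track$freq)]
  if (length(f) < 2) return("other")
  if (isTRUE(harmonic)) return("harmonic")
  if (is.null(jumps)) jumps <- detect_jumps(track, jump_threshold)
  nj <- nrow(jumps)
  if (nj >= 2) return("multi-jump")
  if (nj == 1) return(if (jumps$size[1] > 0) "one-jump-up" else "one-jump-down")
  if (max(f) - min(f) < flat_range) return("flat")
  n <- length(f)
  imax <- which.max(f)
  interior <- imax > max(1, floor(edge_frac * n)) &&
    imax < n - floor(edge_frac * n) + 1
  if (interior && (f[imax] - f[1]) >= rise_min && (f[imax] - f[n]) >= rise_min)
    return("chevron")
  net <- f[n] - f[1]
  if (net > slope_min) return("up-FM")
  if (net < -slope_min) return("down-FM")
  "other"
}

#' Shannon entropy of syllable-type usage
#'
#' `-sum(p * log2(p))` over the type proportions, with `0 * log(0) = 0`.
#'
#' @param x Either a vector of labels (tabulated into proportions) or a
#'   numeric probability vector (must sum to 1 within tolerance).
#' @return Entropy in bits.
#' @export
usage_entropy <- function(x) {
  p <- if (is.numeric(x)) x else as.numeric(table(x)) / length(x)
  if (!length(p)) stop("empty distribution")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("probabilities must be non-negative and sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' First-order Markov sequence entropy
#'
#' Conditional entropy (bits) of the next syllable type given the previous
#' one: `H2 = -sum_Y p(Y) sum_X p(X|Y) log2 p(X|Y)`, with the transition
#' probabilities and the predecessor marginal `p(Y)` estimated by plug-in
#' (maximum-likelihood) frequencies. Transitions are counted within
#' recordings only: consecutive labels spanning a boundary in `recording`
#' contribute no pair.
#'
#' @param labels Character or factor vector of syllable labels in temporal
#'   order.
#' @param recording Optional vector parallel to `labels` identifying the
#'   recording each call belongs to.
#' @return Entropy in bits; `NA` when fewer than two labels pair up.
#' @export
markov_entropy <- function(labels, recording = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 2) return(NA_real_)
  prev <- labels[-n]; nxt <- labels[-1]
  if (!is.null(recording)) {
    same <- recording[-n] == recording[-1]
    prev <- prev[same]; nxt <- nxt[same]
  }
  if (!length(prev)) return(NA_real_)
  tab <- table(prev, nxt)
  py <- rowSums(tab) / sum(tab)
  h_rows <- apply(tab, 1, function(r) {
    if (sum(r) == 0) return(0)
    p <- r[r > 0] / sum(r)
    -sum(p * log2(p))
  })
  sum(py * h_rows)
}
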