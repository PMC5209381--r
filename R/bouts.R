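# Pause extraction, data-driven bout-cutoff estimation and bout metrics.
#
# The cutoff between intra- and inter-bout pauses is estimated from the
# trough of the pooled pause-length histogram: histograms are built over a
# grid of bin sizes, the centre of the minimum-count bin inside an absolute
# search range is taken per bin size, and the centres are averaged.

#' Pause lengths of a call sequence
#'
#' Gaps from each call's offset to the next call's onset, in order.
#'
#' @param calls Data frame with `onset` and `offset` columns, sorted by
#'   onset.
#' @return Numeric vector of `nrow(calls) - 1` gaps (empty for fewer than
#'   two calls).
#' @export
pause_lengths <- function(calls) {
  calls <- as.data.frame(calls)
  n <- nrow(calls)
  if (n < 2) return(numeric(0))
  gaps <- calls$onset[-1] - calls$offset[-n]
  if (any(gaps <= 0)) warning("non-positive gaps: overlapping calls?")
  gaps
}

#' Estimate the intra-/inter-bout pause cutoff
#'
#' For each histogram bin size, all pooled gaps are binned (bins anchored at
#' 0 s), the minimum-count bin whose centre lies inside `search_range` is
#' found (ties broken toward the smallest centre; empty bins are eligible),
#' and its centre recorded. The cutoff is the mean of those centres across
#' bin sizes. Bin sizes with no centre inside the range are skipped with a
#' warning.
#'
#' @param gaps Numeric vector of pause lengths (s), typically pooled over a
#'   whole cohort for one postnatal day.
#' @param bin_sizes Histogram bin widths in seconds (default 50-300 ms in
#'   10 ms steps).
#' @param search_range Absolute range (s) in which the trough is sought.
#' @return Cutoff in seconds.
#' @export
estimate_bout_cutoff <- function(gaps, bin_sizes = seq(0.05, 0.30, by = 0.01),
                                 search_range = c(0.15, 0.32)) {
  gaps <- gaps[is.finite(gaps) & gaps > 0]
  if (!length(gaps)) stop("no gaps supplied")
  if (length(gaps) < 100)
    warning("fewer than 100 gaps: cutoff estimate may be unstable")
  centers <- numeric(0)
  skipped <- numeric(0)
  for (b in bin_sizes) {
    breaks <- seq(0, max(gaps) + b, by = b)
    cts <- tabulate(findInterval(gaps, breaks, rightmost.closed = FALSE),
                    nbins = length(breaks) - 1L)
    mid <- breaks[-length(breaks)] + b / 2
    ok <- which(mid >= search_range[1] & mid <= search_range[2])
    if (!length(ok)) { skipped <- c(skipped, b); next }
    best <- ok[which.min(cts[ok])]   # which.min ties -> smallest centre
    centers <- c(centers, mid[best])
  }
  if (length(skipped))
    warning(sprintf("no bin centre in the search range for bin size(s) %s ms; skipped",
                    paste(round(skipped * 1000), collapse = ", ")))
  if (!length(centers)) stop("no bin size produced a centre in the search range")
  mean(centers)
}

#' Partition calls into bouts at a pause cutoff
#'
#' The call sequence is split at every gap greater than or equal to `cutoff`
#' (the boundary case counts as inter-bout).
#'
#' @param calls Data frame with `onset`/`offset`, sorted.
#' @param cutoff Pause cutoff in seconds, > 0.
#' @return Object of class `usv_bouts`: list with `bout` (bout index per
#'   call), `sizes` (calls per bout), `cutoff`, `gaps`, and `intra` (logical
#'   per gap: within-bout).
#' @export
partition_bouts <- function(calls, cutoff) {
  stopifnot(cutoff > 0)
  gaps <- pause_lengths(calls)
  intra <- gaps < cutoff
  bout <- c(1L, 1L + cumsum(!intra))
  structure(list(bout = bout, sizes = as.integer(table(bout)),
                 cutoff = cutoff, gaps = gaps, intra = intra),
            class = "usv_bouts")
}

#' Bout-level metrics of one recording
#'
#' An isolated call is a bout of size one (recording edges count as bout
#' boundaries).
#'
#' @param part A `usv_bouts` object from [partition_bouts()].
#' @return List: `n_bouts`, `calls_per_bout` (total calls / bouts),
#'   `percent_isolated` (0-100), `intra_mean`, `inter_mean`,
#'   `all_pause_mean` (s; `NA` when the class is empty).
#' @export
bout_metrics <- function(part) {
  stopifnot(inherits(part, "usv_bouts"))
  n_calls <- length(part$bout)
  n_bouts <- length(part$sizes)
  iso <- sum(part$sizes == 1L)
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  list(n_bouts = n_bouts,
       calls_per_bout = n_calls / n_bouts,
       percent_isolated = 100 * iso / n_calls,
       intra_mean = mean_or_na(part$gaps[part$intra]),
       inter_mean = mean_or_na(part$gaps[!part$intra]),
       all_pause_mean = mean_or_na(part$gaps))
}

#' Proportion of long pauses over a criterion grid
#'
#' For each criterion, the proportion of gaps strictly exceeding it; the
#' curve is non-increasing in the criterion.
#'
#' @param gaps Numeric vector of pause lengths (s).
#' @param criteria Numeric vector of long-pause criteria (s).
#' @return Numeric vector of proportions, one per criterion.
#' @export
long_pause_curve <- function(gaps, criteria) {
  if (!length(gaps)) stop("no gaps supplied")
  vapply(criteria, function(cr) mean(gaps > cr), numeric(1))
}
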