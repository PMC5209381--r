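# Per-animal aggregation and group statistics: every call or pause first
# contributes to its own animal's mean; group comparisons are then run on the
# animal means (two-tailed t). A call-level alternative and subject-level
# bootstrap power-spectrum bands are also provided.

#' Aggregate per-call tables into one row per animal
#'
#' Combines the stage outputs into the animal-summary table that feeds all
#' group statistics and the genotype classifier. Every per-call quantity is
#' averaged within its animal first. Recordings failing the inclusion rule
#' (fewer than `min_calls` calls) are dropped.
#'
#' @param calls Data frame: `recording_id`, `onset`, `offset`, `duration`.
#' @param features Data frame: `recording_id`, `call`, `max_jump`, one
#'   `jump_pos_<thr>`/`jump_neg_<thr>` column per grid threshold, and
#'   optionally `mean_power`.
#' @param bouts Data frame: `recording_id`, `call`, `bout` plus per-recording
#'   metrics columns are recomputed here from the partition (`cutoff` column
#'   required).
#' @param labels Data frame: `recording_id`, `call`, `label`.
#' @param meta Data frame: `recording_id`, `genotype`, `day`, `weight`,
#'   `sex`, plus optionally `n_clicks` and `total_power`.
#' @param min_calls Inclusion threshold (default 10 calls).
#' @return Data frame with one row per included recording: metadata, call
#'   count, mean duration, pause means (all/intra/inter), bout metrics,
#'   per-threshold mean jump counts, mean max jump, entropies.
#' @export
aggregate_cohort <- function(calls, features, bouts, labels, meta,
                             min_calls = 10) {
  for (nm in c("calls", "features", "bouts", "labels", "meta")) {
    x <- get(nm)
    if (is.null(x) || !is.data.frame(x) || !nrow(x))
      stop("missing or empty upstream table: ", nm)
  }
  rows <- list()
  for (rid in unique(meta$recording_id)) {
    cl <- calls[calls$recording_id == rid, , drop = FALSE]
    if (nrow(cl) < min_calls) next
    cl <- cl[order(cl$onset), , drop = FALSE]
    ft <- features[features$recording_id == rid, , drop = FALSE]
    bt <- bouts[bouts$recording_id == rid, , drop = FALSE]
    lb <- labels[labels$recording_id == rid, , drop = FALSE]
    mt <- meta[meta$recording_id == rid, , drop = FALSE][1, ]

    cutoff <- bt$cutoff[1]
    part <- partition_bouts(cl, cutoff)
    bm <- bout_metrics(part)
    jump_cols <- grep("^jump_(pos|neg)_", names(ft), value = TRUE)
    ent_use <- usage_entropy(lb$label)
    ent_mkv <- markov_entropy(lb$label)

    row <- data.frame(
      recording_id = rid, genotype = mt$genotype, day = mt$day,
      weight = if ("weight" %in% names(mt)) mt$weight else NA_real_,
      sex = if ("sex" %in% names(mt)) mt$sex else NA_character_,
      n_calls = nrow(cl),
      n_clicks = if ("n_clicks" %in% names(mt)) mt$n_clicks else NA_real_,
      mean_duration = mean(cl$duration),
      all_pause = bm$all_pause_mean,
      intra_pause = bm$intra_mean,
      inter_pause = bm$inter_mean,
      n_bouts = bm$n_bouts,
      calls_per_bout = bm$calls_per_bout,
      pct_isolated = bm$percent_isolated,
      max_jump = mean(ft$max_jump, na.rm = TRUE),
      total_power = if ("total_power" %in% names(mt)) mt$total_power else NA_real_,
      usage_entropy = ent_use,
      markov_entropy = ent_mkv,
      stringsAsFactors = FALSE)
    for (jc in jump_cols) row[[jc]] <- mean(ft[[jc]], na.rm = TRUE)
    rows[[rid]] <- row
  }
  if (!length(rows)) stop("no recording passed the inclusion rule")
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Two-tailed two-sample t-test on animal means
#'
#' Pooled-variance Student t by default (`df = nA + nB - 2`); Welch by
#' `var_equal = FALSE`. Returns the statistic with group means, SEMs and
#' sizes. Two constant equal groups give `t = 0, p = 1`.
#'
#' @param a,b Numeric vectors (animal means per group), each of length >= 2.
#' @param var_equal Pooled variance (default) or Welch.
#' @return List of class `usv_ttest`: `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `sem_a`, `sem_b`, `n_a`, `n_b`.
#' @export
ttest_two_tailed <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2,
                p = if (eq) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  out <- c(res, list(mean_a = mean(a), mean_b = mean(b),
                     sem_a = sem(a), sem_b = sem(b),
                     n_a = length(a), n_b = length(b)))
  class(out) <- "usv_ttest"
  out
}

#' @export
print.usv_ttest <- function(x, ...) {
  cat(sprintf("two-tailed t-test: t = %.3f, df = %g, p = %.4g\n",
              x$t, x$df, x$p))
  cat(sprintf("  group A: %.4g +/- %.3g (n = %d)\n", x$mean_a, x$sem_a, x$n_a))
  cat(sprintf("  group B: %.4g +/- %.3g (n = %d)\n", x$mean_b, x$sem_b, x$n_b))
  invisible(x)
}

#' Call-level group comparison
#'
#' Treats every call (rather than every animal) as a data point: group means
#' with t-based 95% confidence intervals and a two-sample t-test. More
#' sensitive than the animal-level comparison but anticonservative under
#' within-animal correlation; both views are reported by the pipeline.
#'
#' @param a,b Numeric vectors of call-level values.
#' @param conf Confidence level for the interval (default 0.95).
#' @param var_equal Pooled variance (default) or Welch for the test.
#' @return List: `mean_a`, `ci_a`, `mean_b`, `ci_b` (length-2 intervals),
#'   `t`, `df`, `p`.
#' @export
per_call_comparison <- function(a, b, conf = 0.95, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 calls per group")
  ci <- function(x) {
    se <- stats::sd(x) / sqrt(length(x))
    mean(x) + c(-1, 1) * stats::qt(1 - (1 - conf) / 2, length(x) - 1) * se
  }
  tt <- ttest_two_tailed(a, b, var_equal = var_equal)
  list(mean_a = mean(a), ci_a = ci(a), mean_b = mean(b), ci_b = ci(b),
       t = tt$t, df = tt$df, p = tt$p)
}

#' Bootstrap confidence bands for group power spectra
#'
#' Resamples subjects with replacement within each group (default 1000
#' replicates) and forms per-frequency-bin percentile confidence intervals
#' of the group mean spectrum. A bin is significant when the two groups'
#' intervals are disjoint; it is *reported* significant only when adjacent
#' to at least one other significant bin.
#'
#' @param spec_a,spec_b Subject-by-frequency matrices of per-subject call
#'   spectra (>= 3 subjects each).
#' @param reps Bootstrap replicates.
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return List of class `usv_specband`: per group `mean`, `lower`, `upper`
#'   (per bin), plus `significant` and `reported` logical vectors.
#' @export
bootstrap_spectra <- function(spec_a, spec_b, reps = 1000, conf = 0.95,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(spec_a) < 3 || nrow(spec_b) < 3)
    stop("need at least 3 subjects per group")
  if (ncol(spec_a) != ncol(spec_b)) stop("frequency axes differ")
  alpha <- (1 - conf) / 2
  boot_band <- function(m) {
    bm <- matrix(0, reps, ncol(m))
    for (r in seq_len(reps))
      bm[r, ] <- colMeans(m[sample(nrow(m), replace = TRUE), , drop = FALSE])
    list(mean = colMeans(m),
         lower = apply(bm, 2, stats::quantile, alpha),
         upper = apply(bm, 2, stats::quantile, 1 - alpha))
  }
  ba <- boot_band(spec_a); bb <- boot_band(spec_b)
  sig <- ba$upper < bb$lower | bb$upper < ba$lower
  nb <- length(sig)
  neighbour <- c(sig[-1], FALSE) | c(FALSE, sig[-nb])
  structure(list(group_a = ba, group_b = bb, significant = sig,
                 reported = sig & neighbour, reps = reps),
            class = "usv_specband")
}

#' Correlation of body weight with a call metric
#'
#' Pearson correlation (with two-tailed p from [stats::cor.test()]) between
#' weight and one summary metric, within a genotype subset and day.
#'
#' @param summary Animal-summary data frame from [aggregate_cohort()].
#' @param metric Column name of the metric.
#' @param genotype `"WT"`, `"KO"`, `"HET"` or `"all"`.
#' @param day Optional postnatal day filter.
#' @return List: `r`, `p`, `n`; `r` is `NA` (with a warning) for a constant
#'   metric.
#' @export
weight_correlation <- function(summary, metric, genotype = "WT", day = NULL) {
  d <- summary
  if (genotype != "all") d <- d[d$genotype == genotype, , drop = FALSE]
  if (!is.null(day)) d <- d[d$day == day, , drop = FALSE]
  d <- d[is.finite(d$weight) & is.finite(d[[metric]]), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 paired observations")
  if (stats::sd(d[[metric]]) == 0) {
    warning("constant metric: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = nrow(d)))
  }
  ct <- stats::cor.test(d$weight, d[[metric]])
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}
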