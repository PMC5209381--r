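# Genotype inference from the 5-feature vocal profile: z-scored features,
# leave-one-out k-nearest-neighbour majority vote, and matched resampling of
# the larger group to the size of the smaller one.

#' The classifier's feature set
#'
#' Column names of the five summary features used for genotype inference:
#' intra-bout pause, mean largest pitch jump per call, bouts per recording,
#' calls per bout, and percent isolated calls.
#' @export
knn_features <- function() {
  c("intra_pause", "max_jump", "n_bouts", "calls_per_bout", "pct_isolated")
}

#' z-score feature columns
#'
#' Centres and scales each feature column over all included recordings
#' (sample standard deviation, `n - 1`).
#'
#' @param x Data frame or matrix of raw feature values (>= 2 rows).
#' @param cols Columns to normalize (default: all of `x`).
#' @return Numeric matrix of z-scores with the same column names.
#' @export
normalize_features <- function(x, cols = colnames(x)) {
  xd <- as.data.frame(x)
  if (is.null(cols)) cols <- seq_len(ncol(xd))
  m <- as.matrix(xd[, cols, drop = FALSE])
  if (ncol(m) < 1) stop("no feature columns selected")
  if (nrow(m) < 2) stop("need at least 2 recordings")
  sds <- apply(m, 2, stats::sd)
  bad <- colnames(m)[sds == 0 | !is.finite(sds)]
  if (length(bad))
    stop("zero-variance feature(s): ", paste(bad, collapse = ", "))
  scale(m)[, , drop = FALSE]
}

# majority-vote predictions from a distance matrix; ties in distance are
# broken by the smaller row index (order() is stable)
knn_predict_dist <- function(D, y, k) {
  n <- nrow(D)
  diag(D) <- Inf
  vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    votes <- table(y[nb])
    names(votes)[which.max(votes)]
  }, character(1))
}

#' Leave-one-out k-nearest-neighbour accuracy
#'
#' Each recording is classified by the majority genotype of its `k` nearest
#' neighbours in Euclidean feature space, with the recording itself left out
#' of the comparison set. With odd `k` on a two-class problem, vote ties can
#' only arise through exact distance ties, which are broken deterministically
#' toward the smallest recording index.
#'
#' @param x Numeric feature matrix (typically from [normalize_features()]).
#' @param y Class labels (length `nrow(x)`, both classes present).
#' @param k Number of neighbours (odd; `k < nrow(x)`).
#' @return Fraction of correctly classified recordings.
#' @export
knn_loocv <- function(x, y, k = 3) {
  x <- as.matrix(x)
  if (k >= nrow(x)) stop("k must be smaller than the number of recordings")
  if (k %% 2 == 0) stop("k must be odd")
  if (length(unique(y)) < 2) stop("need both classes")
  D <- as.matrix(stats::dist(x))
  mean(knn_predict_dist(D, y, k) == y)
}

#' Matched-resample genotype classification
#'
#' Repeatedly (default 10000 times) draws a random subset of the larger
#' class matching the size of the smaller class, runs leave-one-out kNN on
#' the balanced table, and summarises the accuracy distribution by its mean
#' and percentile interval. Features are z-scored once over the full table
#' before resampling (set `renormalize = TRUE` to re-score within each
#' subsample).
#'
#' @param x Data frame or matrix of raw features (see [knn_features()]).
#' @param y Two-level class labels.
#' @param k Neighbours (odd), default 3.
#' @param repeats Number of matched resamples.
#' @param seed Optional seed; results are reproducible given it.
#' @param conf Level of the percentile interval (default 0.95).
#' @param renormalize Re-z-score within every subsample.
#' @return List of class `usv_knn`: `mean_accuracy`, `ci` (percentiles),
#'   `accuracies`, `k`, `repeats`, `n_per_class`, `seed`.
#' @export
matched_resample <- function(x, y, k = 3, repeats = 10000, seed = NULL,
                             conf = 0.95, renormalize = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.character(y)
  tab <- sort(table(y))
  if (length(tab) != 2) stop("y must have exactly two classes")
  n_small <- tab[[1]]
  small <- names(tab)[1]; large <- names(tab)[2]
  if (n_small < k + 1) stop("minority class too small for k = ", k)
  idx_small <- which(y == small)
  idx_large <- which(y == large)

  xm <- as.matrix(as.data.frame(x))
  if (!renormalize) {
    z <- normalize_features(xm)
    D <- as.matrix(stats::dist(z))
  }
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    idx <- c(idx_small, sample(idx_large, n_small))
    if (renormalize) {
      zs <- normalize_features(xm[idx, , drop = FALSE])
      Ds <- as.matrix(stats::dist(zs))
    } else Ds <- D[idx, idx]
    acc[r] <- mean(knn_predict_dist(Ds, y[idx], k) == y[idx])
  }
  alpha <- (1 - conf) / 2
  structure(list(mean_accuracy = mean(acc),
                 ci = unname(stats::quantile(acc, c(alpha, 1 - alpha))),
                 accuracies = acc, k = k, repeats = repeats,
                 n_per_class = n_small, seed = seed),
            class = "usv_knn")
}

#' @export
print.usv_knn <- function(x, ...) {
  cat(sprintf("matched-resample %d-NN: accuracy %.1f%% (c.i. %.0f-%.0f%%), %d repeats, n = %d per class\n",
              x$k, 100 * x$mean_accuracy, 100 * x$ci[1], 100 * x$ci[2],
              x$repeats, x$n_per_class))
  invisible(x)
}
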