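# End-to-end orchestration: audio (or annotation) -> detection -> per-call
# features -> bouts -> syllables -> animal summaries -> group statistics and
# the genotype classifier. Plus minimal RIFF/PCM WAV input/output.

#' Pipeline configuration
#'
#' Central bundle of every tunable threshold. Defaults are the package's
#' documented operating point for 250 kHz pup recordings.
#'
#' @param band Analysis band in Hz (25-110 kHz).
#' @param block Sonogram block size in samples.
#' @param purity_threshold Voicing threshold on spectral purity.
#' @param dropout_purity Purity below which pitch is untrackable.
#' @param min_duration,merge_gap Call detection limits (s).
#' @param click_empty_factor,click_max_empty_frac Click rule parameters (see
#'   [detect_clicks()]).
#' @param jump_grid Jump-count threshold grid (Hz).
#' @param class_jump_threshold Jump size defining jump syllables (Hz).
#' @param jump_bridge Dropout-bridging window for jump detection (s).
#' @param bout_bin_sizes,bout_search_range Bout-cutoff estimation grid (s).
#' @param min_calls Recording inclusion threshold.
#' @param knn_k,knn_repeats Classifier settings.
#' @param harmonic_ratio Minimum overtone/fundamental power ratio flagging a
#'   harmonic call.
#' @param prefilter Apply [bandpass()] to the waveform before analysis
#'   (band-limiting is otherwise done in the sonogram domain, which is
#'   equivalent for all frame-level features and much faster).
#' @param seed Seed from which the stochastic stages (classifier resampling,
#'   bootstrap) derive their sub-seeds.
#' @return A named list of class `usv_config`.
#' @export
usv_config <- function(band = c(25e3, 110e3), block = 512L,
                       purity_threshold = 0.25, dropout_purity = 0.15,
                       min_duration = 0.005, merge_gap = 0.010,
                       click_empty_factor = 2,
                       click_max_empty_frac = 200 / 512,
                       jump_grid = jump_threshold_grid(),
                       class_jump_threshold = 5000,
                       jump_bridge = 0.010,
                       bout_bin_sizes = seq(0.05, 0.30, by = 0.01),
                       bout_search_range = c(0.15, 0.32),
                       min_calls = 10, knn_k = 3, knn_repeats = 10000,
                       harmonic_ratio = 0.05, prefilter = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "usv_config"
  validate_config(cfg)
  cfg
}

# schema check run before any stage: names, types and ranges
validate_config <- function(cfg) {
  need <- c("band", "block", "purity_threshold", "dropout_purity",
            "min_duration", "merge_gap", "click_empty_factor",
            "click_max_empty_frac", "jump_grid", "class_jump_threshold",
            "jump_bridge", "bout_bin_sizes", "bout_search_range",
            "min_calls", "knn_k", "knn_repeats", "harmonic_ratio",
            "prefilter", "seed")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("config is missing: ", paste(missing, collapse = ", "))
  stopifnot(length(cfg$band) == 2, cfg$band[1] < cfg$band[2],
            cfg$block >= 64,
            cfg$purity_threshold > 0, cfg$purity_threshold <= 1,
            cfg$min_duration > 0, cfg$merge_gap >= 0,
            cfg$click_max_empty_frac > 0, cfg$click_max_empty_frac <= 1,
            all(cfg$jump_grid > 0), cfg$min_calls >= 1,
            cfg$knn_k %% 2 == 1, cfg$knn_repeats >= 1)
  invisible(cfg)
}

# overtone check: median power ratio at 2*pitch vs pitch over trackable
# frames whose first harmonic stays inside the band
detect_harmonic <- function(sono, call, track, band, min_ratio) {
  ok <- which(!is.na(track$freq) & 2 * track$freq < band[2])
  if (length(ok) < 2) return(FALSE)
  fr <- call$first_frame + ok - 1L
  binw <- sono$fs / sono$block
  b1 <- pmin(round(track$freq[ok] / binw) + 1L, length(sono$freq))
  b2 <- pmin(round(2 * track$freq[ok] / binw) + 1L, length(sono$freq))
  p1 <- sono$power[cbind(fr, b1)]
  p2 <- pmax(sono$power[cbind(fr, b2)], sono$power[cbind(fr, pmax(b2 - 1L, 1L))],
             sono$power[cbind(fr, pmin(b2 + 1L, length(sono$freq)))])
  stats::median(p2 / pmax(p1, .Machine$double.eps)) > min_ratio &&
    length(ok) > 0.5 * nrow(track)
}

#' Analyse one recording
#'
#' Runs detection and per-call feature extraction for a single recording.
#' Audio input (`usv_recording`, or a list with `wave`, `fs`, `meta`) is
#' taken through sonogram, click and call detection, pitch tracking and
#' spectra; annotation input (`usv_annotation`) uses its event tables
#' directly and skips the signal stages.
#'
#' @param rec A `usv_recording` or `usv_annotation`.
#' @param config A [usv_config()] list.
#' @return List with `meta`, `calls` (detected or annotated segments),
#'   `tracks` (per-call pitch tracks), `features` (per-call jump counts,
#'   max jump), `labels`, `n_clicks`, `spectrum` (audio only), `included`.
#' @export
analyze_recording <- function(rec, config = usv_config()) {
  band <- config$band
  if (inherits(rec, "usv_annotation")) {
    calls <- rec$calls
    tracks <- rec$pitch
    if (is.null(tracks))
      stop("annotation generated with detail = 'timing' has no pitch tracks")
    harmonic <- rec$calls$label == "harmonic"
    n_clicks <- length(rec$clicks)
    spectrum <- NULL
  } else {
    wave <- rec$wave; fs <- rec$fs
    if (fs != 250e3)
      warning(sprintf("sampling rate %g Hz (expected 250 kHz); band adapted", fs))
    if (band[2] >= fs / 2) {
      warning("band upper edge clipped to Nyquist")
      band[2] <- 0.98 * fs / 2
    }
    if (isTRUE(config$prefilter)) wave <- bandpass(wave, fs, band[1], band[2])
    sono <- compute_sonogram(wave, fs, config$block)
    frames <- frame_features(sono, band)
    calls <- detect_calls(frames, config$purity_threshold,
                          config$min_duration, config$merge_gap, band)
    clicks <- detect_clicks(sono, config$click_empty_factor,
                            config$click_max_empty_frac, band)
    # click events inside call segments are call structure, not clicks
    if (nrow(clicks) && nrow(calls)) {
      inside <- vapply(clicks$time, function(tt)
        any(tt >= calls$onset & tt <= calls$offset), logical(1))
      clicks <- clicks[!inside, , drop = FALSE]
    }
    n_clicks <- nrow(clicks)
    tracks <- lapply(seq_len(nrow(calls)), function(i)
      pitch_track(frames, calls[i, ], config$dropout_purity))
    harmonic <- vapply(seq_len(nrow(calls)), function(i)
      detect_harmonic(sono, calls[i, ], tracks[[i]], band,
                      config$harmonic_ratio), logical(1))
    spectrum <- if (nrow(calls) > 0) call_power_spectrum(sono, calls, band)
  }

  n <- nrow(calls)
  feats <- vector("list", n)
  labels <- character(n)
  for (i in seq_len(n)) {
    tr <- tracks[[i]]
    jc <- jump_count_grid(tr, config$jump_grid, config$jump_bridge)
    feats[[i]] <- c(call = i, max_jump = max_jump(tr, config$jump_bridge), jc)
    labels[i] <- classify_call(tr, jump_threshold = config$class_jump_threshold,
                               harmonic = harmonic[i])
  }
  features <- if (n) as.data.frame(do.call(rbind, feats)) else
    data.frame(call = integer(0), max_jump = numeric(0))

  list(meta = rec$meta, calls = as.data.frame(calls), tracks = tracks,
       features = features,
       labels = data.frame(call = seq_len(n), label = labels),
       n_clicks = n_clicks, spectrum = spectrum,
       included = include_recording(calls, config$min_calls))
}

#' Run the full cohort analysis
#'
#' Orchestrates every stage over a cohort of recordings: per-recording
#' detection and features, pooled per-day bout-cutoff estimation, bout
#' partitioning, per-animal aggregation, two-tailed group comparisons for
#' every summary metric, subject-bootstrap power-spectrum bands (audio
#' cohorts), and the matched-resample kNN genotype classifier. All
#' randomness derives from `config$seed`.
#'
#' @param cohort A `usv_cohort` (or plain list of `usv_recording` /
#'   `usv_annotation` objects).
#' @param config A [usv_config()] list.
#' @param cutoff `"auto"` (estimate per day from pooled pauses) or a number
#'   in seconds.
#' @param out_dir Optional directory; when given, the interchange CSV tables
#'   (`calls.csv`, `features.csv`, `bouts.csv`, `labels.csv`, `summary.csv`,
#'   `stats.csv`) and a `manifest.txt` are written there.
#' @param verbose Log one line per recording to stderr.
#' @return List of class `usv_analysis`: `summary` (animal table), `tables`
#'   (calls/features/bouts/labels/meta), `cutoffs` (per day), `stats`
#'   (metric-by-day comparison table), `knn` (per day), `spectra` (per day,
#'   audio only), `manifest`.
#' @export
run_cohort_analysis <- function(cohort, config = usv_config(),
                                cutoff = "auto", out_dir = NULL,
                                verbose = FALSE) {
  validate_config(config)
  ids <- names(cohort)
  if (is.null(ids)) ids <- sprintf("rec_%03d", seq_along(cohort))
  per_rec <- list()
  for (i in seq_along(cohort)) {
    res <- analyze_recording(cohort[[i]], config)
    res$recording_id <- ids[i]
    per_rec[[ids[i]]] <- res
    if (verbose)
      message(sprintf("%s: %d calls, %d clicks%s", ids[i], nrow(res$calls),
                      res$n_clicks,
                      if (res$included) "" else " [excluded: <min_calls]"))
  }

  tag <- function(res, tab) {
    d <- res[[tab]]
    if (!nrow(d)) return(NULL)
    data.frame(recording_id = res$recording_id, d, row.names = NULL)
  }
  calls_tab <- do.call(rbind, lapply(per_rec, tag, "calls"))
  feat_tab <- do.call(rbind, lapply(per_rec, tag, "features"))
  lab_tab <- do.call(rbind, lapply(per_rec, tag, "labels"))
  rownames(calls_tab) <- rownames(feat_tab) <- rownames(lab_tab) <- NULL

  meta_tab <- do.call(rbind, lapply(per_rec, function(r)
    data.frame(recording_id = r$recording_id, genotype = r$meta$genotype,
               day = r$meta$day, weight = r$meta$weight, sex = r$meta$sex,
               n_clicks = r$n_clicks,
               total_power = if (!is.null(r$spectrum)) r$spectrum$total else NA_real_,
               included = r$included)))
  rownames(meta_tab) <- NULL

  # pooled per-day cutoff from included recordings
  days <- sort(unique(meta_tab$day))
  cutoffs <- stats::setNames(numeric(length(days)), days)
  for (d in as.character(days)) {
    if (identical(cutoff, "auto")) {
      ok <- meta_tab$recording_id[meta_tab$day == as.integer(d) & meta_tab$included]
      gaps <- unlist(lapply(per_rec[ok], function(r) pause_lengths(r$calls)))
      cutoffs[d] <- estimate_bout_cutoff(gaps, config$bout_bin_sizes,
                                         config$bout_search_range)
    } else cutoffs[d] <- as.numeric(cutoff)
  }

  bout_tab <- do.call(rbind, lapply(per_rec, function(r) {
    if (nrow(r$calls) < 1) return(NULL)
    co <- unname(cutoffs[as.character(r$meta$day)])
    part <- partition_bouts(r$calls, co)
    data.frame(recording_id = r$recording_id, call = r$calls$call,
               bout = part$bout, cutoff = co)
  }))
  rownames(bout_tab) <- NULL

  summary <- aggregate_cohort(calls_tab, feat_tab, bout_tab, lab_tab,
                              meta_tab[meta_tab$included, , drop = FALSE],
                              config$min_calls)

  # group comparisons per day, WT vs KO
  metrics <- c("n_calls", "n_clicks", "mean_duration", "all_pause",
               "intra_pause", "inter_pause", "n_bouts", "calls_per_bout",
               "pct_isolated", "max_jump", "usage_entropy", "markov_entropy",
               "total_power", "jump_pos_5000", "jump_neg_5000")
  stat_rows <- list()
  knn_res <- list()
  spectra <- list()
  for (d in days) {
    sd_ <- summary[summary$day == d, , drop = FALSE]
    wt <- sd_[sd_$genotype == "WT", , drop = FALSE]
    ko <- sd_[sd_$genotype == "KO", , drop = FALSE]
    if (nrow(wt) >= 2 && nrow(ko) >= 2) {
      for (m in intersect(metrics, names(sd_))) {
        a <- wt[[m]]; b <- ko[[m]]
        if (sum(is.finite(a)) < 2 || sum(is.finite(b)) < 2) next
        tt <- ttest_two_tailed(a, b)
        stat_rows[[paste(m, d)]] <- data.frame(
          metric = m, day = d, n_wt = tt$n_a, n_ko = tt$n_b,
          mean_wt = tt$mean_a, mean_ko = tt$mean_b,
          sem_wt = tt$sem_a, sem_ko = tt$sem_b,
          t = tt$t, df = tt$df, p = tt$p)
      }
      feats <- intersect(knn_features(), names(sd_))
      both <- rbind(wt, ko)
      both <- both[stats::complete.cases(both[, feats]), , drop = FALSE]
      tb <- table(both$genotype)
      if (length(tb) == 2 && min(tb) >= config$knn_k + 1) {
        knn_res[[as.character(d)]] <- matched_resample(
          both[, feats], both$genotype, k = config$knn_k,
          repeats = config$knn_repeats, seed = config$seed + 1L)
      }
      sp_ok <- meta_tab$included & meta_tab$day == d
      if (any(sp_ok)) {
        specs <- lapply(per_rec[meta_tab$recording_id[sp_ok]],
                        function(r) r$spectrum$power)
        gt <- meta_tab$genotype[sp_ok]
        have <- !vapply(specs, is.null, logical(1))
        if (sum(have & gt == "WT") >= 3 && sum(have & gt == "KO") >= 3) {
          spectra[[as.character(d)]] <- bootstrap_spectra(
            do.call(rbind, specs[have & gt == "WT"]),
            do.call(rbind, specs[have & gt == "KO"]),
            reps = 1000, seed = config$seed + 2L)
        }
      }
    }
  }
  stats_tab <- if (length(stat_rows))
    do.call(rbind, c(stat_rows, list(make.row.names = FALSE))) else NULL

  manifest <- list(
    n_recordings = length(cohort),
    n_included = sum(meta_tab$included),
    n_calls = nrow(calls_tab), cutoffs = cutoffs,
    stages = c("detect", "features", "bouts", "syllables", "aggregate",
               "stats", if (length(knn_res)) "classify"),
    seed = config$seed)

  out <- structure(list(summary = summary,
                        tables = list(calls = calls_tab, features = feat_tab,
                                      bouts = bout_tab, labels = lab_tab,
                                      meta = meta_tab),
                        cutoffs = cutoffs, stats = stats_tab,
                        knn = knn_res, spectra = spectra,
                        manifest = manifest),
                   class = "usv_analysis")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) if (!is.null(x))
      utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
    wr(calls_tab, "calls.csv"); wr(feat_tab, "features.csv")
    wr(bout_tab, "bouts.csv"); wr(lab_tab, "labels.csv")
    wr(summary, "summary.csv"); wr(stats_tab, "stats.csv")
    files <- list.files(out_dir, pattern = "\\.csv$")
    writeLines(c(sprintf("pupcalls %s", as.character(utils::packageVersion("pupcalls"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("cutoffs: %s", paste(sprintf("P%s=%.4f", names(cutoffs),
                                                      cutoffs), collapse = " ")),
                 paste("output:", files)),
               file.path(out_dir, "manifest.txt"))
    out$manifest$files <- files
  }
  out
}

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF reader for the recording format used here (PCM, one
#' channel). Multichannel, non-PCM, or truncated files raise errors.
#'
#' @param path Path to the WAV file.
#' @return List with `wave` (doubles in `[-1, 1]`), `fs` (Hz), `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; wave <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) break
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      if (fmt[1] != 1) stop("only PCM WAV is supported")
      channels <- fmt[2]
      if (channels != 1) stop("only mono recordings are supported")
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 2, endian = "little")
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (bits != 16) stop("only 16-bit PCM is supported")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      n <- sz %/% 2
      wave <- readBin(con, "integer", n, 2, endian = "little", signed = TRUE)
      if (length(wave) < n) stop("truncated WAV data chunk")
      break
    } else {
      skip <- readBin(con, "raw", sz + sz %% 2)
      if (length(skip) < sz) break
    }
  }
  if (is.null(fs) || is.null(wave)) stop("incomplete WAV file: ", path)
  list(wave = wave / 32767, fs = fs, bits = bits)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param wave Numeric samples in `[-1, 1]`.
#' @param fs Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, fs, path) {
  samples <- as.integer(round(pmin(pmax(wave, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_sz <- 2L * length(samples)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_sz, con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")          # PCM
  writeBin(1L, con, 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, 4, endian = "little")
  writeBin(samples, con, 2, endian = "little")
  invisible(path)
}
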