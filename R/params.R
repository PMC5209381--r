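#' Genotype-level parameters for the synthetic call generator
#'
#' Bundles the group-level event-process parameters that the synthetic cohort
#' generator uses to emulate pup isolation-call recordings: call durations,
#' intra-/inter-bout pause structure, bout sizes, pitch-jump statistics,
#' spectral placement and amplitude. Between-animal variability is carried in
#' the `between` list (standard deviations of animal-level means around the
#' group means, plus the weight model); within-recording variability is
#' controlled by `call_duration_sd` and the gamma shape of the intra-bout
#' pause distribution.
#'
#' @param mean_call_duration Group mean call duration in seconds.
#' @param call_duration_sd Within-animal SD of per-call durations (s).
#' @param intra_bout_pause_mean Group mean intra-bout pause (s).
#' @param inter_bout_pause_mean Group mean inter-bout pause (s); must exceed
#'   `intra_bout_pause_mean`.
#' @param calls_per_bout_mean Group mean calls per bout (total calls / bouts).
#' @param isolated_call_prob Fraction of calls that are isolated (bouts of
#'   size one), in `[0, 1]`.
#' @param jump_prob_per_call Probability that a call contains at least one
#'   pitch jump.
#' @param jump_size_mean,jump_size_sd Mean and SD of planted pitch-jump
#'   magnitudes (Hz); draws are truncated below at `jump_size_min`.
#' @param jump_size_min Minimum planted jump magnitude (Hz).
#' @param jump_extra_rate Poisson rate for additional jumps beyond the first
#'   in a jump-containing call.
#' @param base_freq_range Length-2 numeric, low/high bound (Hz) of the base
#'   frequency of non-harmonic calls; must lie within 25-110 kHz.
#' @param amplitude Linear waveform gain of rendered calls, in `(0, 1]`.
#' @param click_rate Broadband click rate (events per second).
#' @param high_band_power_scale Power attenuation factor applied above 65 kHz
#'   when rendering audio (1 = none).
#' @param harmonic_prob Probability that a call is a low-pitched harmonic
#'   call carrying one overtone.
#' @param shape_weights Named weights for the contour shape of jump-free
#'   calls (`flat`, `up`, `down`, `chevron`).
#' @param intra_pause_shape Gamma shape of within-recording intra-bout pause
#'   draws (mean fixed by the animal-level pause mean).
#' @param intra_pause_max Upper truncation (s) of intra-bout pause draws;
#'   keeps the intra mode clear of the bout-cutoff search range.
#' @param inter_pause_min Lower shift (s) of inter-bout pauses; draws are
#'   `inter_pause_min + Exp(mean - inter_pause_min)`.
#' @param between List of between-animal SDs (`duration`, `intra_pause`,
#'   `inter_pause`, `calls_per_bout`, `isolated`, `jump_prob`, `jump_size`)
#'   and the weight model (`weight_mean`, `weight_sd` in grams).
#' @param start_window Length-2 window (s) for the onset of the first call.
#'
#' @return An object of class `usv_params`.
#' @seealso [usv_presets()] for genotype/day presets derived from published
#'   group summaries.
#' @export
usv_params <- function(mean_call_duration = 0.052,
                       call_duration_sd = 0.012,
                       intra_bout_pause_mean = 0.133,
                       inter_bout_pause_mean = 2.31,
                       calls_per_bout_mean = 5.28,
                       isolated_call_prob = 0.078,
                       jump_prob_per_call = 0.55,
                       jump_size_mean = 27000,
                       jump_size_sd = 6000,
                       jump_size_min = 8000,
                       jump_extra_rate = 0.35,
                       base_freq_range = c(55e3, 95e3),
                       amplitude = 0.25,
                       click_rate = 0.15,
                       high_band_power_scale = 1,
                       harmonic_prob = 0.05,
                       shape_weights = c(flat = 0.12, up = 0.08,
                                         down = 0.68, chevron = 0.12),
                       intra_pause_shape = 45,
                       intra_pause_max = 0.22,
                       inter_pause_min = 0.33,
                       between = list(duration = 0.0128,
                                      intra_pause = 0.0128,
                                      inter_pause = 1.08,
                                      calls_per_bout = 1.56,
                                      isolated = 0.045,
                                      jump_prob = 0.13,
                                      jump_size = 5500,
                                      weight_mean = 4.34,
                                      weight_sd = 0.70),
                       start_window = c(0.5, 2)) {
  p <- list(mean_call_duration = mean_call_duration,
            call_duration_sd = call_duration_sd,
            intra_bout_pause_mean = intra_bout_pause_mean,
            inter_bout_pause_mean = inter_bout_pause_mean,
            calls_per_bout_mean = calls_per_bout_mean,
            isolated_call_prob = isolated_call_prob,
            jump_prob_per_call = jump_prob_per_call,
            jump_size_mean = jump_size_mean,
            jump_size_sd = jump_size_sd,
            jump_size_min = jump_size_min,
            jump_extra_rate = jump_extra_rate,
            base_freq_range = base_freq_range,
            amplitude = amplitude,
            click_rate = click_rate,
            high_band_power_scale = high_band_power_scale,
            harmonic_prob = harmonic_prob,
            shape_weights = shape_weights,
            intra_pause_shape = intra_pause_shape,
            intra_pause_max = intra_pause_max,
            inter_pause_min = inter_pause_min,
            between = between,
            start_window = start_window)
  class(p) <- "usv_params"
  validate_usv_params(p)
  p
}

validate_usv_params <- function(p) {
  stopifnot(inherits(p, "usv_params"))
  if (p$mean_call_duration <= 0 || p$call_duration_sd < 0)
    stop("call duration parameters must be positive")
  if (p$intra_bout_pause_mean <= 0 || p$inter_bout_pause_mean <= 0)
    stop("pause means must be positive")
  if (p$inter_bout_pause_mean <= p$intra_bout_pause_mean)
    stop("inter_bout_pause_mean must exceed intra_bout_pause_mean")
  if (p$calls_per_bout_mean != 0 && p$calls_per_bout_mean < 1)
    stop("calls_per_bout_mean must be >= 1 (or 0 for a silent recording)")
  if (p$isolated_call_prob < 0 || p$isolated_call_prob > 1)
    stop("isolated_call_prob must lie in [0, 1]")
  if (p$jump_prob_per_call < 0 || p$jump_prob_per_call > 1)
    stop("jump_prob_per_call must lie in [0, 1]")
  fr <- p$base_freq_range
  if (length(fr) != 2 || fr[1] >= fr[2] || fr[1] < 25e3 || fr[2] > 110e3)
    stop("base_freq_range must be increasing and within [25, 110] kHz")
  if (p$amplitude <= 0 || p$amplitude > 1)
    stop("amplitude must lie in (0, 1]")
  if (p$click_rate < 0) stop("click_rate must be non-negative")
  if (p$high_band_power_scale <= 0 || p$high_band_power_scale > 1)
    stop("high_band_power_scale must lie in (0, 1]")
  invisible(p)
}

#' Generator presets parameterized from published group summaries
#'
#' Returns a [usv_params()] object for one genotype (`WT`, `HET`, `KO`) and
#' postnatal day (5 or 8). Group means (call duration, intra-/inter-bout
#' pause, calls per bout, isolated-call fraction, per-animal mean maximum
#' pitch jump, body weight) follow the published per-animal group summaries
#' for Gnptab knockout pups and wild-type littermates; between-animal SDs are
#' reconstructed from the printed standard errors as `SEM * sqrt(n)` with the
#' printed group sizes (P5: n = 40 WT / 13 KO; P8: n = 41 WT / 15 KO).
#' Heterozygotes are phenotypically indistinguishable from wild type and
#' share the WT preset.
#'
#' The jump-size/jump-probability pairs are calibrated so that
#' `P(jump) * E[max planted jump]` reproduces the target per-animal mean
#' maximum pitch jump (WT 12689 Hz vs KO 8687 Hz at P8; 11485 vs 8947 at P5).
#' Knockout presets additionally attenuate rendered power above 65 kHz
#' (`high_band_power_scale = 0.55`), emulating the high-frequency power
#' deficit of knockout calls.
#'
#' @param genotype One of `"WT"`, `"HET"`, `"KO"`.
#' @param day Postnatal day, 5 or 8.
#' @return A `usv_params` object.
#' @export
usv_presets <- function(genotype = c("WT", "HET", "KO"), day = c(8, 5)) {
  genotype <- match.arg(genotype)
  day <- as.integer(day[1])
  if (!day %in% c(5L, 8L)) stop("day must be 5 or 8")
  if (genotype == "HET") genotype <- "WT"   # het indistinguishable from WT

  if (day == 8L) {
    if (genotype == "WT") {
      usv_params(
        mean_call_duration = 0.052, intra_bout_pause_mean = 0.133,
        inter_bout_pause_mean = 2.31, calls_per_bout_mean = 5.28,
        isolated_call_prob = 0.078, jump_prob_per_call = 0.55,
        jump_size_mean = 27000, high_band_power_scale = 1,
        between = list(duration = 0.0128, intra_pause = 0.0128,
                       inter_pause = 1.08, calls_per_bout = 1.56,
                       isolated = 0.045, jump_prob = 0.13, jump_size = 5500,
                       weight_mean = 4.34, weight_sd = 0.70))
    } else {
      usv_params(
        mean_call_duration = 0.046, intra_bout_pause_mean = 0.144,
        inter_bout_pause_mean = 1.96, calls_per_bout_mean = 3.66,
        isolated_call_prob = 0.129, jump_prob_per_call = 0.45,
        jump_size_mean = 18500, high_band_power_scale = 0.55,
        between = list(duration = 0.0077, intra_pause = 0.0116,
                       inter_pause = 1.39, calls_per_bout = 1.01,
                       isolated = 0.058, jump_prob = 0.13, jump_size = 5500,
                       weight_mean = 3.85, weight_sd = 0.54))
    }
  } else {
    if (genotype == "WT") {
      usv_params(
        mean_call_duration = 0.044, intra_bout_pause_mean = 0.157,
        inter_bout_pause_mean = 2.61, calls_per_bout_mean = 6.04,
        isolated_call_prob = 0.106, jump_prob_per_call = 0.50,
        jump_size_mean = 26100, high_band_power_scale = 1,
        between = list(duration = 0.0126, intra_pause = 0.0190,
                       inter_pause = 1.44, calls_per_bout = 2.84,
                       isolated = 0.105, jump_prob = 0.13, jump_size = 5500,
                       weight_mean = 3.25, weight_sd = 0.57))
    } else {
      usv_params(
        mean_call_duration = 0.042, intra_bout_pause_mean = 0.170,
        inter_bout_pause_mean = 3.78, calls_per_bout_mean = 3.69,
        isolated_call_prob = 0.179, jump_prob_per_call = 0.42,
        jump_size_mean = 21800, high_band_power_scale = 0.55,
        between = list(duration = 0.0072, intra_pause = 0.0180,
                       inter_pause = 2.50, calls_per_bout = 1.62,
                       isolated = 0.110, jump_prob = 0.13, jump_size = 5500,
                       weight_mean = 2.97, weight_sd = 0.36))
    }
  }
}

#' Per-recording metadata
#'
#' @param animal_id Identifier for the animal/recording.
#' @param genotype `"WT"`, `"HET"` or `"KO"`.
#' @param day Postnatal day, 5 or 8.
#' @param weight Body weight in grams (optional).
#' @param sex `"M"` or `"F"` (optional).
#' @param duration Recording duration in seconds (default 210 s = 3.5 min).
#' @return A list of class `usv_meta`.
#' @export
recording_meta <- function(animal_id, genotype = c("WT", "HET", "KO"),
                           day = c(8, 5), weight = NA_real_,
                           sex = NA_character_, duration = 210) {
  genotype <- match.arg(genotype)
  day <- as.integer(day[1])
  if (!day %in% c(5L, 8L)) stop("day must be 5 or 8")
  if (!is.na(sex) && !sex %in% c("M", "F")) stop("sex must be 'M' or 'F'")
  if (duration <= 0) stop("duration must be positive")
  structure(list(animal_id = as.character(animal_id), genotype = genotype,
                 day = day, weight = weight, sex = sex, duration = duration),
            class = "usv_meta")
}
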