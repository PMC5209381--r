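---
title: "Quantifying mouse pup isolation calls: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mouse pup isolation calls: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Mouse pups separated from their dam emit innate ultrasonic isolation calls
(USVs), typically between 25 and 110 kHz, during their first two postnatal
weeks. The fine structure of these calls — their duration, the pauses that
group them into bouts, abrupt pitch jumps, spectral power, and the diversity
of syllable types — is a sensitive, fully automatable behavioural phenotype.
`pupcalls` implements a complete analysis chain for such recordings, from raw
audio to genotype inference, together with a synthetic-cohort generator that
provides ground truth for validating every stage. The cohort structure and
effect sizes that the generator emulates are those of a knockout of *Gnptab*
(the catalytic subunit of the lysosomal enzyme-targeting phosphotransferase,
the gene disrupted in mucolipidosis II): knockout pups call at normal rates
but with shorter calls, longer intra-bout pauses, fewer and smaller pitch
jumps, more isolated calls, and reduced high-frequency power.

## Signal analysis

**Sonogram.** Recordings are analysed at 250 kHz with 512-sample
Hann-windowed blocks at half overlap. The frame step is therefore
`256/fs` = 1.024 ms (reported at three significant figures as 1.02 ms), and
the frequency resolution under the `fs/(block/2)` reporting convention is
0.98 kHz; the internal bin spacing is `fs/block` = 488 Hz.

**Band limiting.** All frame-level features are computed on the 25–110 kHz
band. By default the band restriction is applied in the sonogram domain
(bins outside the band are excluded from every feature), which for
frame-level statistics is exactly equivalent to an ideal zero-phase band-pass
of the waveform and considerably cheaper at 250 kHz sampling. A waveform
band-pass (`bandpass()`) is also provided: it applies the squared magnitude
response of a 4th-order Butterworth — the frequency-domain equivalent of
forward-backward filtering, hence zero-phase with unbiased call onsets — by
overlap-save FFT convolution.

**Call detection.** A frame is voiced when its *spectral purity* (fraction
of the frame's in-band power concentrated in its single strongest bin) is at
least 0.25 and its power-weighted mean frequency lies inside the band. Runs
of voiced frames separated by at most 10 ms are merged, and merged runs
shorter than 5 ms are discarded. The purity threshold, merge gap and minimum
duration are configurable (`usv_config()`); the defaults were chosen on
synthetic recordings at 20 dB tonal SNR, where they give recall and
precision above 0.99 with boundary errors below 1 ms. *Spectral
discontinuity* (1 − cosine similarity of adjacent frames' power allocations)
is available as an optional splitter for abutting calls bridged by noisy
frames; it is not part of the primary voicing criterion.

**Clicks.** A frame is a click candidate when fewer than `200/512` of its
spectral cells are "empty", a cell being empty when its power is below twice
the sonogram-wide median cell power; cells are counted with the two-sided
block convention (two cells per in-band bin), scaling the 200-of-512 rule
proportionally when fewer cells are analysed. Because the frame containing
a pitch jump briefly carries two tones and can look broadband, click events
that fall inside detected call segments are treated as call structure and
removed; clicks are reported separately and never enter call statistics.

**Pitch and jumps.** Pitch is the per-frame argmax frequency; frames with
purity below 0.15 are dropouts. A pitch jump is a step between consecutive
non-dropout samples exceeding a threshold; jump counts are reported over the
grid 500, 1000, 3000, 5000, 10000, 15000 and 20000 Hz, split by sign, and
the largest absolute step per call (no threshold) is the per-call maximum
jump. Dropout gaps up to 10 ms are bridged when pairing samples — pitch
jumps in pup calls frequently straddle brief energy dips, and without
bridging they would be systematically undercounted. Jumps are never counted
across call boundaries.

## Bout structure

Gaps between consecutive calls are pooled per postnatal day across the whole
cohort. Histograms are built for bin widths 50–300 ms in 10 ms steps, with
bins anchored at 0 s for reproducibility; for each width, the centre of the
minimum-count bin whose centre lies in the absolute range 0.15–0.32 s is
recorded (ties resolved toward the smaller centre, empty bins eligible), and
the cutoff is the mean of those centres. Bin widths of 220–290 ms have no
centre inside the range under the 0-anchored convention and are skipped with
a warning. A gap at or above the cutoff is inter-bout; an isolated call is a
bout of size one, with recording edges counting as bout boundaries.

## Syllables and entropies

Calls are labelled by deterministic rules over the pitch track: harmonic
calls (overtone energy at twice the pitch), multi-jump calls (two or more
jumps above 5 kHz), single-jump calls split by direction, and jump-free
calls by shape — flat (range < 3 kHz), chevron (interior peak with rise and
fall ≥ 3 kHz), up-/down-FM (net change ≥ 2 kHz), and `other` for anything
left, such as U-shaped contours. The taxonomy is a configurable reconstruction:
entropy computations depend only on the label sequence, so any deterministic
scheme preserves the structure of the analysis.

Per recording, *usage entropy* is the Shannon entropy (bits) of the label
proportions, and the *sequence entropy* is the conditional entropy of a
first-order Markov chain, `H2 = -sum_Y p(Y) sum_X p(X|Y) log2 p(X|Y)`, with
plug-in (maximum-likelihood) estimates and the predecessor marginal as the
outer weight. Transitions are counted within recordings only; bout
boundaries do not break transition pairs. No small-sample bias correction is
applied.

## Cohort statistics

Every call or pause first contributes to its own animal's mean; group
comparisons are two-tailed pooled-variance Student t-tests on the animal
means (Welch available by flag). A call-level comparison (every call a data
point, t-based 95% intervals) is also produced; it is more sensitive but
anticonservative under within-animal correlation. Recordings with fewer
than 10 calls are excluded throughout. Group power spectra average the
sonogram power vectors over all call frames per subject; subject-level
bootstrap (1000 replicates) gives percentile bands, a bin is significant
when the two groups' 95% intervals are disjoint, and only bins adjacent to
another significant bin are reported — suppressing isolated false positives.
No multiple-testing correction is applied across metrics by default
(Benjamini–Hochberg can be applied downstream); weight regressions are
Pearson correlations per genotype and day. Sex effects are checked with the
same two-tailed t machinery by splitting the summary table on the `sex`
column instead of genotype.

## Genotype inference

Five per-animal features — intra-bout pause, mean largest pitch jump, bouts
per recording, calls per bout, and percent isolated calls — are z-scored
(sample SD) over all included recordings. Each repeat of the matched
resampling draws a wild-type subset matching the knockout group size, and
every recording is classified by the majority genotype of its three nearest
Euclidean neighbours, leaving itself out. The mean and the 2.5/97.5
percentiles over 10,000 repeats summarise accuracy. Normalisation is
computed once on the full table before subsampling (re-normalisation per
subsample is available); distance ties resolve toward the smaller recording
index, and odd `k` on two classes makes vote ties otherwise impossible.
Under label exchangeability the balanced design has chance level 0.5; the
leave-one-out comparison set (one fewer same-class neighbour) biases null
accuracy slightly below 0.5, which is visible in the chance-level checks.

## The synthetic-cohort generator

The generator is first-class, tested code, and defines the study conditions
for every statistical check in the package:

* **Cohorts.** Defaults mirror the study: P5 with 40 WT and 13 KO animals,
  P8 with 41 and 15, 3.5-minute recordings. Heterozygotes share the WT
  preset, reflecting their indistinguishable phenotype.
* **Group means.** Call duration (P8: 0.052 s WT vs 0.046 s KO; P5: 0.044
  vs 0.042 — the P5 KO per-animal mean is not published and 0.042 s is this
  package's assumption), intra-bout pause (0.133 vs 0.144 s at P8, 0.157 vs
  0.170 s at P5), inter-bout pause, calls per bout (5.28 vs 3.66 at P8),
  isolated-call fraction (7.8% vs 12.9% at P8), body weight (4.34 ± 0.70 vs
  3.85 ± 0.54 g at P8), and per-animal mean maximum pitch jump (12689 vs
  8687 Hz at P8).
* **Between-animal variation.** Published group summaries give standard
  errors only; animal-level SDs are reconstructed as `SEM * sqrt(n)` with
  the published group sizes, and each animal draws its own parameter means
  (truncated normals) before generating its recording.
* **Event process.** A bout is a single isolated call with probability
  `q = isolated_fraction * calls_per_bout` and otherwise holds
  `2 + Poisson` calls, which makes the expected calls-per-bout equal the
  configured value exactly; `q` is capped at 0.8 (and the multi-bout mean at
  30) so jointly extreme animal-level draws cannot degenerate into
  all-singleton recordings. Intra-bout pauses are gamma (shape 45) truncated
  at 0.22 s; inter-bout pauses are 0.33 s plus an exponential. The disjoint
  supports guarantee that any estimated cutoff between 0.22 and 0.33 s
  recovers the generative bout structure exactly, while leaving a genuine
  histogram trough inside the 0.15–0.32 s search range.
* **Calls.** Piecewise-linear pitch contours (flat, up, down, chevron;
  down-FM dominant, as in real pup repertoires) inside 55–95 kHz; harmonic
  calls sit at 30–48 kHz and carry one overtone at 0.35 relative amplitude.
  Jumps are instantaneous steps at interior positions at least 8 ms apart,
  magnitudes truncated-normal above 8 kHz, signs constrained so contours
  stay inside the analysis band. The jump probability / jump-size pairs per
  preset were calibrated once, by simulation against the generator itself,
  so that the per-animal mean maximum jump reproduces the published group
  values; the calibrated means are fixed in `usv_presets()`.
* **Rendering.** Calls are phase-continuous FM tones with 2 ms
  raised-cosine ramps (so synthetic onsets are detectable to within the
  frame step) riding on Gaussian noise at a configurable tonal SNR (default
  20 dB over in-band noise power); clicks are 1.5 ms broadband bursts;
  knockout presets attenuate power above 65 kHz (factor 0.55), emulating
  their high-band deficit; samples are quantised to 16 bits.
* **Emergent quantities.** Bouts per recording and total call counts are
  not parameters: they emerge from durations, pauses and bout sizes within
  the 210 s budget (about 66 bouts per WT and 84 per KO recording at P8).
  The published per-animal bout counts are not perfectly consistent with
  the published pause means under a fixed recording length, so the
  generator treats the pause and bout-size parameters as primitive and lets
  bout counts follow.

**What the generator does not emulate.** Within-animal syllable sequences
are i.i.d., so synthetic sequence entropy nearly equals usage entropy,
whereas real pups show `H2` clearly below `H1`; absolute synthetic entropies
are also higher than published values because the synthetic repertoire is
more uniform — the genotype *contrast* in both entropies still arises,
through jump prevalence. There are no harmonics beyond one overtone, no
amplitude modulation, no room acoustics, and no overlapping callers. Passing
detector tests on this generator therefore demonstrates correctness of the
analysis chain under controlled conditions, not field performance on noisy
colony recordings.

## Numerical choices and degenerate inputs

All-zero sonogram frames have purity 0 and undefined mean frequency; calls
whose tracks hold fewer than two non-dropout samples are excluded from jump
statistics and labelled `other`; two constant equal groups give `t = 0,
p = 1`; constant features abort normalisation with the feature named;
zero-variance weight metrics are flagged rather than returning spurious
correlations. All randomness in an analysis run derives from the single
configured seed (classifier and bootstrap receive fixed offsets), and
annotation-only and audio generation share one event stream per seed, so
detector outputs can be compared against exact ground truth.

## Problem sizes used in the shipped checks

The package's own test suite and acceptance script run entirely on
synthetic data: full-length (210 s) audio recordings in small cohorts for
detector fidelity, annotation-only cohorts at the published group sizes
(41/15) for the statistical and classifier checks, and reduced replicate
counts for Monte-Carlo checks where the estimator's sampling error, not the
replicate count, limits precision. These sizes are stated in the tests
themselves and were chosen so each check pins down its property at
comfortable margins.
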