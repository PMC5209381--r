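# pupcalls

Quantitative analysis of mouse pup ultrasonic isolation calls (USVs).

Mouse pups separated from their dam emit innate ultrasonic calls (25–110
kHz). Their fine structure — call duration, the pauses that organise calls
into bouts, abrupt pitch jumps, spectral power, and syllable-type diversity —
is a sensitive automated behavioural phenotype, used for example to
characterise knockouts of lysosomal enzyme-targeting genes (*Gnptab*), whose
pups call at normal rates but with shorter calls, longer intra-bout pauses,
fewer and smaller pitch jumps, and more isolated calls. `pupcalls`
implements the full analysis chain from raw audio to genotype inference,
plus a synthetic-cohort generator with exact ground truth for validating
every stage.

## The analysis in brief

* **Detection.** Sonograms use 512-sample Hann blocks at half overlap
  (1.02 ms / 0.98 kHz at 250 kHz). A frame is voiced when its *spectral
  purity* — the fraction of in-band power in its strongest bin,
  `max_k P(k) / sum_k P(k)` — exceeds 0.25 and its power-weighted mean
  frequency lies in 25–110 kHz. Broadband *clicks* are frames where fewer
  than 200 of 512 spectral cells are empty relative to the noise floor.
* **Pitch.** Per-frame dominant frequency with dropout handling; pitch
  jumps are steps `|Δf| > θ` between consecutive trackable samples, counted
  over θ ∈ {0.5, 1, 3, 5, 10, 15, 20} kHz, split by sign; the largest step
  per call is its maximum jump.
* **Bouts.** The intra-/inter-bout cutoff is the trough of the pooled
  pause-length histogram, averaged over bin widths 50–300 ms within the
  absolute range 0.15–0.32 s; an isolated call is a bout of size one.
* **Syllables.** Rule-based labels (flat, up-/down-FM, chevron, one-jump
  up/down, multi-jump, harmonic, other); per-recording usage entropy
  `H1 = -Σ p(X) log2 p(X)` and first-order Markov sequence entropy
  `H2 = -Σ_Y p(Y) Σ_X p(X|Y) log2 p(X|Y)`.
* **Statistics.** Animal-first averaging, two-tailed pooled-variance
  t-tests, call-level comparisons with 95% CIs, subject-bootstrap
  power-spectrum bands (1000 replicates, adjacency-filtered significance),
  and weight regressions.
* **Genotype inference.** Five z-scored features (intra-bout pause, max
  jump, bouts, calls/bout, % isolated); leave-one-out 3-NN majority vote on
  group-size-matched subsamples, 10,000 repeats, percentile intervals.

## Worked example

Generate a synthetic P8 cohort (annotation-only, i.e. exact event streams
without audio rendering) and run the full analysis:

```r
library(pupcalls)
coh <- sample_cohort(c(WT = 12, KO = 8), day = 8, seed = 42, duration = 210)
res <- run_cohort_analysis(coh, usv_config(knn_repeats = 2000, seed = 42))

cat("estimated P8 bout cutoff (s):", round(res$cutoffs[["8"]], 3), "\n")
print(res$stats[res$stats$metric %in%
  c("mean_duration", "intra_pause", "calls_per_bout", "pct_isolated",
    "max_jump"),
  c("metric", "mean_wt", "mean_ko", "t", "p")], digits = 3,
  row.names = FALSE)
print(res$knn[["8"]])
```

```
estimated P8 bout cutoff (s): 0.259
         metric  mean_wt  mean_ko     t        p
  mean_duration 5.42e-02 4.75e-02  1.83 8.43e-02
    intra_pause 1.32e-01 1.41e-01 -1.52 1.46e-01
 calls_per_bout 5.29e+00 3.69e+00  2.43 2.58e-02
   pct_isolated 9.62e+00 1.33e+01 -1.60 1.27e-01
       max_jump 1.35e+04 8.64e+03  9.18 3.27e-08
matched-resample 3-NN: accuracy 93.9% (c.i. 88-100%), 2000 repeats, n = 8 per class
```

Reading the output: the pooled pause histogram places the bout cutoff at
0.259 s; knockouts show shorter calls (47.5 vs 54.2 ms), fewer calls per
bout (3.69 vs 5.29, p = 0.026), more isolated calls and a much smaller mean
maximum pitch jump (8.6 vs 13.5 kHz, p < 1e-7); and the 3-nearest-neighbour
classifier recovers genotype from the five-feature vocal profile well above
the 50% chance level. (At this reduced cohort size the classifier runs on
8-vs-8 matched tables; accuracy at the full 41/15 cohort size is lower,
around 80%.) Audio-level analysis works the same way with
`sample_cohort(..., audio = TRUE)` or with your own WAV files via
`read_wav()` and `analyze_recording()`.

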