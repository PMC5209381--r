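Package: pupcalls
Title: Analysis of Mouse Pup Ultrasonic Isolation Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of mouse pup ultrasonic
    isolation calls (USVs): spectrogram-based call and click detection using
    spectral purity and mean-frequency criteria, pitch tracking and pitch-jump
    quantification over a threshold grid, data-driven bout segmentation from
    pause-length histograms, rule-based syllable classification with usage and
    first-order Markov sequence entropies, per-animal cohort statistics with
    subject-level bootstrap power-spectrum bands, and genotype inference by
    matched-resample leave-one-out k-nearest-neighbour classification. Includes
    a synthetic-cohort generator with genotype-dependent call structure and
    full ground truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
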