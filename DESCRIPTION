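Package: peseizr
Title: Patient-Specific Epileptic Seizure Prediction from Intracranial EEG
    Using Permutation Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a patient-specific seizure-prediction pipeline for
    continuous multichannel intracranial EEG: permutation entropy (and its
    Tsallis, Renyi and min-entropy variants) extracted per channel in
    non-overlapping 5-second windows, binary preictal/interictal
    classification with an RBF-kernel support vector machine, a two-step
    firing-power alarm generator (2-minute short windows thresholded at p
    preictal labels, k-of-3 rule over 6-minute long windows), and evaluation
    by sensitivity, false prediction rate and seizure prediction horizon with
    normalized-FPR Euclidean-distance model selection. Includes a synthetic
    iEEG generator with interictal/preictal/ictal regimes so the full
    pipeline is testable without clinical recordings, plus readers for
    EDF and plain-matrix recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
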