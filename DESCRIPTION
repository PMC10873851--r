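Package: microstatr
Title: EEG Microstate Segmentation, Temporal Dynamics and Condition Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Resting-state EEG microstate analysis: global field power (GFP)
    computation and peak detection, polarity-invariant modified k-means
    clustering of GFP-peak topographies with cross-validation based selection
    of the number of classes, two-level (subject to group) clustering,
    winner-takes-all backfitting, mean duration and time coverage extraction,
    topographic permutation tests (TANOVA), within-subject ANOVA, paired
    contrasts and trait correlations with multiplicity control. Includes a
    semi-Markov synthetic-cohort generator with known ground truth so every
    stage is verifiable by parameter recovery, plus readers and writers for a
    plain-text cohort format and minimal EDF.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
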