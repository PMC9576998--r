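Package: bcishift
Title: Estimating Cross-Subject Distribution Shifts in EEG-Based Mental Workload Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies marginal and conditional distribution shifts between
    subjects in multi-subject labeled feature data, with a focus on
    EEG-based passive brain-computer interfaces. Conditional (labeling-rule)
    shift is estimated from the cross-subject disagreement of approximated
    per-subject labeling functions (k-nearest-neighbour classifiers);
    marginal shift is estimated with an H-divergence proxy based on the
    cross-validated accuracy of a random-forest subject discriminator.
    Includes an EEG band-power feature pipeline (resampling, band-pass
    filtering, epoching, power spectral density band integration), four
    feature normalization strategies (none, per-subject z-score, and two
    baseline-referenced schemes), leave-one-subject-out generalization-gap
    evaluation, and a synthetic multi-domain generator with independently
    controllable marginal and conditional shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
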