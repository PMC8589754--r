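Package: pkfilter
Title: Prior Knowledge Filtering for Surgical Phase Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of per-second surgical-phase probability traces
    with prior knowledge filtering (PKF): phase-order correction, per-phase
    sliding-window majority smoothing, gap connection, confidence-based
    overlap resolution, short-segment removal and incidence capping, with
    phase priors (minimum phase time, maximum incidence) derived from
    training annotations. Also provides the focal loss used to train phase
    classifiers on imbalanced data, annotation-segment-balanced and
    class-balanced clip sampling plans, frame-level evaluation metrics
    (accuracy, support-weighted Jaccard, per-phase precision/recall/F1,
    confusion matrices, ribbon plots), a grid-search driver for PKF
    parameters, and a synthetic workflow/noise simulator so the whole
    pipeline is testable without video data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
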