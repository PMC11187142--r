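Package: ripplecue
Title: Sleep Ripple-Spindle Coupling and Cue-Locked Memory Reactivation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolbox for targeted memory reactivation (TMR) studies with
    scalp and intracranial EEG: detection of hippocampal/MTL sharp-wave ripples and
    cortical sleep spindles, phase-amplitude coupling via the Kullback-Leibler
    Modulation Index with trial-shuffle surrogates, circular statistics for
    spindle-phase/ripple coupling, linear-discriminant decoding of retrieval
    patterns with temporal generalization onto sleep data and ripple-locked
    classification against a non-ripple surrogate baseline, and cluster-based
    permutation inference. A synthetic-data module generates NREM-like recordings
    with known ground-truth events, couplings and class patterns so that every
    stage of the pipeline is verifiable without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
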