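Package: ppigate
Title: Simultaneous Muscular and Neural Prepulse Inhibition from EMG and EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for human prepulse-inhibition (PPI) sessions in
    which the acoustic startle reflex is scored from orbicularis oculi EMG and,
    in parallel, neural gating is measured as the P2-N1 event-related potential
    from EEG after automated ICA-based artifact attenuation. Includes readers
    and writers for BrainVision and EDF recordings and BIDS-style event tables,
    zero-phase Butterworth filtering with mains-notch cascades, EMG envelope
    scoring with outlier-trial rejection and responder classification, an
    Infomax ICA implementation with an automated artifactual-component
    classifier (temporal autocorrelation, topographic and trial focality,
    stimulus-locked SNR, EOG/EMG reference correlation), N1/P2 peak measurement,
    the percent-PPI statistic with the repeated-measures test battery, and a
    seeded synthetic-session simulator that provides ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
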