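Package: doaindex
Title: Depth-of-Anesthesia Index from EEG Entropy and Vital Signs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a 0-100 depth-of-anesthesia (DoA) index from a raw
    125 Hz single-channel EEG and 0.2 Hz vital signs. The EEG is cleaned by
    empirical mode decomposition (reconstruction from intrinsic mode
    functions 2-6, covering 0.8-32 Hz), summarised as sample entropy over
    non-overlapping 5-second windows, and fused with electromyography,
    heart rate, pulse, blood pressures and a signal quality index through a
    feed-forward neural network (7-10-1, log-sigmoid) trained by
    backpropagation with momentum against an averaged clinician
    consciousness score. Includes patient-level 10-fold cross-validation
    with fold ensembling, perturbation sensitivity analysis of the model
    inputs, MAE/correlation/ROC evaluation, and a synthetic-patient
    generator for end-to-end testing without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
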