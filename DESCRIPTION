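Package: pephys
Title: Axiomatic Prediction-Error Analysis of Psychophysiological Outcome
    Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of autonomic outcome responses in
    Pavlovian fear conditioning under partial reinforcement. Generates
    multi-modal synthetic recordings (skin conductance, pupil size, heart
    period, respiration amplitude) with known evoked-response structure,
    preprocesses each modality into a clean 10 Hz signal, cuts
    outcome-locked baseline-corrected epochs, fits per-time-bin linear
    mixed-effects contrasts with cluster-based permutation inference,
    evaluates the axiomatic conditions for signed and unsigned
    prediction-error encoding, performs trough-to-peak robustness scoring,
    and runs a simulation-based power analysis for cluster-level tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    arrow,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
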