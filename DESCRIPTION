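Package: betatrace
Title: Single-Channel EEG Beta-Band Attention Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Offline analysis pipeline for low-cost single-channel EEG
    attention monitoring in the classroom. Converts vendor-unit sample
    streams to microvolts, assembles two-second epochs from a packetized
    client-server transport, rejects artifact epochs by an amplitude
    threshold, estimates per-epoch beta-band (12-30 Hz) power with a
    Butterworth/detrend/z-score/Tukey-Welch chain, summarizes subjects by
    total mean beta power with cohort min-max normalization, relates the
    summary to task scores via Pearson, Spearman and skipped (robust)
    correlation with bootstrap confidence intervals, compares best and
    worst performers with a Mann-Whitney U test after normality and
    variance screening, and classifies pass/fail outcomes with a
    grid-searched multilayer perceptron under leave-one-out
    cross-validation. Includes a synthetic cohort generator with known
    ground truth so the whole chain is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    purrr,
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
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
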