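Package: baepstd
Title: Standardized Intraoperative BAEP Indexes for Predicting Hearing Preservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intraoperative binaural brainstem auditory
    evoked potentials (BAEPs) recorded during cerebellopontine-angle surgery.
    Standardizes affected-side wave indicators (latencies I-V, interpeak
    latencies, amplitudes of waves I and V) against the synchronously recorded
    healthy side to cancel common-mode intraoperative interference, computes
    standardized indexes (STI), intraoperative difference values (D) and
    standardized differences (STD), labels hearing preservation from pure tone
    average and word recognition scores via AAO-HNS classes, and evaluates
    predictors of hearing preservation with univariate and stepwise logistic
    regression, ROC/AUC analysis with Youden cutoffs, and paired AUC
    comparison. Includes a synthetic cohort simulator for end-to-end testing
    of the full pipeline, waveform synthesis and peak extraction for the
    measurement layer, and a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
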