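Package: memsig
Title: Spectral and Behavioural Biomarkers of Successful Memory Encoding in Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying subsequent-memory effects in intracranial EEG
    recorded during delayed free recall. Provides a synthetic generator of
    recall behaviour and multichannel 1/f-like encoding epochs with injectable
    effect sizes; serial-position curves, temporal and semantic (ARC) recall
    clustering scores and mixed-effects group contrasts; Morlet-wavelet
    spectral power subsequent-memory t-statistics aggregated to region-by-band
    cells with Benjamini-Hochberg corrected group tests; theta phase-locking
    connectivity networks calibrated by label-shuffle permutation; a
    penalized logistic classifier of recall with session- or list-wise
    cross-validated AUC and permutation significance; and propensity-score
    matched cohort construction with balance diagnostics.
License: MIT + file LICENSE
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
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
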