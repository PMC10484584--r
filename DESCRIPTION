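Package: hsatscore
Title: Autonomic Arousal Detection and Apnea-Hypopnea Index Surrogates for Home Sleep Apnea Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for improving the diagnostic accuracy of home sleep apnea
    tests (HSATs). Implements an autonomic arousal detector based on a dilated
    temporal convolutional network operating on photoplethysmography and
    respiratory flow, scoring rules that turn annotations into apnea-hypopnea
    index surrogates (REI, sleep-staged AHI with and without autonomic arousal
    confirmation of hypopneas), clock shift/drift alignment of dual recordings,
    a physiologically structured synthetic cohort generator, and the full
    diagnostic-agreement statistics suite (ICC of absolute agreement,
    Bland-Altman limits, Wilson and Simel confidence intervals, Cohen's kappa,
    ROC/PR curves, Benjamini-Yekutieli multiplicity control).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    signal,
    generics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
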