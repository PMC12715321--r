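Package: micrographr
Title: Quantification and Automated Recognition of Micrographia from
    Scanned Handwriting Sheets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify consistent and progressive micrographia from
    scanned pen-and-paper handwriting sheets and to evaluate automated
    recognition of Parkinson's disease handwriting. Provides a synthetic
    sheet generator with per-row ink-area ground truth, projection-profile
    row segmentation, calibrated pen-stroke-area metrics (first-row area and
    the last-five/first-five sequence effect), patient-disjoint k-fold
    cross-validated image classification with per-patient likelihood-ratio
    scores, ROC/Youden diagnostics with prevalence-aware operating metrics,
    and a statistical reporting layer. All results are tidy tibbles with
    broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
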