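Package: htmscreen
Title: Pooled Screening Analysis for Bacterial Memory-Circuit Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pooled screens of engineered bacterial
    biosensor strains whose bistable memory switch records transient
    transcriptional signals and, when on, confers antibiotic resistance.
    Provides read-to-trigger counting, spike-in-normalized odds ratios with
    exact one-tailed tests against a shifted null (Fisher noncentral
    hypergeometric), coverage filtering, hit calling, in-vivo responder
    classification, disease-differential scoring, ROC-based cutoff
    calibration, and a ground-truthed synthetic screen simulator that
    emulates the wet-lab protocol end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
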