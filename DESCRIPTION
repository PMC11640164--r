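Package: immunosig
Title: T-Cell Signature Scoring and Differential Immune Infiltration
    Analysis for Bulk Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores sign-aware average z-score T-cell gene signatures
    (stem-like tumor-infiltrating lymphocytes, tissue-resident memory,
    activated-potentially anti-tumor, early and late dysfunctional T cells,
    and BTN3A isoforms) on batch-adjusted log2(TPM+1) bulk expression
    matrices, and runs the downstream analyses those scores support:
    cross-tumor differential infiltration testing with false discovery rate
    control, responder versus non-responder comparison under a 24-month
    overall-survival rule, median-split Kaplan-Meier survival analysis with
    the log-rank test, and rank-based AUROC validation of response
    prediction. Includes a parametric empirical-Bayes batch adjustment, a
    self-contained rank-statistics kernel, and a seeded synthetic cohort
    generator that emulates a multi-cancer observational cohort so the whole
    pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    survival,
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
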