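Package: p53ihc
Title: Concordance of p53 Immunohistochemistry with TP53 Mutation Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates p53 immunohistochemistry (IHC) as a surrogate for TP53
    mutation status in ovarian carcinoma. Parses TP53 variants from HGVS
    protein or coding notation, classifies them into gain-of-function,
    loss-of-function and no-detectable-mutation functional classes, predicts
    the expected IHC staining pattern (overexpression, complete absence,
    wild-type or cytoplasmic) from mechanistic position rules
    (nonsense-mediated decay, DO-7 epitope retention, nuclear localization
    signal loss), cross-tabulates observed staining against mutation class as
    binary and ternary diagnostic classifiers with sensitivity, specificity,
    balanced accuracy and exact binomial confidence intervals, books audited
    revisions of discordant cases, and simulates cohorts with the statistical
    structure of a high-grade serous / endometrioid ovarian carcinoma study
    so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    caret,
    e1071,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
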