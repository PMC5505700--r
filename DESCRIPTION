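Package: tsc2sig
Title: Tsc2 Loss-of-Function Expression Signatures and Clinical
    Association Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives a Tsc2 loss-of-function gene-expression signature from
    mouse fibroblast RNA-seq profiles using the SAM permutation procedure
    (two-class and paired two-class, with fudge-factor estimation and a
    delta-threshold median FDR), quantifies reversal of the signature by the
    mTORC1 inhibitor sirolimus, projects the signature onto a human tumor
    cohort as a directional z-score expression score stratified by non-silent
    TSC1/TSC2 mutation status, and applies the accompanying clinical
    association statistics (Pearson and partial correlation, factorial simple
    main effects, Kaplan-Meier and log-rank).  A synthetic-data module
    generates expression, mutation, clinical and survival tables with planted
    ground truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    car,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
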