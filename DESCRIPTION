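Package: refstab
Title: Reference-Gene Stability Evaluation for RT-qPCR Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates candidate housekeeping (reference) genes for RT-qPCR
    normalization from matrices of raw threshold-cycle (Ct) values. Implements
    five stability estimators (geNorm M-values with stepwise exclusion,
    model-based NormFinder variance decomposition, BestKeeper descriptives and
    index correlation, the comparative delta-Ct method, and the coefficient of
    variation), the geNorm pairwise-variation rule for the optimal number of
    reference genes, a geometric-mean-of-ranks consensus, and delta-delta-Ct
    relative quantification against single- or multi-gene normalization
    factors. Ships a seeded synthetic Ct generator emulating a two-condition
    (acidic vs physiological pH), multi-cell-line qPCR study design, so every
    stage is testable without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
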