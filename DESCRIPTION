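Package: chemosig
Title: Tumor Response Gene Signatures for Induction Chemotherapy from
    Two-Channel Microarrays and qRT-PCR
Version: 0.1.0
Authors@R:
    person("PF", "Signature Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for deriving and evaluating small gene
    signatures that predict tumor response to cisplatin/5-fluorouracil
    induction chemotherapy. Covers spot-level filtering and intra-array
    loess normalization of two-channel microarray data, moderated t-test
    differential expression with Benjamini-Hochberg adjustment, a
    six-criterion composite gene filter with a group-separation score,
    linear support vector machine classification under leave-one-out
    cross-validation with per-fold feature re-selection, delta-delta-Ct
    relative quantification of TaqMan low-density array data with
    cross-platform signature transfer, and evaluation via confusion-matrix
    rates, ROC/AUC, SMACOF multidimensional scaling, Fisher exact and
    rank-based cohort tests. Ships a seeded synthetic-cohort generator so
    the whole pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
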