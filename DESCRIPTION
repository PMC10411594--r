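Package: asereg
Title: Cis- and Trans-Regulatory Analysis of Allele-Specific Expression in
    Reciprocal Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation and classification of regulatory effects on gene
    expression from allele-specific RNA-seq counts in parental lines and
    reciprocal F1 hybrids. Per-gene negative-binomial generalized linear
    models decompose allelic expression into cis-regulatory (CR),
    parent-of-origin (PO) and maternal-genotype (MG) effects, with
    sex-by-cis and tissue-by-cis interaction models and explicit
    allelic-reversal models. A three-test hierarchy (parental differential
    expression, hybrid allelic imbalance, Fisher's exact trans test)
    assigns each gene to one of seven cis/trans divergence categories, and
    a fold-change rule classifies the mode of inheritance of hybrid
    expression (additive, dominant, over-/underdominant). Includes a
    negative-binomial simulator with per-gene ground truth for every
    effect class, sex-bias binning and comparison statistics, and
    cross-sample overlap tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
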