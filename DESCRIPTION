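Package: tcravidity
Title: Sequence-Based Inference of T Cell Receptor Structural Avidity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the structural avidity (monomeric pMHC-TCR dissociation
    half-life) of T cell receptors from CDR3beta sequence and structure-derived
    features. Implements biophysicochemical 4-mer encoding of CDR3beta with the
    five Atchley factors and normalized minimum Manhattan TCR-pair distances,
    UPGMA clustering with high-avidity hotspot detection and a permutation
    control, a linear contact-count model of pMHC-TCR half-life, a logistic
    high/low-avidity classifier on solvent-exposure-gated amino-acid features
    with exhaustive feature-subset search and cross-validation, and
    repertoire-level randomization tests for tumor-versus-blood enrichment of
    predicted high-avidity clonotypes. Includes synthetic-data generators with
    planted structure for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
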