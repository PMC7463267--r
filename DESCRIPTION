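Package: pssmfold
Title: Protein Fold Recognition from PSSM Profiles with Fused
    Auto-Cross-Covariance and Separated-Dimer Features
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for recognising protein folds from PSI-BLAST
    position-specific scoring matrices (PSSMs).  Variable-length L x 20
    profiles are transformed into fixed-length evolutionary feature
    vectors by the auto-cross-covariance (ACC) transform and by
    separated-dimer (SD) scores, the two blocks are fused, features are
    ranked by information gain and band-selected, and folds are
    classified with a grid-tuned one-vs-one support vector machine with
    a radial basis kernel.  Includes a synthetic PSSM generator with
    controllable class structure, a command-line pipeline, and per-class
    sensitivity, precision and F1 reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
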