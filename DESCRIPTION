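Package: DisorderBench
Title: Assessment Toolkit for Intrinsic Disorder and Binding-Site Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds masked residue-level reference sets from disorder,
    binding and observed-structure interval annotations, evaluates
    per-residue predictor outputs with community assessment conventions
    (score rounding, threshold inference, F_max over a fixed threshold
    grid, ROC AUC, zero-denominator metric conventions, residue-level
    bootstrap confidence intervals), implements naive baseline predictors
    (random, label-shuffling, Jensen-Shannon conservation, structure
    complement), orchestrates the disorder, binding and fully-disordered
    protein challenges, and generates complete synthetic benchmark
    fixtures with analytically known operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
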