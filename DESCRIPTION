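Package: sweatPK
Title: Dynamic Metabolic Phenotyping from Finger-Sweat Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models caffeine catabolism measured in finger sweat, where every
    sampled time-point carries an unknown sweat volume. Implements a
    one-compartment first-order kinetic network for caffeine and its
    dimethylxanthine products (paraxanthine, theobromine, theophylline),
    robust bounded multi-start least-squares estimation of kinetic constants
    and per-time-point sweat volumes, synthetic cohort generation with known
    ground truth, LC-MS quantification quality control (calibration, LOD/LLOQ,
    coefficients of variation), and cohort-level statistics (paired tests,
    s0/permutation-FDR volcano analysis, shared-control bootstrap, PCA of
    kinetic constants).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    deSolve,
    minpack.lm,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
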