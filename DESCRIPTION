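Package: roma
Title: Representation and Quantification of Module Activity in Expression Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the activity of gene modules (pathways, transcription
    factor target sets, co-expression clusters) in individual samples as the
    first principal component of the module-restricted expression matrix,
    computed by an iterative SVD algorithm with weighted, fixed-center and
    leave-one-out robust variants. Resolves the PC1 sign ambiguity from prior
    activator/inhibitor annotations, and assesses module overdispersion (L1,
    the fraction of variance explained by PC1) and coordination (L1/L2)
    against empirical null distributions built from random gene sets on a
    log-scale size grid. Includes readers and writers for tab-delimited
    expression matrices and GMT module files with optional signed gene
    weights, low-rank imputation of missing values, a planted-factor
    synthetic data generator with known ground truth, and a two-group
    Kolmogorov-Smirnov comparison of module activities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
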