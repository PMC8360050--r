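Package: clrDiag
Title: Library-Size Dependence Diagnostics for Log-Ratio Analysis of
    Sparse Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Log-ratio principal component analysis (PCA) and redundancy
    analysis (RDA) of amplicon-sequencing count tables become dependent on
    the library size when the data combine many zeroes with large
    library-size variability: after pseudo-counting, row centring leaks the
    per-sample mean of the log counts (r) into the transformed matrix.
    clrDiag provides two per-taxon diagnostics that detect this leakage (the
    correlation of each column of the double-centred log matrix with r, and
    squared taxon loadings on principal axes), log-ratio PCA/RDA with a
    Monte Carlo permutation test on the constrained-inertia fraction,
    alternative transforms (geometric Bayesian-multiplicative zero
    imputation, log proportions, canonical correspondence analysis on raw or
    square-rooted counts), a negative-binomial count simulator with
    controllable library-size variability and treatment-library-size
    coupling, and a scenario harness for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    biomformat,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
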