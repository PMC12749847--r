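Package: mtgblup
Title: Single- and Multi-Trait GBLUP Genomic Prediction for
    Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genomic selection pipeline for multi-environment plant
    breeding trials: SNP quality control and genomic relationship matrix
    construction, incomplete-block design adjustment of plot-level
    phenotypes via linear mixed models, single-trait GBLUP fitted by
    REML through a spectral decomposition of the relationship matrix,
    multi-trait GBLUP with Kronecker covariance fitted by a Gibbs
    sampler with inverse-Wishart updates and data augmentation of
    missing cells, the CV2 pair-balanced cross-validation scheme for
    comparing the two models, and a synthetic-data generator that
    simulates genotypes, genetic values and alpha-lattice trials from
    the same generative model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lme4,
    jsonlite,
    yaml,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
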