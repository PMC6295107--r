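Package: coxummdr
Title: Cox Model Based Unified Multifactor Dimensionality Reduction for
    Survival Phenotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects gene-gene interactions associated with a censored
    survival phenotype. Multi-locus genotype combinations are reduced to a
    binary high/low-risk attribute using martingale residuals from a null
    Cox model, and the resulting risk indicator is tested in a
    covariate-adjusted Cox proportional hazards model with a Wald statistic
    whose null distribution is a non-central chi-square; the non-centrality
    induced by the data-driven classification step is estimated from a
    small number of trait permutations. Includes the cross-validated
    Cox-MDR best-pair comparator, a penetrance-model simulator for
    two-locus epistasis with Weibull-baseline survival times and calibrated
    uniform censoring, and harnesses for type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Survival, GeneticVariability, SNP, GenomeWideAssociation,
    StatisticalMethod, Epistasis
RoxygenNote: 7.3.3
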