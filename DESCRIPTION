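Package: dpr
Title: Latent Dirichlet Process Regression for Polygenic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian non-parametric polygenic prediction of quantitative
    traits with latent Dirichlet process regression: a multiple regression
    model whose per-SNP effect-size variances follow a Dirichlet-process
    prior, equivalent to an infinite normal scale-mixture on the effects.
    Provides a blocked stick-breaking Gibbs sampler and a mean-field
    variational Bayes fitter, readers and writers for PLINK binary and
    BIMBAM mean-genotype formats, genotype quality control (Hardy-Weinberg
    equilibrium, call rate, minor allele frequency), mean imputation and
    phenotype quantile normalization, a simulator for four genetic
    architecture scenarios, Monte Carlo cross-validation, SNP heritability
    (PVE) and posterior inclusion probability summaries, and genetic
    relatedness matrix utilities.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
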