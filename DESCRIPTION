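Package: caprigen
Title: Bayesian Threshold Animal Models for Binary Abortion Traits in Dairy Goats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic and epidemiological analysis of parity-specific binary
    abortion traits in pedigreed dairy-goat herds. Provides pedigree
    validation, inbreeding coefficients and numerator-relationship-matrix
    algebra; univariate and multivariate linear and threshold (liability)
    animal models fitted by Gibbs sampling; posterior summaries (posterior
    mean, posterior SD, highest-posterior-density intervals, effective
    sample size); heritability and genetic/phenotypic correlation
    estimation; k-fold cross-validated model comparison by predictive
    correlation; logistic-regression risk-factor analysis with odds ratios;
    and a synthetic-herd simulator for end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    coda,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
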