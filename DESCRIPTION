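Package: pedREML
Title: Pedigree-Based Animal Models by Average-Information REML
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of genetic parameters for quantitative traits with
    pedigree-based animal models. Builds the numerator relationship matrix,
    inbreeding coefficients and its sparse inverse (Henderson's rules with
    inbreeding); fits univariate and bivariate linear mixed models by
    restricted maximum likelihood using the average-information algorithm
    with an expectation-maximisation fallback; derives heritabilities,
    genetic and phenotypic correlations, genetic coefficients of variation,
    sampling-based standard errors and likelihood-ratio tests; and includes
    a gene-dropping simulator that generates pedigrees and phenotypes with
    the covariance structure the model assumes, patterned on a Korean
    Hanwoo carcass and primal-cut study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
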