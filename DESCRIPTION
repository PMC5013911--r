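Package: permanovaS
Title: Distance-Based Microbiome Association Tests with Confounder
    Adjustment and Multi-Distance Ensembling
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests the association between microbial community composition
    and a covariate of interest using pairwise beta-diversity distances and
    the PERMANOVA pseudo-F statistic.  Extends classic PERMANOVA with
    flexible confounder adjustment (Freedman-Lane residual permutation for
    continuous covariates, parametric bootstrap for binary covariates),
    stratified permutation for paired designs, and a multistage min-P
    procedure that ensembles any number of distances into a single unified
    test.  Implements six beta-diversity distances, including the
    presence-weighted UniFrac family which is sensitive to richness
    differences on the phylogeny, and a Dirichlet-multinomial community
    simulator with lineage-targeted differentiation patterns for power and
    type-I-error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
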