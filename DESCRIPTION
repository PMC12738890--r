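Package: ssrpop
Title: Microsatellite Population Genetics and Coalescent ABC Demographic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diploid codominant microsatellite (SSR) genotype data:
    GenAlEx-dialect readers and STRUCTURE writers, per-population diversity
    statistics (Na, Ne, Shannon's I, Ho, He, FIS), pairwise and global FST with
    island-model gene flow (Nm), AMOVA on Smouse-Peakall squared genotypic
    distances with permutation tests, Nei (1978) genetic distance, principal
    coordinate analysis, UPGMA clustering, and the Evanno delta-K statistic over
    STRUCTURE log-likelihoods. Includes a coalescent simulator for SSR loci
    under a generalized stepwise mutation model with single-nucleotide indels,
    multi-population demographic scenarios (splits, admixture, ancestral size
    change), and approximate Bayesian computation: rejection sampling, scenario
    choice by multinomial logistic regression, Beaumont-style local-linear
    parameter adjustment, and PCA model checking. A synthetic-data module
    generates study-shaped fixtures so every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
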