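Package: codonsel
Title: Codon-Level Selection Analysis with Site Models, Counting Methods,
    and Population-Genetic Selection Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects natural selection on protein-coding genes. Implements
    maximum-likelihood codon site models (M0, M1a, M2a, M7, M8) with
    likelihood-ratio tests, Bayesian site detection (Bayes empirical Bayes,
    random-effects likelihood, and FUBAR-style grid posteriors) with
    multi-method consensus calls, counting-based dN/dS (SLAC) with bootstrap
    confidence intervals, a gene-level test for episodic diversifying
    selection, evolutionary fingerprinting of site rate classes, a
    population-genetics-phylogenetics mapper of population-scaled selection
    coefficients along a gene, and a permutation-envelope test for
    age-dependent expression change. Ships seed-deterministic simulators for
    codon alignments, polymorphism/divergence counts, and expression
    trajectories so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
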