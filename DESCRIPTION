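Package: hogflow
Title: Single-Cell Reporter Distribution Analysis for HOG Pathway Signaling Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative comparison of single-cell fluorescence reporter
    distributions from flow cytometry, built around the budding yeast
    high-osmolarity glycerol (HOG) MAPK pathway. Estimates Kullback-Leibler
    divergence between samples via empirical distribution functions, tests
    mutant reporter distributions against day-pooled wild-type replicates
    (Wilcoxon rank-sum with Bonferroni correction), simulates a two-stage
    stochastic model of HOG transcriptional activation with an exact
    Gillespie algorithm, calibrates simulated molecule counts to the
    fluorescence scale, and fits mutants by sweeping activity and chromatin
    remodeling parameter scales to classify which mutants the model explains.
    Includes a synthetic flow-cytometry data generator emulating the
    day-structured replicate design of such experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    yaml,
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
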