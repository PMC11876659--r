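Package: connectopath
Title: Graph-Theoretical Analysis of Structural and Functional Brain
    Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds functional (band-limited Pearson) and structural
    (fractional-anisotropy-weighted) brain networks from parcellated
    per-subject data, binarizes them over a sparsity grid and computes
    global and nodal graph topology (clustering, path length, small-world
    gamma/lambda/sigma against degree-preserving rewired nulls, global and
    local efficiency, degree, betweenness, nodal efficiency) with
    area-under-curve integration across thresholds.  Provides
    covariate-adjusted permutation tests for group differences with
    Bonferroni or Benjamini-Hochberg correction, partial correlations with
    clinical variables, Baron-Kenny sequential-regression mediation with
    percentile bootstrap confidence intervals, a synthetic two-group
    cohort generator with known ground truth for end-to-end validation,
    and a pipeline orchestrator that runs the whole analysis from one
    configuration.
License: MIT + file LICENSE
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
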