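Package: rulewarp
Title: Latent Rule States and Representational Warping in Set-Shifting Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for rule-based decision-making experiments built
    around the cognitive set-shifting task (a three-color by three-shape analog
    of the Wisconsin Card Sorting Task). Infers latent stimulus-response rule
    states from choice sequences with a constrained seven-state hidden Markov
    model (tied transitions, structural zeros, Baum-Welch and Viterbi),
    evaluates residual choices against a Bayesian ideal-observer expected
    information-gain model, and quantifies how rules reshape neural choice
    coding through single-neuron statistics (Gini sparsity, mutual information,
    identity-category tuning indices, relevance-tuning regressions),
    pseudopopulation construction, representational similarity analysis, and
    choice-predictive subspace projections. Includes parameterized generators
    for synthetic behavior and Poisson spike counts with ground truth so that
    every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
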