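Package: wnp
Title: Gene Function Prediction on Weighted Functional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Guilt-by-association annotation of uncharacterized gene products
    on probabilistic functional networks. Implements the Weighted Network
    Predictor (WNP), a Potts-like objective over log-likelihood-scored edges
    maximized by generalized simulated annealing with a restart-consensus
    layer, together with five reference algorithms (binary simulated
    annealing, FunctionalFlow, chi-square neighborhood scoring, FS-weighted
    averaging, and weighted-average neighbor voting), a planted-module
    synthetic network generator, and a leave-a-percent-out cross-validation
    harness with ROC/AUC and success-rate-versus-functional-degree curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    purrr,
    Rcpp,
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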