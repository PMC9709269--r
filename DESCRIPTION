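Package: refbias
Title: Reward-Driven Learning of Next-Mention and Referent-Form Biases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An operator-based sentence-processing agent that learns
    implicit-causality (next-mention) and referent-form (pronoun versus
    proper name) prediction biases from distributional asymmetries in its
    input, via reward-driven context-operator associative learning. The
    package provides a minimal production-rule engine (buffers, condition
    and action primitives, noisy activation-based operator selection,
    declarative retrieval), the fixed operator set of the reference
    learning model, a synthetic corpus generator with configurable
    continuation probabilities, and a multi-run learning experiment with
    binned learning curves and frozen-learning evaluation on novel items.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
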