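Package: hyperlca
Title: Extended Latent Class Analysis for Random Hypergraphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Model-based clustering of hyperedges in binary hypergraph
    (two-mode network) data via the extended latent class analysis (ELCA)
    model, a two-layer Bernoulli mixture in which each hyperedge carries a
    primary cluster label with membership profile phi and an independent
    size cluster label scaling all membership probabilities by a factor a.
    Provides an expectation conditional maximization (ECM) fitting algorithm
    with minorization-maximization inner steps, BIC model selection over
    (G, K) grids, an exact simulator with hyperedge-size moment and
    Poisson-mixture limit utilities, evaluation metrics (label alignment,
    misclassification, parameter error, model recovery), plain-text file
    formats for incidence data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
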