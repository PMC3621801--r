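Package: netdiss
Title: Dissimilarity-Based Hypothesis Tests for Labelled Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: One- and two-sample hypothesis tests for aligned, labelled
    networks based on a neighbour-aware dissimilarity statistic D that
    combines edge-indicator and weight L1 differences at each node with a
    down-weighted copy over the node's first neighbours. Null distributions
    are obtained by Monte-Carlo sampling from a null network model, by
    bootstrap resampling of a-priori samples, or by permutation of pooled
    sampling units. Includes the network models used to study the test:
    Erdos-Renyi random graphs, block-diagonal correlation populations with
    multivariate-normal sampling, thresholded Pearson correlation networks,
    and shrinkage partial-correlation (Gaussian graphical model) networks,
    together with a simulation harness for type-I-error and power studies
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
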