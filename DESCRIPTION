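Package: emotrain
Title: Directional Emotion Entrainment Analysis for Social Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies directional emotion entrainment between users of an
    online community from ternary (-1/0/+1) emotion time series. Provides
    plug-in and quadrature-smoothed transfer-entropy estimators of dyadic
    entrainment strength, cross-entropy emotional distance, classification of
    dyads into Dual/Single/None entrainment patterns against a time-varying
    community threshold, peer- and community-level convergence analyses,
    community lifecycle statistics with exponential growth fits, a naive Bayes
    polarity classifier with negation-scoped n-gram features and self-training,
    an entrainment-augmented factor-graph model for next-emotion prediction,
    and conventional baseline encodings. A synthetic generator of coupled
    ternary Markov chains with planted dyad patterns supplies ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    nnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
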