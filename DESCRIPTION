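Package: podseq
Title: Interpretable Embedding of Sequence-to-Sequence Recurrent Network
    States
Version: 0.1.0
Authors@R:
    person("podseq", "maintainers", email = "podseq@example.org",
           role = c("aut", "cre"))
Description: Captures the encoder and decoder hidden states of GRU
    encoder-decoder (Seq2Seq) sequence predictors as spatiotemporal
    matrices and embeds them with proper orthogonal decomposition
    (column-centered singular value decomposition with
    singular-value-energy truncation). Decoder-state trajectories form
    separable attractors in the embedding space, so clustering them
    (K-means++ or single-linkage cosine agglomerative) recognizes sequence
    types without labels, monitoring clustering quality along training
    locates the optimal-fit/overfitting transition, and a sliding-window
    scan segments long multi-activity sequences unsupervised. Includes a
    deterministic synthetic-data generator (circles, ellipses, shifted and
    variable-rate circles, one-hot variants, composite sequences) and a
    from-scratch GRU Seq2Seq implementation with full backpropagation
    through the decoder's output-feedback path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
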