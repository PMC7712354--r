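Package: cpembed
Title: Class-Probability Weighted Word Embeddings for Multiclass Text
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised term-weighting of pretrained word embeddings for
    multiclass document classification, with a biomedical-text focus.
    Computes per-term frequency (TF), inverse document frequency (IDF)
    and class-probability (CP) scores from a labeled corpus, scales each
    term's embedding vector by one of these scalars, and evaluates the
    resulting feature tables with a bidirectional LSTM classifier (built
    in, frozen embedding layer) and a suite of classical machine-learning
    baselines.  Includes a word2vec-text-format reader/writer, a
    deterministic synthetic corpus generator emulating balanced medical
    abstract collections, stratified splitting, a scheme-comparison
    harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    withr,
    yaml,
    stats,
    utils,
    e1071,
    nnet,
    rpart,
    class,
    randomForest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
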