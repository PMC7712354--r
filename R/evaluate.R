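#' Split a corpus into training and test parts
#'
#' Documents are shuffled with the seed, then partitioned so the training
#' part holds `round(train_fraction * m)` documents.  With
#' `stratified = TRUE` (the default) class proportions are preserved within
#' rounding: per-class quotas are floors of the exact shares, with the
#' remainder distributed to the classes with the largest fractional parts,
#' so the total is exact.
#'
#' @param corpus a corpus object.
#' @param train_fraction fraction of documents for training, in (0, 1).
#' @param seed integer seed (same seed, same partition).
#' @param stratified preserve class proportions.
#' @return list with corpus elements `train` and `test`.
#' @export
split_corpus <- function(corpus, train_fraction = 0.8, seed = 1L,
                         stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  m <- corpus$m
  n_train <- round(train_fraction * m)
  label <- corpus$documents$label
  train_idx <- withr::with_seed(seed, {
    if (stratified) {
      if (any(corpus$class_counts < 2L)) {
        stop("stratified split requires at least 2 documents per class")
      }
      q <- train_fraction * as.numeric(corpus$class_counts)
      base <- floor(q)
      rem <- n_train - sum(base)
      frac <- q - base
      extra <- integer(length(q))
      if (rem > 0) extra[order(-frac, seq_along(frac))[seq_len(rem)]] <- 1L
      take <- pmin(as.integer(base + extra), as.integer(corpus$class_counts))
      unlist(lapply(seq_along(corpus$classes), function(k) {
        idx <- which(label == corpus$classes[k])
        sample(idx)[seq_len(take[k])]
      }), use.names = FALSE)
    } else {
      sample(m)[seq_len(n_train)]
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(m), train_idx)
  list(train = corpus_subset(corpus, train_idx),
       test = corpus_subset(corpus, test_idx))
}

#' Exact-match classification accuracy
#'
#' @param predicted,truth equal-length label vectors.
#' @return fraction of exact matches.
#' @export
accuracy <- function(predicted, truth) {
  if (!length(truth)) stop("empty label vectors")
  if (length(predicted) != length(truth)) {
    stop("predicted and truth have different lengths")
  }
  mean(as.character(predicted) == as.character(truth))
}

#' Compare the four weighting schemes on one corpus
#'
#' For every seed: split the corpus, compute term weights on the training
#' split only, weight the base table under each scheme, encode both splits
#' against the training vocabulary, train the BLSTM, and record the final
#' epoch's training/validation accuracy and loss.  The held-out split
#' doubles as the validation set.  Returns every run plus per-scheme
#' medians, since single runs of a stochastic trainer are not comparable.
#'
#' @param corpus a deduplicated corpus.
#' @param base an embedding_table covering the corpus vocabulary.
#' @param config a model_config (its seed is overridden per run).
#' @param seeds integer vector of split/training seeds.
#' @param schemes subset of `c("baseline", "tf", "idf", "cp")`.
#' @param train_fraction,stratified see [split_corpus()].
#' @param cp_rule see [compute_term_weights()].
#' @return list with `results` (one tibble row per scheme x seed) and
#'   `medians` (per-scheme medians over seeds).
#' @export
compare_schemes <- function(corpus, base, config, seeds = 1:3,
                            schemes = c("baseline", "tf", "idf", "cp"),
                            train_fraction = 0.8, stratified = TRUE,
                            cp_rule = "max") {
  schemes <- match.arg(schemes, several.ok = TRUE)
  rows <- list()
  for (seed in seeds) {
    sp <- split_corpus(corpus, train_fraction, seed, stratified)
    tw <- compute_term_weights(sp$train, cp_rule = cp_rule)
    tables <- weight_all_schemes(base, tw)
    for (scheme in schemes) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      enc_tr <- encode(sp$train, tables[[scheme]], cfg$max_seq_len)
      enc_te <- encode(sp$test, tables[[scheme]], cfg$max_seq_len,
                       index_to_term = enc_tr$index_to_term,
                       classes = enc_tr$classes)
      model <- build_blstm(cfg, enc_tr$embedding_matrix)
      model <- train_blstm(model, enc_tr, enc_te)
      last <- model$history[nrow(model$history), ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scheme = scheme, seed = seed,
        train_accuracy = last$train_accuracy, val_accuracy = last$val_accuracy,
        train_loss = last$train_loss, val_loss = last$val_loss,
        n_train = sp$train$m, n_test = sp$test$m)
    }
  }
  results <- do.call(rbind, rows)
  medians <- do.call(rbind, lapply(unique(results$scheme), function(s) {
    r <- results[results$scheme == s, ]
    tibble::tibble(scheme = s,
                   val_accuracy = stats::median(r$val_accuracy),
                   train_accuracy = stats::median(r$train_accuracy),
                   val_loss = stats::median(r$val_loss),
                   train_loss = stats::median(r$train_loss))
  }))
  list(results = results, medians = medians)
}

#' Audit that deployed term weights ignore test labels
#'
#' Recomputes the term weights after shuffling the labels of the held-out
#' documents (split membership fixed by document id) and reports the
#' largest absolute change across the TF, IDF, CP and per-class CP maps.
#' Because weights are computed on the training split only, the deployed
#' maps must be bit-identical (difference exactly 0).
#'
#' @param corpus a corpus object.
#' @param train_fraction,seed,stratified see [split_corpus()].
#' @param cp_rule see [compute_term_weights()].
#' @return list with `max_abs_diff` and the logical `identical`.
#' @export
leakage_audit <- function(corpus, train_fraction = 0.8, seed = 1L,
                          stratified = TRUE, cp_rule = "max") {
  sp <- split_corpus(corpus, train_fraction, seed, stratified)
  deployed <- compute_term_weights(sp$train, cp_rule = cp_rule)
  shuffled <- sp$test
  shuffled$documents$label <- withr::with_seed(seed + 1L,
    sample(shuffled$documents$label))
  # rebuild the full corpus with shuffled test labels, keep the same
  # membership by doc_id, and recompute the weights the pipeline would use
  docs <- rbind(sp$train$documents, shuffled$documents)
  rebuilt <- build_corpus(raw_documents(
    docs$doc_id,
    vapply(docs$tokens, paste, character(1), collapse = " "),
    as.list(docs$label)))
  train_ids <- sp$train$documents$doc_id
  rebuilt_train <- corpus_subset(rebuilt, match(train_ids, rebuilt$documents$doc_id))
  recomputed <- compute_term_weights(rebuilt_train, cp_rule = cp_rule)
  d <- max(abs(deployed$tf - recomputed$tf),
           abs(deployed$idf - recomputed$idf),
           abs(deployed$cp - recomputed$cp),
           abs(deployed$cp_by_class - recomputed$cp_by_class))
  list(max_abs_diff = d, identical = d == 0)
}
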