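# Shared fixtures and independent brute-force oracles for the counting
# statistics.  The oracles work directly on raw token lists with explicit
# loops, independent of the package's factor/tabulate indexing.

make_corpus <- function(texts, labels, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("d%03d", seq_along(texts))
  build_corpus(raw_documents(ids, texts, as.list(labels)))
}

random_toy_corpus <- function(seed, max_docs = 50, max_vocab = 200) {
  withr::with_seed(seed, {
    n_classes <- sample(2:4, 1)
    n_docs <- sample((2 * n_classes):max_docs, 1)
    nv <- sample(3:max_vocab, 1)
    vocab <- paste0("w", int_to_letters_helper(seq_len(nv)))
    classes <- paste0("k", letters[seq_len(n_classes)])
    # every class gets at least two documents so stratified splits work
    labels <- c(rep(classes, 2),
                sample(classes, n_docs - 2 * n_classes, replace = TRUE))
    texts <- vapply(seq_len(n_docs), function(i) {
      paste(sample(vocab, sample(3:40, 1), replace = TRUE), collapse = " ")
    }, character(1))
    make_corpus(texts, labels)
  })
}

int_to_letters_helper <- function(n) {
  vapply(n, function(x) {
    out <- character(0)
    repeat {
      out <- c(letters[(x - 1L) %% 26L + 1L], out)
      x <- (x - 1L) %/% 26L
      if (x <= 0L) break
    }
    paste(out, collapse = "")
  }, character(1))
}

oracle_tf_corpus <- function(corpus, term) {
  total <- 0L; hits <- 0L
  for (toks in corpus$documents$tokens) {
    total <- total + length(toks)
    for (t in toks) if (t == term) hits <- hits + 1L
  }
  hits / total
}

oracle_idf <- function(corpus, term) {
  n <- 0L
  for (toks in corpus$documents$tokens) if (term %in% toks) n <- n + 1L
  log(corpus$m / n)
}

oracle_cp <- function(corpus, term, class_k) {
  in_class <- 0L; with_term <- 0L
  for (i in seq_len(corpus$m)) {
    if (corpus$documents$label[i] == class_k) {
      in_class <- in_class + 1L
      if (term %in% corpus$documents$tokens[[i]]) with_term <- with_term + 1L
    }
  }
  with_term / in_class
}

# Fixture-scale BLSTM configuration used across the heavier tests: 32 units
# and 30 epochs (the TF-weighted table rescales inputs by ~1/|V|, so it
# needs the most optimization steps of the four schemes).
fixture_config <- function(n_classes, seed = 1L, epochs = 30L) {
  model_config(n_classes = n_classes, blstm_units = 32L, epochs = epochs,
               max_seq_len = 100L, seed = seed)
}

# full encode/train/evaluate round for one scheme on a pre-split corpus
train_scheme <- function(sp, base, scheme, cfg) {
  tw <- compute_term_weights(sp$train)
  tab <- weight_table(base, tw, scheme)
  enc_tr <- encode(sp$train, tab, cfg$max_seq_len)
  enc_te <- encode(sp$test, tab, cfg$max_seq_len,
                   index_to_term = enc_tr$index_to_term, classes = enc_tr$classes)
  model <- train_blstm(build_blstm(cfg, enc_tr$embedding_matrix), enc_tr, enc_te)
  list(model = model, enc_tr = enc_tr, enc_te = enc_te, sp = sp)
}
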