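tiny_setup <- function(seed = 1, dim = 8, n_per_class = 12) {
  withr::with_seed(seed, {
    classes <- c("a", "b", "c")
    texts <- unlist(lapply(classes, function(k) {
      vapply(seq_len(n_per_class), function(i) {
        paste(sample(paste0(k, "tok", letters[1:5]), 10, replace = TRUE),
              collapse = " ")
      }, character(1))
    }))
    corpus <- make_corpus(texts, rep(classes, each = n_per_class))
    base <- synthetic_embeddings(corpus$vocabulary, dim = dim, seed = seed)
    list(corpus = corpus, base = base)
  })
}

test_that("encode pads, truncates and maps embedding rows correctly", {
  corpus <- make_corpus(c("a b c", "a b c d e f g"), c("x", "y"))
  tab <- synthetic_embeddings(corpus$vocabulary, dim = 6, seed = 2)
  enc <- encode(corpus, tab, max_seq_len = 5)
  expect_identical(dim(enc$sequences), c(2L, 5L))
  expect_identical(enc$sequences[1, 4:5], c(0L, 0L))         # right padding
  expect_true(all(enc$sequences[2, ] > 0L))                  # truncated to 5
  expect_identical(enc$labels, c(0L, 1L))
  # embedding row i+1 equals the table vector of index_to_term[i]
  expect_equal(enc$embedding_matrix[1, ], rep(0, 6))
  for (i in seq_along(enc$index_to_term)) {
    expect_equal(enc$embedding_matrix[i + 1, ],
                 lookup(tab, enc$index_to_term[i]), ignore_attr = TRUE)
  }
  expect_error(encode(corpus, tab, 5, classes = c("x")), "outside the class")
})

test_that("softmax outputs are probability vectors even untrained", {
  s <- tiny_setup()
  cfg <- model_config(n_classes = 3, dim = 8, blstm_units = 8, epochs = 0,
                      max_seq_len = 12, seed = 4)
  enc <- encode(s$corpus, s$base, cfg$max_seq_len)
  model <- build_blstm(cfg, enc$embedding_matrix)
  P <- predict(model, enc, type = "prob")
  expect_identical(dim(P), c(s$corpus$m, 3L))
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, s$corpus$m), tolerance = 1e-6)
  # all-padding document still yields a valid prediction
  empty <- enc
  empty$sequences <- matrix(0L, 1, cfg$max_seq_len)
  P0 <- predict(model, empty, type = "prob")
  expect_equal(sum(P0), 1, tolerance = 1e-6)
  # epochs = 0: empty history
  trained0 <- train_blstm(model, enc)
  expect_identical(nrow(trained0$history), 0L)
})

test_that("the BLSTM learns a separable toy problem and is deterministic", {
  s <- tiny_setup()
  accs <- vapply(1:3, function(seed) {
    cfg <- model_config(n_classes = 3, dim = 8, blstm_units = 8, epochs = 40,
                        batch_size = 8, max_seq_len = 12, seed = seed)
    enc <- encode(s$corpus, s$base, cfg$max_seq_len)
    model <- train_blstm(build_blstm(cfg, enc$embedding_matrix), enc)
    tail(model$history$train_accuracy, 1)
  }, numeric(1))
  expect_gte(median(accs), 0.95)
  # identical seed and inputs -> identical history
  cfg <- model_config(n_classes = 3, dim = 8, blstm_units = 8, epochs = 3,
                      max_seq_len = 12, seed = 11)
  enc <- encode(s$corpus, s$base, cfg$max_seq_len)
  h1 <- train_blstm(build_blstm(cfg, enc$embedding_matrix), enc)$history
  h2 <- train_blstm(build_blstm(cfg, enc$embedding_matrix), enc)$history
  expect_identical(h1, h2)
  # prediction count matches document count
  model <- train_blstm(build_blstm(cfg, enc$embedding_matrix), enc)
  expect_length(predict(model, enc), s$corpus$m)
})

test_that("frozen embeddings are bit-identical after training; trainable ones move", {
  s <- tiny_setup()
  cfg <- model_config(n_classes = 3, dim = 8, blstm_units = 8, epochs = 2,
                      max_seq_len = 12, seed = 5)
  enc <- encode(s$corpus, s$base, cfg$max_seq_len)
  model <- build_blstm(cfg, enc$embedding_matrix)
  trained <- train_blstm(model, enc)
  expect_identical(trained$embedding_matrix, enc$embedding_matrix)
  cfg$trainable_embeddings <- TRUE
  trained2 <- train_blstm(build_blstm(cfg, enc$embedding_matrix), enc)
  expect_false(identical(trained2$embedding_matrix, enc$embedding_matrix))
  # padding row stays zero either way
  expect_equal(trained2$embedding_matrix[1, ], rep(0, 8))
})

test_that("mean pooling matches hand-computed averages", {
  tab <- synthetic_embeddings(c("u", "v", "w"), dim = 4, seed = 6)
  expect_equal(pool_document_vector("u", tab), lookup(tab, "u"))
  hand <- (lookup(tab, "u") + lookup(tab, "v") + lookup(tab, "w")) / 3
  expect_equal(pool_document_vector(c("u", "v", "w"), tab), hand)
  # opposite vectors cancel
  tab$vectors["v", ] <- -tab$vectors["u", ]
  expect_warning(z <- pool_document_vector(c("u", "v"), tab), "zero")
  expect_equal(z, rep(0, 4))
  expect_error(pool_document_vector(character(0), tab), "empty")
  corpus <- make_corpus(c("u v", "w w"), c("x", "y"))
  M <- pool_corpus_matrix(corpus, synthetic_embeddings(c("u", "v", "w"), 4, 6))
  expect_identical(dim(M), c(2L, 4L))
})

test_that("baseline suite runs all eight algorithms on separable blobs", {
  withr::with_seed(3, {
    n <- 40
    centers <- matrix(rnorm(3 * 10, sd = 4), nrow = 3)
    X <- do.call(rbind, lapply(1:3, function(k) {
      matrix(rnorm(n * 10), ncol = 10) + matrix(centers[k, ], n, 10, byrow = TRUE)
    }))
    y <- rep(c("a", "b", "c"), each = n)
    idx <- sample(length(y), 90)
    res <- run_baselines(X[idx, ], y[idx], X[-idx, ], y[-idx])
    expect_length(res, 8L)
    expect_named(res, c("LR", "kNN5", "RF", "SVM", "LinearSVM", "DT", "MLP", "GNB"))
    expect_gte(res[["LinearSVM"]], 0.9)
    expect_true(all(res >= 0 & res <= 1))
    expect_error(run_baselines(X[idx, ], y[idx], X[-idx, ], y[-idx],
                               suite = "AdaBoost"), "unknown algorithm")
    # degenerate single-class task: every algorithm is trivially perfect
    one <- run_baselines(X[1:20, ], rep("a", 20), X[21:30, ], rep("a", 10))
    expect_true(all(one == 1))
  })
})
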