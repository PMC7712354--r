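test_that("per-document TF is count over length", {
  expect_identical(tf_per_document(c("a", "b", "a", "a"), "a"), 0.75)
  expect_identical(tf_per_document(c("a", "b"), "z"), 0)
  expect_identical(tf_per_document("x", "x"), 1)
  expect_error(tf_per_document(character(0), "x"), "empty document")
})

test_that("corpus-level TF is total occurrences over total tokens", {
  corpus <- make_corpus(c("a b", "a a"), c("x", "y"))
  expect_equal(tf_corpus(corpus, "a"), 0.75)
  expect_equal(tf_corpus(make_corpus("x", "k"), "x"), 1)
  # uniform corpus: every term once -> 1/n each
  corpus <- make_corpus(c("a b", "c d"), c("x", "y"))
  expect_equal(unname(tf_corpus(corpus, c("a", "b", "c", "d"))), rep(0.25, 4))
  expect_error(tf_corpus(corpus, "nope"), "not in vocabulary")
})

test_that("IDF follows log(m/N) with the documented closed forms", {
  # term in every document -> 0
  corpus <- make_corpus(c("a b", "a c"), c("x", "y"))
  expect_equal(idf(corpus, "a"), 0)
  # m = 10, N = 1 -> ln 10
  texts <- c("rare common", rep("common filler", 9))
  corpus <- make_corpus(texts, rep(c("x", "y"), 5))
  expect_equal(idf(corpus, "rare"), log(10))
  # monotone: rarer term has larger idf
  expect_gt(idf(corpus, "rare"), idf(corpus, "filler"))
  # literal orientation is the sign flip
  expect_equal(idf(corpus, "rare", orientation = "literal"), -log(10))
})

test_that("class probability is the within-class containment fraction", {
  texts <- c("t a", "t b", "t c", "d e", "x y")
  labels <- c("A", "A", "A", "A", "B")
  corpus <- make_corpus(texts, labels)
  expect_equal(class_probability(corpus, "t", "A"), 0.75)
  expect_equal(class_probability(corpus, "x", "B"), 1)
  expect_equal(class_probability(corpus, "x", "A"), 0)
  expect_error(class_probability(corpus, "t", "nope"), "unknown class")
})

test_that("reduce_cp applies max/mean and rejects unknown rules", {
  expect_identical(reduce_cp(c(0.1, 0.9), "max"), 0.9)
  expect_equal(reduce_cp(c(0.2, 0.4), "mean"), 0.3)
  expect_identical(reduce_cp(0.7, "max"), 0.7)  # single class
  m <- matrix(c(0.1, 0.9, 0.2, 0.4), nrow = 2, byrow = TRUE)
  expect_equal(reduce_cp(m, "max"), c(0.9, 0.4))
  expect_error(reduce_cp(c(0.1), "median"))
})

test_that("compute_term_weights covers the vocabulary with coherent maps", {
  corpus <- random_toy_corpus(3)
  tw <- compute_term_weights(corpus)
  expect_setequal(tw$term, corpus$vocabulary)
  expect_identical(names(tw$tf), tw$term)
  expect_true(all(tw$tf >= 0 & tw$tf <= 1))
  expect_true(all(tw$cp >= 0 & tw$cp <= 1))
  expect_true(all(tw$idf >= 0))
  expect_equal(unname(tw$cp), unname(reduce_cp(tw$cp_by_class, "max")))
  # a term appearing in all docs of all classes: idf 0, cp 1
  corpus2 <- make_corpus(c("t a", "t b", "t c"), c("A", "B", "B"))
  tw2 <- compute_term_weights(corpus2)
  expect_equal(unname(tw2$idf["t"]), 0)
  expect_equal(unname(tw2$cp["t"]), 1)
})

test_that("vectorized weights match the brute-force recount oracle", {
  corpus <- random_toy_corpus(17, max_docs = 30)
  tw <- compute_term_weights(corpus)
  for (term in sample(corpus$vocabulary, min(12, length(corpus$vocabulary)))) {
    expect_equal(unname(tw$tf[term]), oracle_tf_corpus(corpus, term), tolerance = 1e-12)
    expect_equal(unname(tw$idf[term]), oracle_idf(corpus, term), tolerance = 1e-12)
    for (k in corpus$classes) {
      expect_equal(unname(tw$cp_by_class[term, k]), oracle_cp(corpus, term, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("weight invariants hold on random corpora", {
  for (seed in c(5, 23, 91)) {
    corpus <- random_toy_corpus(seed, max_docs = 30)
    tw <- compute_term_weights(corpus)
    # total-occurrence normalization
    expect_equal(sum(tw$tf), 1, tolerance = 1e-12)
    # idf nonincreasing in document frequency
    cc <- cpembed:::corpus_counts(corpus)
    ord <- order(cc$dfreq)
    expect_true(all(diff(tw$idf[ord]) <= 1e-12))
    # max reduction dominates mean
    tw_mean <- compute_term_weights(corpus, cp_rule = "mean")
    expect_true(all(tw$cp - tw_mean$cp >= -1e-12))
  }
})

test_that("mean-document TF estimator averages per-document TF over containing docs", {
  corpus <- make_corpus(c("a a b", "a c"), c("x", "y"))
  tf <- tf_corpus(corpus, "a", estimator = "mean_doc")
  expect_equal(tf, mean(c(2 / 3, 1 / 2)))
})

test_that("term weights serialize and reload through TSV", {
  corpus <- random_toy_corpus(8, max_docs = 15, max_vocab = 30)
  tw <- compute_term_weights(corpus)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_term_weights(tw, path)
  back <- read_term_weights(path)
  expect_equal(unname(back$tf), unname(tw$tf), tolerance = 1e-9)
  expect_equal(unname(back$cp_by_class), unname(tw$cp_by_class), tolerance = 1e-9)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(header[1:4], c("term", "tf", "idf", "cp"))
})
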