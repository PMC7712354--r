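test_that("clean_text removes punctuation and digits, lowercases, squishes", {
  expect_identical(clean_text("Acute MI, 3 patients!"), "acute mi patients")
  expect_identical(clean_text(""), "")
  expect_identical(clean_text("blood"), "blood")
  expect_identical(clean_text("a_b-c.d"), "a b c d")
  expect_identical(clean_text("123"), "")
  expect_identical(clean_text("  spaced\tout\ntext  "), "spaced out text")
})

test_that("clean_text is idempotent and leaves no digit/punct in any token", {
  withr::with_seed(42, {
    pool <- c(letters, LETTERS, 0:9, strsplit("!\"#$%&'()*+,-./:;<=>?@[]^_`{|}~", "")[[1]],
              " ", "\t", "é", "–", "−")
    for (i in 1:50) {
      raw <- paste(sample(pool, sample(1:80, 1), replace = TRUE), collapse = "")
      once <- clean_text(raw)
      expect_identical(clean_text(once), once)
      toks <- tokenize(once)
      if (length(toks)) {
        expect_false(any(grepl("[[:digit:][:punct:]]", toks)))
        expect_identical(toks, tolower(toks))
      }
    }
  })
})

test_that("tokenize splits on whitespace, preserving order, dropping empties", {
  expect_identical(tokenize("acute mi patients"), c("acute", "mi", "patients"))
  expect_identical(tokenize("blood"), "blood")
  expect_identical(tokenize(" a  b "), c("a", "b"))
  expect_identical(tokenize(""), character(0))
})

test_that("deduplicate_multilabel keeps exactly the single-label documents", {
  docs <- raw_documents(c("d1", "d2", "d3", "d4"),
                        c("a", "b", "c", "d"),
                        list("A", c("A", "B"), "C", character(0)))
  out <- suppressMessages(deduplicate_multilabel(docs))
  expect_identical(out$doc_id, c("d1", "d3"))
  # identity on all-single-label input, order preserved
  single <- raw_documents(c("x", "y"), c("t", "u"), list("A", "B"))
  expect_identical(deduplicate_multilabel(single), single)
})

test_that("deduplicate_multilabel never grows and matches constructed counts", {
  withr::with_seed(7, {
    n <- 20
    labels <- lapply(1:n, function(i) "A")
    multi <- sample(n, 7)
    for (i in multi) labels[[i]] <- c("A", "B")
    docs <- raw_documents(sprintf("d%02d", 1:n), rep("txt", n), labels)
    out <- suppressMessages(deduplicate_multilabel(docs))
    expect_identical(nrow(out), 13L)
    expect_true(!is.unsorted(match(out$doc_id, docs$doc_id)))
  })
})

test_that("build_corpus assembles vocabulary, classes and counts", {
  corpus <- make_corpus(c("a b", "b c"), c("x", "y"))
  expect_setequal(corpus$vocabulary, c("a", "b", "c"))
  expect_identical(corpus$m, 2L)
  expect_identical(corpus$classes, c("x", "y"))
  expect_identical(sum(corpus$class_counts), 2L)
  one <- make_corpus("solo", "k")
  expect_length(one$vocabulary, 1L)
  expect_error(build_corpus(raw_documents(character(), character(), list())),
               "zero documents")
  expect_error(build_corpus(raw_documents("d1", "t", list(c("A", "B")))),
               "exactly one label")
})

test_that("corpus vocabulary equals the union of document token sets", {
  corpus <- random_toy_corpus(11)
  expect_setequal(corpus$vocabulary,
                  unique(unlist(corpus$documents$tokens)))
})

test_that("TSV round trip preserves documents and labels", {
  docs <- raw_documents(c("d1", "d2"), c("acute mi", "blood flow"),
                        list("A", c("A", "B")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus_tsv(docs, path)
  back <- read_corpus_tsv(path)
  expect_identical(back$doc_id, docs$doc_id)
  expect_identical(back$text, docs$text)
  expect_identical(back$labels, docs$labels)
})

test_that("directory-per-class layout is read correctly", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "cardio"))
  dir.create(file.path(root, "renal"))
  writeLines("heart attack", file.path(root, "cardio", "a.txt"))
  writeLines("kidney stone", file.path(root, "renal", "b.txt"))
  docs <- read_corpus_dir(root)
  expect_identical(nrow(docs), 2L)
  expect_setequal(unlist(docs$labels), c("cardio", "renal"))
  corpus <- build_corpus(docs)
  expect_true("kidney" %in% corpus$vocabulary)
})

test_that("corpus_summary reports per-class counts and vocabulary size", {
  corpus <- make_corpus(c("a b", "b c", "c d"), c("x", "y", "y"))
  s <- corpus_summary(corpus)
  expect_identical(s$n_documents, c(1L, 2L))
  expect_identical(attr(s, "vocabulary_size"), 4L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus_summary(corpus, path)
  rep <- utils::read.delim(path)
  expect_identical(rep$n_documents[rep$class == "<vocabulary>"], 4L)
  expect_identical(rep$n_documents[rep$class == "<total>"], 3L)
})
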