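# Letters-only base-26 encoding so synthetic tokens survive cleaning
# (digits would be stripped).
int_to_letters <- function(n) {
  vapply(n, function(x) {
    out <- character(0)
    x <- as.integer(x)
    repeat {
      out <- c(letters[(x - 1L) %% 26L + 1L], out)
      x <- (x - 1L) %/% 26L
      if (x <= 0L) break
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Specification for a synthetic labeled corpus
#'
#' Defaults emulate the shape of a balanced medical-abstract benchmark:
#' 23 classes x 400 documents averaging ~180 tokens.  Each document mixes a
#' shared background vocabulary with its class's indicative vocabulary;
#' indicative terms have their sampling odds multiplied by
#' `class_term_boost` inside their own class (boost 1 = no class signal).
#' Document lengths follow a clipped negative binomial around
#' `mean_doc_len`, giving heavy-tailed lengths like real abstracts.
#'
#' @param n_classes number of classes.
#' @param docs_per_class documents per class.
#' @param mean_doc_len mean document length in tokens.
#' @param len_dispersion negative-binomial size parameter (smaller = more
#'   dispersed); lengths are clipped below at 5.
#' @param shared_vocab_size background vocabulary size.
#' @param class_vocab_size indicative terms per class.
#' @param class_term_boost odds multiplier (>= 1) for a class's indicative
#'   terms within that class.
#' @param multilabel_fraction fraction of documents (exact count, rounded)
#'   given a second label, to exercise the multilabel filter.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_classes = 23L, docs_per_class = 400L,
                           mean_doc_len = 180L, len_dispersion = 10,
                           shared_vocab_size = 2000L, class_vocab_size = 40L,
                           class_term_boost = 5, multilabel_fraction = 0,
                           seed = 1L) {
  stopifnot(n_classes >= 1L, docs_per_class >= 1L, mean_doc_len >= 1L,
            len_dispersion > 0, shared_vocab_size >= 1L, class_vocab_size >= 1L,
            class_term_boost >= 1, multilabel_fraction >= 0,
            multilabel_fraction < 1)
  structure(list(n_classes = as.integer(n_classes),
                 docs_per_class = as.integer(docs_per_class),
                 mean_doc_len = as.integer(mean_doc_len),
                 len_dispersion = len_dispersion,
                 shared_vocab_size = as.integer(shared_vocab_size),
                 class_vocab_size = as.integer(class_vocab_size),
                 class_term_boost = class_term_boost,
                 multilabel_fraction = multilabel_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labeled synthetic corpus
#'
#' @param spec a synthetic_spec.
#' @return a raw-document table (see [raw_documents()]); class names are
#'   `"ca"`, `"cb"`, ...; tokens are letters-only strings like `"bgqt"`
#'   (background) and `"caxbd"` (class `ca` indicative term).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  K <- spec$n_classes
  classes <- paste0("c", int_to_letters(seq_len(K)))
  shared <- paste0("bg", int_to_letters(seq_len(spec$shared_vocab_size)))
  class_terms <- lapply(seq_len(K), function(k) {
    paste0(classes[k], "x", int_to_letters(seq_len(spec$class_vocab_size)))
  })
  all_terms <- c(shared, unlist(class_terms))
  n_shared <- length(shared)
  vc <- spec$class_vocab_size
  n <- K * spec$docs_per_class
  withr::with_seed(spec$seed, {
    label_idx <- rep(seq_len(K), each = spec$docs_per_class)
    lens <- pmax(5L, stats::rnbinom(n, size = spec$len_dispersion,
                                    mu = spec$mean_doc_len))
    texts <- character(n)
    for (k in seq_len(K)) {
      w <- rep(1, length(all_terms))
      w[n_shared + (k - 1L) * vc + seq_len(vc)] <- spec$class_term_boost
      p <- w / sum(w)
      for (i in which(label_idx == k)) {
        texts[i] <- paste(sample(all_terms, lens[i], replace = TRUE, prob = p),
                          collapse = " ")
      }
    }
    labels <- as.list(classes[label_idx])
    n_multi <- round(spec$multilabel_fraction * n)
    if (n_multi > 0L) {
      pick <- sample(n, n_multi)
      for (i in pick) {
        other <- sample(setdiff(seq_len(K), label_idx[i]), 1L)
        labels[[i]] <- c(labels[[i]], classes[other])
      }
    }
    raw_documents(sprintf("syn%06d", seq_len(n)), texts, labels)
  })
}

#' Standing synthetic test fixtures
#'
#' Named small corpora exercising the pipeline end to end:
#' * `null` — 4 classes x 100 docs, boost 1: no class signal, so a
#'   classifier should sit at chance.
#' * `separable` — 5 classes x 200 docs, small shared vocabulary with a
#'   strong boost: near-disjoint class vocabularies, easily learnable.
#' * `moderate` — 6 classes x 150 docs, boost 2.5: partial class signal.
#' * `multilabel` — 100 docs with multilabel_fraction 0.2, so exactly 80
#'   survive the multilabel filter.
#' * `ohsumed_shape` — the generator defaults (23 x 400, mean 180 tokens).
#'
#' @param seed base seed; each fixture derives its own offset.
#' @param which subset of fixture names to generate.
#' @return named list of raw-document tables.
#' @export
generate_fixture_suite <- function(seed = 1L,
                                   which = c("null", "separable", "moderate",
                                             "multilabel", "ohsumed_shape")) {
  which <- match.arg(which, several.ok = TRUE)
  specs <- list(
    null = synthetic_spec(n_classes = 4L, docs_per_class = 100L,
                          mean_doc_len = 40L, shared_vocab_size = 300L,
                          class_vocab_size = 30L, class_term_boost = 1,
                          seed = seed),
    separable = synthetic_spec(n_classes = 5L, docs_per_class = 200L,
                               mean_doc_len = 60L, shared_vocab_size = 50L,
                               class_vocab_size = 30L, class_term_boost = 40,
                               seed = seed + 1L),
    moderate = synthetic_spec(n_classes = 6L, docs_per_class = 150L,
                              mean_doc_len = 50L, shared_vocab_size = 400L,
                              class_vocab_size = 30L, class_term_boost = 2.5,
                              seed = seed + 2L),
    multilabel = synthetic_spec(n_classes = 5L, docs_per_class = 20L,
                                mean_doc_len = 30L, shared_vocab_size = 200L,
                                class_vocab_size = 20L, class_term_boost = 5,
                                multilabel_fraction = 0.2, seed = seed + 3L),
    ohsumed_shape = synthetic_spec(seed = seed + 4L)
  )
  lapply(specs[which], generate_corpus)
}
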