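#' Clean raw text for tokenization
#'
#' Applies the three cleaning rules used throughout the package: remove
#' punctuation (Unicode punctuation and symbol categories, replaced by a
#' space so joined words split apart), remove digits (removed in place, so
#' purely numeric tokens vanish), and lowercase everything.  Runs of
#' whitespace collapse to single spaces.  The function is idempotent and
#' vectorized.
#'
#' @param x character vector of raw text.
#' @return character vector of the same length, cleaned.
#' @examples
#' clean_text("Acute MI, 3 patients!")  # "acute mi patients"
#' @export
clean_text <- function(x) {
  stopifnot(is.character(x))
  x <- tolower(x)
  x <- gsub("[\\p{P}\\p{S}]+", " ", x, perl = TRUE)
  x <- gsub("\\p{N}+", "", x, perl = TRUE)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

#' Tokenize a cleaned string
#'
#' Whitespace splitting with empty tokens dropped; order is preserved
#' because the sequence classifier consumes token order.
#'
#' @param cleaned a single cleaned string (see [clean_text()]).
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(cleaned) {
  stopifnot(is.character(cleaned), length(cleaned) == 1L)
  out <- strsplit(trimws(cleaned), "\\s+")[[1L]]
  out[nzchar(out)]
}

#' Construct a raw-document table
#'
#' A raw document carries an identifier, its unprocessed text, and the full
#' list of labels as read from the input (zero or more; multiclass filtering
#' happens later in [deduplicate_multilabel()]).
#'
#' @param doc_id character vector of unique identifiers.
#' @param text character vector of raw text.
#' @param labels list of character vectors, one per document.
#' @return a tibble with columns `doc_id`, `text`, `labels` (list-column).
#' @export
raw_documents <- function(doc_id, text, labels) {
  doc_id <- as.character(doc_id)
  text <- as.character(text)
  if (!is.list(labels)) labels <- as.list(labels)
  stopifnot(length(doc_id) == length(text), length(text) == length(labels))
  if (anyDuplicated(doc_id)) stop("doc_id values must be unique")
  labels <- lapply(labels, as.character)
  tibble::tibble(doc_id = doc_id, text = text, labels = labels)
}

#' Keep only single-label documents
#'
#' Multiclass modeling requires exactly one label per document; documents
#' with two or more labels (and the degenerate zero-label case) are removed.
#' Relative order is preserved and the removal counts are reported.
#'
#' @param docs raw-document table (see [raw_documents()]).
#' @return the filtered raw-document table.
#' @export
deduplicate_multilabel <- function(docs) {
  nlab <- lengths(docs$labels)
  n_multi <- sum(nlab > 1L)
  n_none <- sum(nlab == 0L)
  if (n_multi + n_none > 0L) {
    message(sprintf("deduplicate_multilabel: removed %d multi-label and %d unlabeled documents (%d remain)",
                    n_multi, n_none, sum(nlab == 1L)))
  }
  docs[nlab == 1L, , drop = FALSE]
}

#' Build a corpus from single-label raw documents
#'
#' Cleans and tokenizes every document and assembles the corpus object:
#' the document table (id, label, token sequence), the vocabulary V (sorted
#' distinct terms), the class inventory, the total document count m and the
#' per-class document counts.
#'
#' @param docs raw-document table; every document must carry exactly one
#'   label (apply [deduplicate_multilabel()] first).
#' @return an object of class `"corpus"`.
#' @export
build_corpus <- function(docs) {
  if (!nrow(docs)) stop("cannot build a corpus from zero documents")
  if (any(lengths(docs$labels) != 1L)) {
    stop("all documents must have exactly one label; run deduplicate_multilabel() first")
  }
  label <- vapply(docs$labels, `[[`, character(1), 1L)
  cleaned <- clean_text(docs$text)
  toks <- strsplit(cleaned, " ", fixed = TRUE)
  toks <- lapply(toks, function(t) t[nzchar(t)])
  n_empty <- sum(lengths(toks) == 0L)
  if (n_empty > 0L) {
    message(sprintf("build_corpus: %d documents are empty after cleaning", n_empty))
  }
  classes <- sort(unique(label))
  counts <- vapply(classes, function(k) sum(label == k), integer(1))
  structure(list(
    documents = tibble::tibble(doc_id = docs$doc_id, label = label, tokens = toks),
    vocabulary = sort(unique(unlist(toks, use.names = FALSE))),
    classes = classes,
    m = nrow(docs),
    class_counts = counts
  ), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d documents, %d classes, vocabulary %d terms\n",
              x$m, length(x$classes), length(x$vocabulary)))
  cat("classes:", paste(head(x$classes, 8), collapse = ", "),
      if (length(x$classes) > 8) "..." else "", "\n")
  invisible(x)
}

# Subset a corpus by document row indices; vocabulary is recomputed, the
# class inventory is inherited from the parent so encodings stay aligned.
corpus_subset <- function(corpus, idx) {
  docs <- corpus$documents[idx, , drop = FALSE]
  counts <- vapply(corpus$classes, function(k) sum(docs$label == k), integer(1))
  structure(list(
    documents = docs,
    vocabulary = sort(unique(unlist(docs$tokens, use.names = FALSE))),
    classes = corpus$classes,
    m = nrow(docs),
    class_counts = counts
  ), class = "corpus")
}

#' Summarize a corpus
#'
#' @param corpus a corpus object.
#' @return a tibble with one row per class (`class`, `n_documents`) plus
#'   attributes `vocabulary_size` and `n_documents_total`.
#' @export
corpus_summary <- function(corpus) {
  out <- tibble::tibble(class = corpus$classes,
                        n_documents = as.integer(corpus$class_counts))
  attr(out, "vocabulary_size") <- length(corpus$vocabulary)
  attr(out, "n_documents_total") <- corpus$m
  out
}

#' Write a corpus summary report as TSV
#'
#' Per-class document counts followed by total and vocabulary-size rows.
#'
#' @param corpus a corpus object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_corpus_summary <- function(corpus, path) {
  s <- corpus_summary(corpus)
  df <- rbind(data.frame(class = s$class, n_documents = s$n_documents),
              data.frame(class = c("<total>", "<vocabulary>"),
                         n_documents = c(corpus$m, length(corpus$vocabulary))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a labeled corpus from a delimited file
#'
#' Expects a header with at least `label` and `text` columns (a `doc_id`
#' column is honored if present).  Multi-label documents encode their labels
#' joined by `label_sep`.
#'
#' @param path input file.
#' @param sep field separator (default tab).
#' @param label_sep separator joining multiple labels (default `"|"`).
#' @return raw-document table.
#' @export
read_corpus_tsv <- function(path, sep = "\t", label_sep = "|") {
  df <- utils::read.delim(path, sep = sep, header = TRUE, quote = "",
                          colClasses = "character", fileEncoding = "UTF-8",
                          check.names = FALSE)
  if (!all(c("label", "text") %in% names(df))) {
    stop("corpus file must have 'label' and 'text' columns")
  }
  doc_id <- if ("doc_id" %in% names(df)) df$doc_id else sprintf("doc%06d", seq_len(nrow(df)))
  raw_documents(doc_id, df$text, strsplit(df$label, label_sep, fixed = TRUE))
}

#' Write a labeled corpus to a delimited file
#'
#' @param docs raw-document table.
#' @inheritParams read_corpus_tsv
#' @return `path`, invisibly.
#' @export
write_corpus_tsv <- function(docs, path, sep = "\t", label_sep = "|") {
  lab <- vapply(docs$labels, paste, character(1), collapse = label_sep)
  txt <- gsub("[\t\n\r]", " ", docs$text)
  df <- data.frame(doc_id = docs$doc_id, label = lab, text = txt,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a corpus laid out as one directory per class
#'
#' Each immediate subdirectory of `root` names a class; every `*.txt` file
#' inside is one document (the file stem is the document id, prefixed by the
#' class to keep ids unique across classes).
#'
#' @param root directory containing one subdirectory per class.
#' @return raw-document table.
#' @export
read_corpus_dir <- function(root) {
  classes <- list.dirs(root, full.names = FALSE, recursive = FALSE)
  if (!length(classes)) stop("no class subdirectories under ", root)
  rows <- lapply(classes, function(k) {
    files <- list.files(file.path(root, k), pattern = "\\.txt$", full.names = TRUE)
    if (!length(files)) return(NULL)
    txt <- vapply(files, function(f) paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                                           collapse = " "), character(1))
    stem <- sub("\\.txt$", "", basename(files))
    tibble::tibble(doc_id = paste(k, stem, sep = "/"), text = unname(txt),
                   labels = as.list(rep(k, length(files))))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no .txt documents found under ", root)
  out
}
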