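#' Term frequency within one document
#'
#' TF of a term in a document: occurrence count divided by document length
#' in tokens, so values lie in \[0, 1\].
#'
#' @param tokens character vector, the document's token sequence.
#' @param term the term to score.
#' @return a single number in \[0, 1\].
#' @export
tf_per_document <- function(tokens, term) {
  stopifnot(is.character(tokens), is.character(term), length(term) == 1L)
  if (!length(tokens)) stop("term frequency is undefined for an empty document")
  sum(tokens == term) / length(tokens)
}

# Shared per-corpus counting: total occurrences, document frequency, and
# per-class document frequency for every vocabulary term.
corpus_counts <- function(corpus) {
  vocab <- corpus$vocabulary
  nv <- length(vocab)
  toks <- corpus$documents$tokens
  occ <- tabulate(factor(unlist(toks, use.names = FALSE), levels = vocab), nbins = nv)
  uniq <- lapply(toks, unique)
  dfreq <- tabulate(factor(unlist(uniq, use.names = FALSE), levels = vocab), nbins = nv)
  label <- corpus$documents$label
  class_df <- vapply(corpus$classes, function(k) {
    tabulate(factor(unlist(uniq[label == k], use.names = FALSE), levels = vocab), nbins = nv)
  }, integer(nv))
  if (nv == 1L) class_df <- matrix(class_df, nrow = 1L,
                                   dimnames = list(NULL, corpus$classes))
  list(vocab = vocab, occ = occ, total_tokens = sum(lengths(toks)),
       dfreq = dfreq, class_df = class_df, uniq = uniq)
}

#' Corpus-level term frequency
#'
#' One TF scalar per term, as needed to scale a single embedding vector:
#' total occurrences of the term across the corpus divided by the total
#' token count ("global" estimator).  The alternative "mean_doc" estimator
#' averages the per-document TF over the documents containing the term.
#'
#' @param corpus a corpus object.
#' @param term character vector of terms (must be in the vocabulary).
#' @param estimator `"global"` (default) or `"mean_doc"`.
#' @return numeric vector of TF scores in (0, 1\].
#' @export
tf_corpus <- function(corpus, term, estimator = c("global", "mean_doc")) {
  estimator <- match.arg(estimator)
  miss <- setdiff(term, corpus$vocabulary)
  if (length(miss)) stop("term(s) not in vocabulary: ", paste(miss, collapse = ", "))
  cc <- corpus_counts(corpus)
  tf <- tf_from_counts(cc, corpus, estimator)
  tf[match(term, cc$vocab)]
}

tf_from_counts <- function(cc, corpus, estimator) {
  if (estimator == "global") return(cc$occ / cc$total_tokens)
  nv <- length(cc$vocab)
  contrib <- numeric(nv)
  toks <- corpus$documents$tokens
  for (t in toks) {
    if (!length(t)) next
    contrib <- contrib + tabulate(factor(t, levels = cc$vocab), nbins = nv) / length(t)
  }
  ifelse(cc$dfreq > 0, contrib / cc$dfreq, 0)
}

#' Inverse document frequency
#'
#' IDF of a term: `log(m / N)` with natural logarithm, where m is the number
#' of documents and N the number of documents containing the term; zero iff
#' the term occurs in every document, larger for rarer terms.  The
#' `"literal"` orientation `log(N / m)` (the sign-flipped variant) is
#' available for comparison runs.
#'
#' @inheritParams tf_corpus
#' @param orientation `"standard"` (default, `log(m/N)`) or `"literal"`
#'   (`log(N/m)`).
#' @return numeric vector of IDF scores.
#' @export
idf <- function(corpus, term, orientation = c("standard", "literal")) {
  orientation <- match.arg(orientation)
  miss <- setdiff(term, corpus$vocabulary)
  if (length(miss)) stop("term(s) not in vocabulary: ", paste(miss, collapse = ", "))
  cc <- corpus_counts(corpus)
  n <- cc$dfreq[match(term, cc$vocab)]
  if (orientation == "standard") log(corpus$m / n) else log(n / corpus$m)
}

#' Class probability of a term
#'
#' Estimated conditional probability P(term | class): the fraction of the
#' class's documents that contain the term (document-granularity estimator,
#' values in \[0, 1\]).  With `granularity = "token"` the estimate is the
#' term's share of the class's tokens instead.
#'
#' @inheritParams tf_corpus
#' @param class_k a class name from the corpus inventory.
#' @param granularity `"document"` (default) or `"token"`.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
class_probability <- function(corpus, term, class_k,
                              granularity = c("document", "token")) {
  granularity <- match.arg(granularity)
  miss <- setdiff(term, corpus$vocabulary)
  if (length(miss)) stop("term(s) not in vocabulary: ", paste(miss, collapse = ", "))
  if (!class_k %in% corpus$classes) stop("unknown class: ", class_k)
  n_k <- corpus$class_counts[[class_k]]
  if (n_k == 0L) stop("class has zero documents: ", class_k)
  in_class <- corpus$documents$label == class_k
  if (granularity == "document") {
    uniq <- lapply(corpus$documents$tokens[in_class], unique)
    cnt <- tabulate(factor(unlist(uniq, use.names = FALSE), levels = corpus$vocabulary),
                    nbins = length(corpus$vocabulary))
    cnt[match(term, corpus$vocabulary)] / n_k
  } else {
    toks <- unlist(corpus$documents$tokens[in_class], use.names = FALSE)
    if (!length(toks)) stop("class has zero tokens: ", class_k)
    cnt <- tabulate(factor(toks, levels = corpus$vocabulary),
                    nbins = length(corpus$vocabulary))
    cnt[match(term, corpus$vocabulary)] / length(toks)
  }
}

#' Reduce per-class CP values to one scalar per term
#'
#' The weighting step needs a single CP scalar per term; the reduction over
#' classes is `max` (strongest class affinity, the default) or `mean`.
#'
#' @param cp_by_class a numeric vector (one term's per-class CP values) or a
#'   terms-by-classes matrix.
#' @param rule `"max"` or `"mean"`.
#' @return a single number, or a vector with one entry per matrix row.
#' @export
reduce_cp <- function(cp_by_class, rule = c("max", "mean")) {
  rule <- match.arg(rule)
  f <- if (rule == "max") max else mean
  if (is.matrix(cp_by_class)) apply(cp_by_class, 1L, f) else f(cp_by_class)
}

#' Compute the full per-term weight triple
#'
#' Builds the TF, IDF and CP maps over the whole vocabulary in one pass,
#' plus the per-class CP matrix the reduction was taken over.  In a
#' train/test protocol this is computed on the training corpus only (CP uses
#' labels) and then applied to both splits.
#'
#' @param corpus a corpus object (typically the training split).
#' @param cp_rule class-reduction rule for CP, `"max"` (default) or `"mean"`.
#' @param idf_orientation see [idf()].
#' @param tf_estimator see [tf_corpus()].
#' @param cp_granularity see [class_probability()].
#' @return an object of class `"term_weights"` with fields `term`, `tf`,
#'   `idf`, `cp`, `cp_by_class`.
#' @export
compute_term_weights <- function(corpus, cp_rule = c("max", "mean"),
                                 idf_orientation = c("standard", "literal"),
                                 tf_estimator = c("global", "mean_doc"),
                                 cp_granularity = c("document", "token")) {
  cp_rule <- match.arg(cp_rule)
  idf_orientation <- match.arg(idf_orientation)
  tf_estimator <- match.arg(tf_estimator)
  cp_granularity <- match.arg(cp_granularity)
  if (!corpus$m) stop("empty corpus")
  cc <- corpus_counts(corpus)
  tf <- tf_from_counts(cc, corpus, tf_estimator)
  idf_v <- if (idf_orientation == "standard") log(corpus$m / cc$dfreq) else log(cc$dfreq / corpus$m)
  if (cp_granularity == "document") {
    cp_mat <- sweep(cc$class_df, 2L, as.numeric(corpus$class_counts), "/")
  } else {
    label <- corpus$documents$label
    cp_mat <- vapply(corpus$classes, function(k) {
      toks <- unlist(corpus$documents$tokens[label == k], use.names = FALSE)
      cnt <- tabulate(factor(toks, levels = cc$vocab), nbins = length(cc$vocab))
      if (length(toks)) cnt / length(toks) else rep(0, length(cc$vocab))
    }, numeric(length(cc$vocab)))
  }
  rownames(cp_mat) <- cc$vocab
  colnames(cp_mat) <- corpus$classes
  structure(list(
    term = cc$vocab,
    tf = stats::setNames(tf, cc$vocab),
    idf = stats::setNames(idf_v, cc$vocab),
    cp = stats::setNames(reduce_cp(cp_mat, cp_rule), cc$vocab),
    cp_by_class = cp_mat,
    reduction = cp_rule,
    m = corpus$m,
    settings = list(idf_orientation = idf_orientation, tf_estimator = tf_estimator,
                    cp_granularity = cp_granularity)
  ), class = "term_weights")
}

#' @export
print.term_weights <- function(x, ...) {
  cat(sprintf("<term_weights> %d terms over %d classes (cp reduction: %s)\n",
              length(x$term), ncol(x$cp_by_class), x$reduction))
  invisible(x)
}

#' @export
as.data.frame.term_weights <- function(x, ...) {
  data.frame(term = x$term, tf = unname(x$tf), idf = unname(x$idf),
             cp = unname(x$cp), stringsAsFactors = FALSE)
}

#' Serialize term weights to TSV
#'
#' Columns: term, tf, idf, cp, then one `cp.<class>` column per class.
#'
#' @param w a term_weights object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_term_weights <- function(w, path) {
  df <- as.data.frame(w)
  cpb <- as.data.frame(w$cp_by_class)
  names(cpb) <- paste0("cp.", colnames(w$cp_by_class))
  utils::write.table(cbind(df, cpb), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read term weights written by [write_term_weights()]
#'
#' @param path input file.
#' @return a term_weights object (reduction rule recorded as `"unknown"`).
#' @export
read_term_weights <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          fileEncoding = "UTF-8", check.names = FALSE)
  cp_cols <- grep("^cp\\.", names(df), value = TRUE)
  cp_mat <- as.matrix(df[cp_cols])
  rownames(cp_mat) <- df$term
  colnames(cp_mat) <- sub("^cp\\.", "", cp_cols)
  structure(list(
    term = df$term,
    tf = stats::setNames(df$tf, df$term),
    idf = stats::setNames(df$idf, df$term),
    cp = stats::setNames(df$cp, df$term),
    cp_by_class = cp_mat,
    reduction = "unknown",
    m = NA_integer_,
    settings = list()
  ), class = "term_weights")
}
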