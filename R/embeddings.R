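#' Load word vectors in word2vec text format
#'
#' Parses the standard `.vec` dialect: a header line `"<count> <dim>"`, then
#' one `"<token> v1 ... v_dim"` line per token.  Gzipped files are handled
#' transparently.  Malformed lines (wrong field count or non-numeric values)
#' raise an error naming the line; duplicate tokens keep the last occurrence
#' with a warning.
#'
#' @param path path to a `.vec` (optionally `.gz`) file.
#' @param expected_dim if given, the file's dimension must match.
#' @param oov_policy lookup behavior for out-of-vocabulary terms: `"zero"`
#'   (zero vector, the default), `"error"`, or `"hash"` (a deterministic
#'   pseudo-random vector derived from the term string).
#' @return an object of class `"embedding_table"`.
#' @export
load_word_vectors <- function(path, expected_dim = NULL,
                              oov_policy = c("zero", "error", "hash")) {
  oov_policy <- match.arg(oov_policy)
  con <- gzfile(path, "rt", encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) stop("empty word-vector file: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.integer(header)))) {
    stop("line 1: expected header '<count> <dim>', got: ", lines[1L])
  }
  n_declared <- as.integer(header[1L])
  dim <- as.integer(header[2L])
  if (!is.null(expected_dim) && dim != expected_dim) {
    stop(sprintf("embedding dimension %d does not match expected %d", dim, expected_dim))
  }
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "\\s+")
  nf <- lengths(parts)
  bad <- which(nf != dim + 1L)
  if (length(bad)) {
    stop(sprintf("line %d: expected %d fields (token + %d values), found %d",
                 bad[1L] + 1L, dim + 1L, dim, nf[bad[1L]]))
  }
  tokens <- vapply(parts, `[[`, character(1), 1L)
  # word2vec prints U+2212 for minus in some exports; normalize before parsing
  vals <- suppressWarnings(vapply(parts, function(p) {
    as.numeric(gsub("−", "-", p[-1L], fixed = TRUE))
  }, numeric(dim)))
  if (dim == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(apply(vals, 2L, anyNA))
  if (length(bad)) stop(sprintf("line %d: non-numeric vector value", bad[1L] + 1L))
  M <- t(vals)
  rownames(M) <- tokens
  if (length(tokens) != n_declared) {
    warning(sprintf("header declares %d vectors but %d were parsed",
                    n_declared, length(tokens)))
  }
  if (anyDuplicated(tokens)) {
    dup <- unique(tokens[duplicated(tokens)])
    warning("duplicate token(s), keeping last occurrence: ",
            paste(head(dup, 5), collapse = ", "))
    keep <- !duplicated(tokens, fromLast = TRUE)
    M <- M[keep, , drop = FALSE]
  }
  new_embedding_table(dim, M, oov_policy)
}

new_embedding_table <- function(dim, vectors, oov_policy = "zero", hash_seed = 0L) {
  structure(list(dim = as.integer(dim), vectors = vectors,
                 oov_policy = oov_policy, hash_seed = as.integer(hash_seed)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<%s> %d terms, dim %d, oov policy '%s'%s\n",
              class(x)[1L], nrow(x$vectors), x$dim, x$oov_policy,
              if (!is.null(x$scheme)) paste0(", scheme '", x$scheme, "'") else ""))
  invisible(x)
}

#' Write word vectors in word2vec text format
#'
#' Values are serialized with 6 decimals, matching common `.vec` exports.
#' A `.gz` suffix triggers gzip compression.
#'
#' @param table an embedding_table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_word_vectors <- function(table, path) {
  M <- table$vectors
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(M), table$dim), con)
  if (nrow(M)) {
    body <- vapply(seq_len(nrow(M)), function(i) {
      paste(rownames(M)[i], paste(sprintf("%.6f", M[i, ]), collapse = " "))
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

# 31-bit string hash; pure function of the term string.
string_hash <- function(term) {
  p <- 2147480009  # prime below 2^31
  h <- 0
  for (v in utf8ToInt(term)) h <- (h * 131 + v) %% p
  as.integer(h)
}

term_seed <- function(term, seed) {
  p <- 2147480009
  as.integer((string_hash(term) + (seed %% p) * 7919) %% p)
}

#' Deterministic synthetic embedding table
#'
#' Each term's vector is a pure function of the term string and the seed
#' (standard-normal entries), so the table is independent of vocabulary
#' order and reproducible across sessions.  Intended as a test stand-in for
#' a pretrained table.
#'
#' @param vocab character vector of terms (may be empty).
#' @param dim embedding dimension (default 100).
#' @param seed integer seed.
#' @param oov_policy see [load_word_vectors()].
#' @return an embedding_table.
#' @export
synthetic_embeddings <- function(vocab, dim = 100L, seed = 1L,
                                 oov_policy = c("zero", "error", "hash")) {
  oov_policy <- match.arg(oov_policy)
  stopifnot(dim >= 1L)
  vocab <- as.character(vocab)
  M <- matrix(0, nrow = length(vocab), ncol = dim,
              dimnames = list(vocab, NULL))
  if (length(vocab)) {
    rows <- withr::with_preserve_seed({
      lapply(vocab, function(term) {
        set.seed(term_seed(term, seed))
        rnorm(dim)
      })
    })
    M <- do.call(rbind, rows)
    rownames(M) <- vocab
  }
  new_embedding_table(dim, M, oov_policy, hash_seed = seed)
}

#' Look up term vectors
#'
#' In-vocabulary terms return their stored vectors; out-of-vocabulary terms
#' follow the table's `oov_policy` (zero vector, error naming the term, or a
#' deterministic hash-seeded vector).
#'
#' @param table an embedding_table.
#' @param term character vector of terms.
#' @return a numeric vector (single term) or a terms-by-dim matrix.
#' @export
lookup <- function(table, term) {
  idx <- match(term, rownames(table$vectors))
  out <- matrix(0, nrow = length(term), ncol = table$dim,
                dimnames = list(term, NULL))
  hit <- !is.na(idx)
  out[hit, ] <- table$vectors[idx[hit], , drop = FALSE]
  if (any(!hit)) {
    oov <- term[!hit]
    if (table$oov_policy == "error") {
      stop("out-of-vocabulary term(s): ", paste(head(oov, 5), collapse = ", "))
    }
    if (table$oov_policy == "hash") {
      out[!hit, ] <- withr::with_preserve_seed({
        do.call(rbind, lapply(oov, function(t) {
          set.seed(term_seed(t, table$hash_seed))
          rnorm(table$dim)
        }))
      })
    }
  }
  if (length(term) == 1L) drop(out) else out
}
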