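#' Scale an embedding table by per-term statistical weights
#'
#' Produces one weighted feature table: every term's vector is multiplied
#' element-wise by its scalar weight under the chosen scheme — `"tf"` (HTF),
#' `"idf"` (HIDF) or `"cp"` (HCP) — while `"baseline"` returns the table
#' unmodified.  Terms present in the base table but absent from the weight
#' maps (e.g. seen only outside the training split) receive
#' `missing_weight`, 0 by default, so they carry no evidence.
#'
#' @param base an embedding_table.
#' @param w a term_weights object covering the vocabulary of interest.
#' @param scheme one of `"baseline"`, `"tf"`, `"idf"`, `"cp"`.
#' @param missing_weight weight for terms without a computed score.
#' @return a `"weighted_embedding_table"` (also an embedding_table).
#' @export
weight_table <- function(base, w, scheme = c("baseline", "tf", "idf", "cp"),
                         missing_weight = 0) {
  scheme <- match.arg(scheme)
  out <- base
  if (scheme != "baseline") {
    s <- w[[scheme]][match(rownames(base$vectors), w$term)]
    s[is.na(s)] <- missing_weight
    out$vectors <- base$vectors * s
  }
  out$scheme <- scheme
  class(out) <- c("weighted_embedding_table", "embedding_table")
  out
}

#' All four feature tables at once
#'
#' @inheritParams weight_table
#' @return named list of weighted_embedding_tables for schemes `baseline`,
#'   `tf`, `idf`, `cp`, sharing dimension and vocabulary.
#' @export
weight_all_schemes <- function(base, w, missing_weight = 0) {
  schemes <- c("baseline", "tf", "idf", "cp")
  stats::setNames(lapply(schemes, function(s) {
    weight_table(base, w, s, missing_weight)
  }), schemes)
}
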