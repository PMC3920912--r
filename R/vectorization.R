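#' BM25 parameters
#'
#' Okapi BM25 weighting constants: `k1` controls term-frequency saturation
#' (weight approaches `idf * (k1 + 1)` as tf grows) and `b` in \[0, 1\]
#' controls document-length normalization (0 = none, 1 = full). The classic
#' Okapi defaults `k1 = 1.2`, `b = 0.75` are used; the exact BM25 variant is
#' recorded in the output metadata of [vectorize_corpus()].
#'
#' @param k1 saturation constant, > 0.
#' @param b length-normalization constant in \[0, 1\].
#' @return list of class `bm25_params`.
#' @export
bm25_params <- function(k1 = 1.2, b = 0.75) {
  stopifnot(is.numeric(k1), length(k1) == 1, k1 > 0,
            is.numeric(b), length(b) == 1, b >= 0, b <= 1)
  structure(list(k1 = k1, b = b), class = "bm25_params")
}

#' BM25 term weight
#'
#' `idf(df, n_docs) * tf * (k1 + 1) / (tf + k1 * (1 - b + b * doc_len / avg_len))`
#' with `idf = max(0, log((n_docs - df + 0.5) / (df + 0.5)))`. The idf is
#' floored at zero so weights are nonnegative, keeping cosine similarities of
#' weighted vectors in \[0, 1\] — the property the neighbour-graph weights
#' rely on.
#'
#' @param tf term count in the document (vectorized).
#' @param df number of documents containing the term.
#' @param n_docs corpus size.
#' @param doc_len token count of the document.
#' @param avg_len average token count over the corpus, > 0.
#' @param params a [bm25_params()] object.
#' @return nonnegative weight(s).
#' @examples
#' bm25_weight(2, 1, 10, 100, 100)  # frequent rare term
#' @export
bm25_weight <- function(tf, df, n_docs, doc_len, avg_len,
                        params = bm25_params()) {
  stopifnot(inherits(params, "bm25_params"))
  if (!is.numeric(avg_len) || any(avg_len <= 0)) {
    stop("avg_len must be positive", call. = FALSE)
  }
  if (any(tf >= 1 & df < 1)) {
    stop("df must be >= 1 whenever tf >= 1", call. = FALSE)
  }
  idf <- pmax(0, log((n_docs - df + 0.5) / (df + 0.5)))
  sat <- tf * (params$k1 + 1) /
    (tf + params$k1 * (1 - params$b + params$b * doc_len / avg_len))
  out <- idf * sat
  out[tf == 0] <- 0
  out
}

#' BM25-weight and L2-normalize a token-count corpus
#'
#' Takes a long table of token counts, applies [bm25_weight()] per
#' (document, term) cell, and L2-normalizes each document vector so that the
#' dot product of two rows is their cosine similarity. The vocabulary is the
#' terms in order of first appearance, persisted as column names.
#'
#' @param token_counts data frame with columns `doc_id`, `term`, `count`
#'   (one row per document-term pair, counts >= 0).
#' @param params a [bm25_params()] object.
#' @return sparse feature matrix (`dgCMatrix`) with docs in rows (ordered by
#'   first appearance of `doc_id`), terms in columns; every nonzero row has
#'   unit Euclidean norm. Attribute `"weighting"` records the variant and
#'   constants used.
#' @export
vectorize_corpus <- function(token_counts, params = bm25_params()) {
  stopifnot(is.data.frame(token_counts),
            all(c("doc_id", "term", "count") %in% names(token_counts)))
  tc <- dplyr::filter(token_counts, .data$count > 0)
  if (!nrow(tc)) stop("corpus has no document with a token", call. = FALSE)
  docs <- unique(token_counts$doc_id)
  terms <- unique(tc$term)
  i <- match(tc$doc_id, docs)
  j <- match(tc$term, terms)
  n_docs <- length(docs)
  doc_len <- as.numeric(tapply(tc$count, factor(i, levels = seq_len(n_docs)),
                               sum, default = 0))
  avg_len <- mean(doc_len[doc_len > 0])
  df_term <- as.numeric(table(factor(j, levels = seq_along(terms))))
  w <- bm25_weight(tc$count, df_term[j], n_docs, doc_len[i], avg_len, params)
  X <- Matrix::sparseMatrix(i = i, j = j, x = w,
                            dims = c(n_docs, length(terms)),
                            dimnames = list(as.character(docs), terms))
  zero <- Matrix::rowSums(X^2) == 0
  if (any(zero)) {
    warning(sum(zero), " document(s) have an all-zero vector after weighting",
            call. = FALSE)
  }
  X <- normalize_rows(X)
  dimnames(X) <- list(as.character(docs), terms)
  attr(X, "weighting") <- list(scheme = "okapi-bm25", k1 = params$k1,
                               b = params$b, idf = "floored-okapi",
                               norm = "l2")
  X
}
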