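#' Weighted kNN label score
#'
#' The weighted vote of a document's k nearest neighbours for one label:
#' `S(d, cl) = sum_{d' in kNN(d)} w(d, d') I(d', cl) / sum_{d' in kNN(d)} w(d, d')`
#' where `I(d', cl)` indicates that neighbour `d'` carries label `cl`. With
#' nonnegative weights the score is a convex combination of the neighbours'
#' memberships, hence in \[0, 1\]. If all neighbour weights are zero the
#' score is defined as 0 (with a warning).
#'
#' @param d document index (1-based).
#' @param cl label index (1-based).
#' @param graph a [build_graph()] result.
#' @param Y binary label matrix (or `multilabel_dataset`) supplying the
#'   neighbours' memberships.
#' @return score in \[0, 1\].
#' @examples
#' ds <- generate_multilabel(synthetic_spec(n_docs = 30, n_labels = 3,
#'                                          n_features = 10, seed = 2))
#' g <- build_graph(ds$X, k = 5)
#' wknn_score(1, 1, g, ds$Y)
#' @export
wknn_score <- function(d, cl, graph, Y) {
  if (inherits(Y, "multilabel_dataset")) Y <- Y$Y
  stopifnot(inherits(graph, "neighbor_graph"),
            d >= 1, d <= graph$n, cl >= 1, cl <= ncol(Y))
  wts <- graph$w[d, ]
  denom <- sum(wts)
  if (denom <= 0) {
    warning("all neighbour weights of document ", d,
            " are zero; score defined as 0", call. = FALSE)
    return(0)
  }
  memb <- as.numeric(Y[graph$idx[d, ], cl])
  sum(wts * memb) / denom
}

#' All WkNN label scores
#'
#' Vectorized [wknn_score()] over every (document, label) cell.
#'
#' @inheritParams wknn_score
#' @return dense `n x m` numeric matrix of scores.
#' @export
wknn_score_matrix <- function(graph, Y) {
  if (inherits(Y, "multilabel_dataset")) Y <- Y$Y
  stopifnot(inherits(graph, "neighbor_graph"), graph$n == nrow(Y))
  denom <- rowSums(graph$w)
  zero <- denom <= 0
  if (any(zero)) {
    warning(sum(zero), " document(s) have all-zero neighbour weights; ",
            "their scores are defined as 0", call. = FALSE)
  }
  S <- matrix(0, graph$n, ncol(Y))
  Yd <- as.matrix(Y)
  for (i in which(!zero)) {
    S[i, ] <- (graph$w[i, ] %*% Yd[graph$idx[i, ], , drop = FALSE]) / denom[i]
  }
  colnames(S) <- colnames(Y)
  S
}

#' Restore missing labels by weighted kNN voting
#'
#' Scores every (document, label) combination with [wknn_score()] over the
#' training set and proposes as missing every pair that is not already
#' labeled and whose score reaches the threshold `T`. The default vote
#' weight is cosine similarity (larger = closer); `weight =
#' "inverse-distance"` uses `1 / (1 - sim + eps)` for the literal
#' distance-as-weight reading.
#'
#' @param X feature matrix or `multilabel_dataset` (training set only; test
#'   documents are never consulted).
#' @param Y binary training label matrix (ignored if `X` is a
#'   `multilabel_dataset`).
#' @param k number of neighbours.
#' @param T acceptance threshold in \[0, 1\]; a pair is proposed when
#'   `S(d, cl) >= T`.
#' @param weight `"similarity"` (default) or `"inverse-distance"`.
#' @param graph optional prebuilt [build_graph()] result (overrides `k`).
#' @return tibble of class `relevance_pairs` with columns `doc`, `label`
#'   (1-based) and `score`, sorted by descending score; only pairs with
#'   `Y[doc, label] == 0` appear.
#' @examples
#' ds <- generate_multilabel(synthetic_spec(n_docs = 60, n_labels = 4,
#'                                          n_features = 20, seed = 5))
#' corr <- delete_labels(ds$Y, p = 0.3, seed = 9)
#' restore_wknn(ds$X, corr$Y_incomplete, k = 10, T = 0.3)
#' @export
restore_wknn <- function(X, Y = NULL, k = 10, T = 0.3,
                         weight = c("similarity", "inverse-distance"),
                         graph = NULL) {
  weight <- match.arg(weight)
  if (inherits(X, "multilabel_dataset")) {
    Y <- X$Y
    X <- X$X
  }
  stopifnot(!is.null(Y), T >= 0)
  Y <- as_sparse_numeric(Y, "Y")
  if (is.null(graph)) graph <- build_graph(X, k)
  if (weight == "inverse-distance") {
    graph$w <- 1 / (1 - graph$w + 1e-6)
  }
  S <- wknn_score_matrix(graph, Y)
  keep <- which(S >= T & as.matrix(Y) == 0, arr.ind = TRUE)
  pairs <- tibble::tibble(
    doc = as.integer(keep[, 1]),
    label = as.integer(keep[, 2]),
    score = S[keep]
  )
  pairs <- dplyr::arrange(pairs, dplyr::desc(.data$score), .data$doc,
                          .data$label)
  class(pairs) <- c("relevance_pairs", class(pairs))
  pairs
}
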