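#' Cosine similarity of two vectors
#'
#' `sum(x * y) / (||x|| ||y||)`; defined as 0 when either vector is zero.
#' For nonnegative vectors the value lies in \[0, 1\].
#'
#' @param x,y numeric vectors of equal length.
#' @return a single similarity value.
#' @examples
#' cosine_sim(c(1, 1, 0), c(1, 0, 0))  # 1 / sqrt(2)
#' @export
cosine_sim <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' Build the k-nearest-neighbour similarity graph
#'
#' The shared substrate of both label-restoration algorithms: a directed
#' graph in which each document points to its `k` most cosine-similar other
#' documents, edge weight = the similarity. Exact search (full pairwise
#' similarity); ties in similarity are broken by ascending document index so
#' the graph is reproducible across runs and platforms. Self-edges are
#' excluded — a document never votes for its own labels.
#'
#' @param X feature matrix (rows = documents) or a `multilabel_dataset`.
#' @param k number of neighbours per document (clamped to the pool size with
#'   a warning if too large).
#' @param candidates optional integer vector: only these documents may serve
#'   as neighbours (used by the experiment pipeline to keep the development
#'   split out of the voting pool). Default: all documents.
#' @return object of class `neighbor_graph`: list with `k`, `n`, integer
#'   matrix `idx` (`n x k`, neighbour ids by descending similarity) and
#'   numeric matrix `w` (matching similarities).
#' @export
build_graph <- function(X, k, candidates = NULL) {
  if (inherits(X, "multilabel_dataset")) X <- X$X
  X <- as_sparse_numeric(X, "X")
  n <- nrow(X)
  candidates <- sort(unique(as.integer(candidates %||% seq_len(n))))
  stopifnot(k >= 1, n >= 2, all(candidates >= 1), all(candidates <= n),
            length(candidates) >= 2)
  kmax <- length(candidates) - 1L  # a doc cannot be its own neighbour
  if (k > kmax) {
    warning("k = ", k, " exceeds the neighbour pool; clamped to ", kmax,
            call. = FALSE)
    k <- kmax
  }
  nrm <- sqrt(Matrix::rowSums(X^2))
  Xn <- Matrix::Diagonal(x = ifelse(nrm > 0, 1 / nrm, 0)) %*% X
  S <- as.matrix(Matrix::tcrossprod(Xn[, , drop = FALSE],
                                    Xn[candidates, , drop = FALSE]))
  idx <- matrix(0L, n, k)
  w <- matrix(0, n, k)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[candidates == i] <- -Inf
    # order by descending similarity, ties by ascending document index
    o <- order(-s, candidates)
    o <- o[seq_len(k)]
    idx[i, ] <- candidates[o]
    w[i, ] <- S[i, o]
  }
  structure(list(k = as.integer(k), n = n, idx = idx, w = w),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("<neighbor_graph> ", x$n, " nodes, k = ", x$k,
      ", mean edge weight ", round(mean(x$w), 4), "\n", sep = "")
  invisible(x)
}

#' Edge list of a neighbour graph
#'
#' @param graph a [build_graph()] result.
#' @return tibble with columns `from`, `to`, `weight` (directed edges,
#'   neighbours in rank order within each `from`).
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  tibble::tibble(
    from = rep(seq_len(graph$n), each = graph$k),
    to = as.integer(t(graph$idx)),
    weight = as.numeric(t(graph$w))
  )
}
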