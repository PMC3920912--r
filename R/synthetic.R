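#' Synthetic multilabel dataset specification
#'
#' Describes a cluster-per-label generative model that embodies the
#' compactness hypothesis (similar objects tend to share labels): each label
#' owns a cluster center in a nonnegative feature space; a document's vector
#' sits at the normalized mean of its labels' centers plus isotropic
#' nonnegative noise, so documents sharing labels are close in cosine
#' similarity. Extra labels are drawn from the clusters geometrically
#' nearest the primary one, making co-occurring labels adjacent — exactly
#' the regime in which neighbourhood-based label restoration is learnable.
#'
#' The defaults (600 documents, 8 labels, 50 features, `co_label_rate` 0.6
#' over the `q = 5` nearest clusters, hence `1 + 5 * 0.6 = 4` expected
#' labels per document) mimic a Yeast-benchmark-like density of about 4
#' labels per object.
#'
#' @param n_docs number of documents.
#' @param n_labels number of labels (>= 2), one cluster each.
#' @param n_features dimensionality of the feature space.
#' @param spread within-cluster standard deviation (>= 0) of the isotropic
#'   noise, on the unit-sphere scale of the normalized centers.
#' @param co_label_rate probability, per nearby cluster, that the document
#'   also receives that cluster's label.
#' @param q number of nearest other clusters eligible as co-labels.
#' @param cluster_centers optional `n_labels x n_features` nonnegative
#'   matrix of centers; by default centers give each label a dedicated block
#'   of features plus a small shared background, then are L2-normalized.
#' @param seed RNG seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_docs = 600, n_labels = 8, n_features = 50,
                           spread = 0.15, co_label_rate = 0.6, q = 5,
                           cluster_centers = NULL, seed = 1L) {
  stopifnot(n_docs >= 1, n_labels >= 2, n_features >= 2,
            spread >= 0, co_label_rate >= 0, co_label_rate <= 1, q >= 0)
  q <- min(q, n_labels - 1)
  if (n_labels > n_docs) {
    stop("validation error: cannot guarantee a document per label with ",
         "n_labels > n_docs", call. = FALSE)
  }
  if (!is.null(cluster_centers)) {
    stopifnot(is.matrix(cluster_centers),
              nrow(cluster_centers) == n_labels,
              ncol(cluster_centers) == n_features,
              all(cluster_centers >= 0))
  }
  structure(
    list(n_docs = n_docs, n_labels = n_labels, n_features = n_features,
         spread = spread, co_label_rate = co_label_rate, q = q,
         cluster_centers = cluster_centers, seed = seed),
    class = "synthetic_spec"
  )
}

default_centers <- function(n_labels, n_features) {
  # one dominant feature block per label + weak shared background, so
  # distinct clusters are well separated (pairwise cosine well below 1)
  C <- matrix(0.05, n_labels, n_features)
  block <- floor(n_features / n_labels)
  for (l in seq_len(n_labels)) {
    lo <- (l - 1) * block + 1
    hi <- if (l == n_labels) n_features else l * block
    C[l, lo:hi] <- 1 + stats::runif(hi - lo + 1)
  }
  C / sqrt(rowSums(C^2))
}

#' Generate a synthetic multilabel dataset
#'
#' Draws documents from the model described in [synthetic_spec()]: a primary
#' label uniformly at random, each of the `q` nearest other clusters added
#' with probability `co_label_rate`, the feature vector placed at the
#' normalized mean of the assigned labels' centers with
#' `abs(N(0, spread^2))` noise, then L2-normalized (matching the geometry of
#' BM25 text vectors: nonnegative, unit norm). Deterministic given the spec's
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @return a [multilabel_dataset] with `n_docs` rows; every row has at least
#'   one label.
#' @examples
#' ds <- generate_multilabel(synthetic_spec(n_docs = 50, n_labels = 4,
#'                                          n_features = 20, seed = 3))
#' label_stats(ds)
#' @export
generate_multilabel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    C <- spec$cluster_centers %||%
      default_centers(spec$n_labels, spec$n_features)
    C <- C / pmax(sqrt(rowSums(C^2)), .Machine$double.eps)
    # center adjacency by cosine similarity, ties by ascending index
    csim <- tcrossprod(C)
    near <- lapply(seq_len(spec$n_labels), function(l) {
      o <- order(-csim[l, -l])
      setdiff(seq_len(spec$n_labels), l)[o][seq_len(spec$q)]
    })
    Y <- matrix(0, spec$n_docs, spec$n_labels)
    primary <- sample.int(spec$n_labels, spec$n_docs, replace = TRUE)
    for (d in seq_len(spec$n_docs)) {
      Y[d, primary[d]] <- 1
      if (spec$q > 0 && spec$co_label_rate > 0) {
        extra <- near[[primary[d]]][
          stats::runif(spec$q) < spec$co_label_rate]
        Y[d, extra] <- 1
      }
    }
    centers <- Y %*% C / rowSums(Y)
    noise <- abs(matrix(stats::rnorm(spec$n_docs * spec$n_features,
                                     sd = spec$spread),
                        spec$n_docs, spec$n_features))
    if (spec$spread == 0) noise[] <- 0
    X <- normalize_rows(centers + noise)
  })
  multilabel_dataset(X, Y,
                     label_names = paste0("label_", seq_len(spec$n_labels)),
                     feature_names = paste0("f", seq_len(spec$n_features)))
}
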