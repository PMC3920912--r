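#' Multilabel dataset container
#'
#' Bundles a feature matrix `X` (documents in rows, nonnegative feature
#' weights in columns) with a binary label matrix `Y` (documents by
#' categories). Both are stored as sparse [Matrix::Matrix] objects; density is
#' never assumed. Rows of `X` are typically L2-normalized (see
#' [normalize_rows()] and [vectorize_corpus()]), which puts all pairwise
#' cosine similarities in \[0, 1\].
#'
#' A *training* label matrix must have at least one positive label per row:
#' the whole restoration machinery assumes every training document carries
#' some expert label (only missing labels occur, never spurious ones). Rows
#' with no labels are legal in a test-role matrix (prediction targets).
#'
#' @param X numeric matrix or sparse Matrix, `n_docs x n_features`, finite
#'   and nonnegative values.
#' @param Y binary matrix or sparse Matrix, `n_docs x n_labels`, entries in
#'   `{0, 1}`.
#' @param label_names character vector of label names; defaults to
#'   `colnames(Y)` or `"label_1" ...`.
#' @param feature_names character vector of feature names; defaults to
#'   `colnames(X)` or `"f1" ...`.
#' @param role `"train"` (every row must have >= 1 label) or `"test"`
#'   (empty label rows allowed).
#' @return An object of class `multilabel_dataset`: a list with elements
#'   `X` (`dgCMatrix`), `Y` (`dgCMatrix`), `label_names`, `feature_names`,
#'   `role`.
#' @examples
#' X <- matrix(runif(12), 4, 3)
#' Y <- matrix(c(1, 0, 1, 1, 0, 1, 1, 0), 4, 2)
#' ds <- multilabel_dataset(X, Y)
#' label_stats(ds)
#' @export
multilabel_dataset <- function(X, Y, label_names = NULL, feature_names = NULL,
                               role = c("train", "test")) {
  role <- match.arg(role)
  X <- as_sparse_numeric(X, "X")
  Y <- as_sparse_numeric(Y, "Y")
  if (nrow(X) != nrow(Y)) {
    stop("X and Y must have the same number of rows (documents): ",
         nrow(X), " vs ", nrow(Y), call. = FALSE)
  }
  if (nrow(X) < 1L || ncol(X) < 1L) {
    stop("X must have at least one document and one feature", call. = FALSE)
  }
  if (!all(is.finite(X@x))) stop("X contains non-finite values", call. = FALSE)
  if (length(Y@x) && !all(Y@x %in% c(0, 1))) {
    stop("Y entries must be 0 or 1", call. = FALSE)
  }
  Y <- Matrix::drop0(Y)
  if (is.null(label_names)) {
    label_names <- colnames(Y) %||% paste0("label_", seq_len(ncol(Y)))
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  }
  stopifnot(length(label_names) == ncol(Y),
            length(feature_names) == ncol(X))
  colnames(Y) <- label_names
  colnames(X) <- feature_names
  if (role == "train") assert_training_labels(Y)
  structure(
    list(X = X, Y = Y, label_names = label_names,
         feature_names = feature_names, role = role),
    class = "multilabel_dataset"
  )
}

as_sparse_numeric <- function(M, what) {
  if (inherits(M, "sparseMatrix")) {
    M <- methods::as(methods::as(M, "generalMatrix"), "CsparseMatrix")
    M <- methods::as(M, "dMatrix")
  } else if (is.matrix(M) || is.data.frame(M)) {
    M <- Matrix::Matrix(as.matrix(M), sparse = TRUE)
    M <- methods::as(methods::as(M, "generalMatrix"), "CsparseMatrix")
  } else {
    stop(what, " must be a matrix or sparse Matrix", call. = FALSE)
  }
  M
}

assert_training_labels <- function(Y) {
  rs <- Matrix::rowSums(Y)
  if (any(rs == 0)) {
    bad <- which(rs == 0)
    stop("training label matrix has ", length(bad),
         " row(s) with zero labels (first: row ", bad[1],
         "); every training document must carry at least one label",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.multilabel_dataset <- function(x, ...) {
  cat("<multilabel_dataset> ", nrow(x$X), " docs, ", ncol(x$X),
      " features, ", ncol(x$Y), " labels (role: ", x$role, ")\n", sep = "")
  st <- label_stats(x)
  cat("  positives: ", st$n_positives,
      "; labels/doc: ", round(st$labels_per_doc, 3),
      "; docs/label: ", round(st$docs_per_label, 3), "\n", sep = "")
  invisible(x)
}

#' L2-normalize the rows of a feature matrix
#'
#' Every nonzero row is scaled to unit Euclidean norm; zero rows are left
#' untouched. Applied after weighting so that similarity between documents is
#' the cosine of their feature vectors.
#'
#' @param X matrix or sparse Matrix.
#' @return sparse Matrix of the same shape with unit-norm nonzero rows.
#' @export
normalize_rows <- function(X) {
  X <- as_sparse_numeric(X, "X")
  nrm <- sqrt(Matrix::rowSums(X^2))
  scale <- ifelse(nrm > 0, 1 / nrm, 0)
  Matrix::Diagonal(x = scale) %*% X
}

#' Label-matrix summary statistics
#'
#' Average number of labels per document and documents per label, the two
#' quantities used to characterize how densely a collection is annotated and
#' how much a modification step enriched it.
#'
#' @param Y a `multilabel_dataset` or a binary label matrix.
#' @return A one-row tibble with columns `n_docs`, `n_labels`, `n_positives`,
#'   `labels_per_doc` (= positives / docs) and `docs_per_label`
#'   (= positives / labels).
#' @export
label_stats <- function(Y) {
  if (inherits(Y, "multilabel_dataset")) Y <- Y$Y
  Y <- as_sparse_numeric(Y, "Y")
  tot <- sum(Y)
  tibble::tibble(
    n_docs = nrow(Y),
    n_labels = ncol(Y),
    n_positives = as.integer(tot),
    labels_per_doc = tot / nrow(Y),
    docs_per_label = tot / ncol(Y)
  )
}

#' Split a dataset into train / dev / test index sets
#'
#' Indices are drawn without replacement and are pairwise disjoint. The dev
#' set is carved from the training portion (the protocol used by the
#' experiment pipeline: 20% of the training documents by default).
#'
#' @param n_docs total number of documents.
#' @param test_fraction fraction held out as the test set.
#' @param dev_fraction fraction *of the training portion* used as the
#'   development (validation) set; 0 for none.
#' @param seed RNG seed; the split is deterministic given `(n_docs, fractions,
#'   seed)`.
#' @return list with integer vectors `train`, `dev`, `test` (1-based).
#' @export
split_dataset <- function(n_docs, test_fraction = 1 / 3, dev_fraction = 0.2,
                          seed = 1L) {
  stopifnot(n_docs >= 2, test_fraction >= 0, test_fraction < 1,
            dev_fraction >= 0, dev_fraction <= 0.5)
  withr::with_seed(seed, {
    perm <- sample.int(n_docs)
    n_test <- floor(test_fraction * n_docs)
    test <- sort(perm[seq_len(n_test)])
    train_all <- sort(perm[setdiff(seq_len(n_docs), seq_len(n_test))])
    n_dev <- floor(dev_fraction * length(train_all))
    dev_pick <- sample(seq_along(train_all), n_dev)
    dev <- train_all[sort(dev_pick)]
    train <- setdiff(train_all, dev)
  })
  list(train = train, dev = dev, test = test)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

subset_dataset <- function(ds, idx, role = ds$role) {
  multilabel_dataset(ds$X[idx, , drop = FALSE], ds$Y[idx, , drop = FALSE],
                     label_names = ds$label_names,
                     feature_names = ds$feature_names, role = role)
}
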