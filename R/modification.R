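#' Add restored pairs to the training labels
#'
#' "add" mode of training-set modification: the proposed (document, label)
#' pairs become positives (elementwise OR with the existing matrix). Pairs
#' already positive change nothing, so the operation is idempotent and never
#' removes an expert-assigned label.
#'
#' @param Y binary label matrix or `multilabel_dataset`.
#' @param pairs a `relevance_pairs` tibble (columns `doc`, `label`) from
#'   [restore_wknn()] / [restore_softsl()], or any data frame with those
#'   columns.
#' @return label matrix of the same shape with `Y' >= Y` elementwise.
#' @export
apply_add <- function(Y, pairs) {
  if (inherits(Y, "multilabel_dataset")) Y <- Y$Y
  Y <- as_sparse_numeric(Y, "Y")
  pairs <- validate_pairs(pairs, nrow(Y), ncol(Y))
  if (!nrow(pairs)) return(Y)
  add <- Matrix::sparseMatrix(i = pairs$doc, j = pairs$label, x = 1,
                              dims = dim(Y))
  out <- Y + add
  out@x <- pmin(out@x, 1)
  dimnames(out) <- dimnames(Y)
  Matrix::drop0(out)
}

#' Build a del-mode negative-example mask
#'
#' "del" mode of training-set modification: instead of adding the restored
#' pairs as positives, the documents of each proposed pair are excluded from
#' that label's *negative* examples during per-label Binary-Relevance
#' training. The label matrix itself is unchanged — expert positives are
#' never touched, and pairs that are already positive need no exclusion.
#'
#' @inheritParams apply_add
#' @return object of class `negative_mask`: a list, one element per label,
#'   of document indices to drop from that label's negatives (possibly
#'   empty).
#' @export
apply_del <- function(Y, pairs) {
  if (inherits(Y, "multilabel_dataset")) Y <- Y$Y
  Y <- as_sparse_numeric(Y, "Y")
  pairs <- validate_pairs(pairs, nrow(Y), ncol(Y))
  mask <- rep(list(integer(0)), ncol(Y))
  names(mask) <- colnames(Y) %||% paste0("label_", seq_len(ncol(Y)))
  if (nrow(pairs)) {
    is_neg <- as.numeric(Y[cbind(pairs$doc, pairs$label)]) == 0
    pairs <- pairs[is_neg, , drop = FALSE]
    sp <- split(pairs$doc, factor(pairs$label, levels = seq_len(ncol(Y))))
    mask <- lapply(sp, function(d) sort(unique(as.integer(d))))
    names(mask) <- colnames(Y) %||% paste0("label_", seq_len(ncol(Y)))
  }
  structure(mask, class = "negative_mask")
}

validate_pairs <- function(pairs, n, m) {
  stopifnot(is.data.frame(pairs), all(c("doc", "label") %in% names(pairs)))
  if (nrow(pairs)) {
    if (any(pairs$doc < 1 | pairs$doc > n)) {
      stop("doc index out of range in pairs", call. = FALSE)
    }
    if (any(pairs$label < 1 | pairs$label > m)) {
      stop("label index out of range in pairs", call. = FALSE)
    }
  }
  dplyr::distinct(tibble::as_tibble(pairs[c("doc", "label")]))
}

#' Restore-and-modify in one step
#'
#' Convenience wrapper running a restorer and applying the chosen
#' modification mode to a training dataset.
#'
#' @param ds a training [multilabel_dataset].
#' @param restorer `"wknn"`, `"softsl"`, or `"none"`.
#' @param mode `"add"`, `"del"`, or `"none"`.
#' @param ... passed to [restore_wknn()] (e.g. `k`, `T`) or the `params`
#'   argument of [restore_softsl()].
#' @return list with `ds` (dataset with modified `Y` in add mode), `mask`
#'   (a `negative_mask` in del mode, else `NULL`) and `pairs` (the
#'   proposals).
#' @export
modify_training_set <- function(ds, restorer = c("wknn", "softsl", "none"),
                                mode = c("add", "del", "none"), ...) {
  restorer <- match.arg(restorer)
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "multilabel_dataset"))
  if (restorer == "none" || mode == "none") {
    return(list(ds = ds, mask = NULL,
                pairs = tibble::tibble(doc = integer(0), label = integer(0),
                                       score = numeric(0))))
  }
  pairs <- switch(restorer,
    wknn = restore_wknn(ds, ...),
    softsl = restore_softsl(ds, ...)
  )
  if (mode == "add") {
    ds2 <- multilabel_dataset(ds$X, apply_add(ds$Y, pairs),
                              label_names = ds$label_names,
                              feature_names = ds$feature_names)
    list(ds = ds2, mask = NULL, pairs = pairs)
  } else {
    list(ds = ds, mask = apply_del(ds$Y, pairs), pairs = pairs)
  }
}
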