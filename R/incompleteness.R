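#' Simulate an incompletely labeled training set
#'
#' Deletes a controlled fraction `p` of the positive labels of each class
#' from a completely labeled matrix, modelling a training set whose
#' annotators missed labels. Two constraints are honoured, mirroring how the
#' incomplete-set model is defined:
#'
#' * per class, the number of deleted positives is `round(p * positives)`
#'   (`floor`/`ceiling` selectable), so the class-size distribution of the
#'   labels is preserved;
#' * every document keeps at least one label (a deletion that would empty a
#'   row is skipped and counted as a shortfall, never redistributed to other
#'   classes).
#'
#' Classes are visited in a seeded random order and candidate positives are
#' sampled uniformly without replacement within each class, so the procedure
#' is deterministic given `(Y, p, seed)`.
#'
#' @param Y a `multilabel_dataset` or binary label matrix; every row must
#'   have at least one positive.
#' @param p fraction of labels to delete per class, in `[0, 1)`.
#' @param seed RNG seed.
#' @param rounding how to turn `p * positives` into a count: `"round"`
#'   (half-up), `"floor"`, or `"ceiling"`.
#' @return list with:
#'   * `Y_incomplete`: the corrupted label matrix (same shape, `<= Y`
#'     elementwise, every row still >= 1 positive);
#'   * `deleted`: tibble of the removed `(doc, label)` pairs (1-based
#'     indices, one row each);
#'   * `shortfall`: tibble per label of requested vs achieved deletions.
#' @examples
#' Y <- matrix(1, 4, 3)
#' out <- delete_labels(Y, p = 0.5, seed = 7)
#' sum(out$Y_incomplete) + nrow(out$deleted) == sum(Y)
#' @export
delete_labels <- function(Y, p, seed = 1L,
                          rounding = c("round", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  if (inherits(Y, "multilabel_dataset")) Y <- Y$Y
  Y <- as_sparse_numeric(Y, "Y")
  if (!is.numeric(p) || length(p) != 1 || p < 0 || p >= 1) {
    stop("p must be a single value in [0, 1)", call. = FALSE)
  }
  assert_training_labels(Y)
  round_fun <- switch(rounding,
    round = function(x) floor(x + 0.5),
    floor = floor,
    ceiling = ceiling
  )
  Yw <- as.matrix(Y)  # work dense; corruption runs on modest training sets
  row_counts <- rowSums(Yw)
  m <- ncol(Yw)
  deleted_doc <- integer(0)
  deleted_lab <- integer(0)
  shortfall <- data.frame(label = seq_len(m), requested = 0L, achieved = 0L)
  withr::with_seed(seed, {
    for (cl in sample.int(m)) {
      pos <- which(Yw[, cl] == 1)
      want <- as.integer(round_fun(p * length(pos)))
      shortfall$requested[cl] <- want
      if (want == 0L) next
      cand <- pos[sample.int(length(pos))]
      got <- 0L
      for (d in cand) {
        if (got >= want) break
        if (row_counts[d] <= 1L) next  # sole label is protected
        Yw[d, cl] <- 0
        row_counts[d] <- row_counts[d] - 1L
        deleted_doc <- c(deleted_doc, d)
        deleted_lab <- c(deleted_lab, cl)
        got <- got + 1L
      }
      shortfall$achieved[cl] <- got
    }
  })
  deleted <- tibble::tibble(doc = deleted_doc, label = deleted_lab)
  deleted <- dplyr::arrange(deleted, .data$doc, .data$label)
  n_short <- sum(shortfall$requested - shortfall$achieved)
  if (n_short > 0) {
    message("delete_labels: ", n_short,
            " deletion(s) blocked by the >=1-label-per-row constraint")
  }
  list(
    Y_incomplete = Matrix::drop0(Matrix::Matrix(Yw, sparse = TRUE)),
    deleted = deleted,
    shortfall = tibble::as_tibble(shortfall)
  )
}
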