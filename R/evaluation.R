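#' Micro-averaged precision, recall and F1
#'
#' Pools true/false positives and false negatives over all
#' (document, label) cells before taking ratios — the multilabel metric
#' under which a classifier is rewarded equally for every label cell.
#' Ratios with a zero denominator are defined as 0.
#'
#' @param Y_true,Y_pred binary matrices of the same shape (sparse or dense;
#'   `multilabel_dataset`s are accepted and their `Y` used).
#' @return one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @examples
#' micro_prf(matrix(c(1, 0, 1, 1), 2), matrix(c(1, 1, 0, 1), 2))
#' @export
micro_prf <- function(Y_true, Y_pred) {
  if (inherits(Y_true, "multilabel_dataset")) Y_true <- Y_true$Y
  if (inherits(Y_pred, "multilabel_dataset")) Y_pred <- Y_pred$Y
  Yt <- as.matrix(Y_true)
  Yp <- as.matrix(Y_pred)
  if (!all(dim(Yt) == dim(Yp))) {
    stop("Y_true and Y_pred must have the same shape", call. = FALSE)
  }
  tp <- sum(Yt == 1 & Yp == 1)
  fp <- sum(Yt == 0 & Yp == 1)
  fn <- sum(Yt == 1 & Yp == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1)
}

#' CROC x-axis rescaling
#'
#' The exponential magnification of the early-retrieval region of a ROC
#' curve: `x_new(x) = (1 - exp(-alpha * x)) / (1 - exp(-alpha))`. Fixes 0
#' and 1, strictly increasing and concave for `alpha > 0`; `alpha = 7` is
#' the conventional magnification.
#'
#' @param x false-positive rate(s) in \[0, 1\].
#' @param alpha magnification constant, > 0.
#' @return rescaled value(s) in \[0, 1\].
#' @export
croc_rescale <- function(x, alpha = 7) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    stop("alpha must be a single positive number", call. = FALSE)
  }
  stopifnot(all(x >= 0 & x <= 1))
  (1 - exp(-alpha * x)) / (1 - exp(-alpha))
}

#' CROC curve and AUC for one label
#'
#' Standard ROC sweep over descending scores (instances with tied scores
#' move together, giving a unique curve), followed by exponential rescaling
#' of the false-positive axis with [croc_rescale()]. The AUC is the
#' trapezoidal area on the *rescaled* axis, between the realized points
#' anchored at (0, 0) and (1, 1).
#'
#' @param scores numeric prediction scores for the documents.
#' @param truth binary ground-truth memberships (same length); both classes
#'   must be present.
#' @param alpha magnification constant passed to [croc_rescale()].
#' @return object of class `croc_curve`: list with `points` (tibble `fpr`,
#'   `x_new`, `tpr`), `auc`, `alpha`, `n_pos`, `n_neg` and `integration`
#'   metadata.
#' @examples
#' cc <- croc_curve(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))
#' cc$auc  # 1: perfect ranking
#' @export
croc_curve <- function(scores, truth, alpha = 7) {
  stopifnot(length(scores) == length(truth),
            all(truth %in% c(0, 1)))
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("truth must contain at least one positive and one negative",
         call. = FALSE)
  }
  o <- order(-scores)
  s <- scores[o]
  y <- truth[o]
  # group tied scores: cumulative counts at each distinct threshold
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  ctp <- cumsum(y)[last_of_group]
  cfp <- cumsum(1 - y)[last_of_group]
  fpr <- c(0, cfp / n_neg)
  tpr <- c(0, ctp / n_pos)
  x_new <- croc_rescale(fpr, alpha)
  auc <- sum(diff(x_new) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = tibble::tibble(fpr = fpr, x_new = x_new, tpr = tpr),
         auc = auc, alpha = alpha, n_pos = n_pos, n_neg = n_neg,
         integration = "trapezoid-on-rescaled-axis"),
    class = "croc_curve"
  )
}

#' @export
print.croc_curve <- function(x, ...) {
  cat("<croc_curve> alpha = ", x$alpha, ", AUC = ", round(x$auc, 4),
      " (", x$n_pos, " pos / ", x$n_neg, " neg)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname croc_curve
#' @param x a `croc_curve`.
#' @param ... unused.
#' @export
tidy.croc_curve <- function(x, ...) x$points

#' @rdname croc_curve
#' @export
glance.croc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, alpha = x$alpha,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname croc_curve
#' @param object a `croc_curve`.
#' @export
autoplot.croc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x_new, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(
      x = sprintf("rescaled false-positive rate (alpha = %g)", object$alpha),
      y = "true-positive rate",
      title = sprintf("CROC curve, AUC = %.3f", object$auc)
    ) +
    ggplot2::coord_equal()
}

#' Tidy a Binary-Relevance model
#'
#' @param x a [train_br()] fit.
#' @param ... unused.
#' @return tibble with one row per label: `label`, `base`, `threshold`,
#'   `n_instances` (training instances after del-mode masking),
#'   `constant` (TRUE for degenerate always-one-class scorers).
#' @export
tidy.br_model <- function(x, ...) {
  tibble::tibble(
    label = x$label_names,
    base = x$base,
    threshold = x$b,
    n_instances = x$n_instances,
    constant = vapply(x$fits, function(f) f$type == "constant", logical(1))
  )
}

#' @rdname tidy.br_model
#' @return for `glance`: a one-row tibble with model-level settings.
#' @export
glance.br_model <- function(x, ...) {
  tibble::tibble(
    n_labels = length(x$fits),
    base = x$base,
    C = x$C,
    n_trees = x$n_trees,
    n_features = x$n_features
  )
}
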