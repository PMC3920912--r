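#' Train a Binary-Relevance multilabel classifier
#'
#' Decomposes the m-label problem into m independent binary problems. For
#' label `l` the positives are the documents carrying `l`; the negatives are
#' all other documents *minus* the del-mode mask (documents proposed as
#' relevant to `l`, excluded so that likely missing labels do not act as
#' false negatives during training). Base learners:
#'
#' * `"linear-svm"`: linear large-margin classifier (cost parameter `C`),
#'   decision rule `score(x) >= b_l` with `b_l = 0` by default;
#' * `"random-forest"`: ensemble of `n_trees` trees with
#'   `floor(sqrt(n_features))` split candidates per node, score = fraction
#'   of trees voting positive, default threshold `b_l = 0.5`.
#'
#' Labels with no positive (or no negative) training documents get a
#' constant scorer (logged via message).
#'
#' @param X feature matrix or training `multilabel_dataset`.
#' @param Y binary label matrix (ignored when `X` is a dataset).
#' @param mask optional `negative_mask` from [apply_del()].
#' @param base `"linear-svm"` or `"random-forest"`.
#' @param C cost parameter of the linear base learner.
#' @param n_trees forest size.
#' @param seed RNG seed (forest training).
#' @return object of class `br_model`: per-label fits, thresholds `b`,
#'   and training metadata.
#' @examples
#' ds <- generate_multilabel(synthetic_spec(n_docs = 80, n_labels = 4,
#'                                          n_features = 20, seed = 4))
#' fit <- train_br(ds)
#' mean(predict(fit, ds$X) == as.matrix(ds$Y))
#' @export
train_br <- function(X, Y = NULL, mask = NULL,
                     base = c("linear-svm", "random-forest"),
                     C = 1, n_trees = 30, seed = 1L) {
  base <- match.arg(base)
  if (inherits(X, "multilabel_dataset")) {
    Y <- X$Y
    X <- X$X
  }
  stopifnot(!is.null(Y), C > 0, n_trees >= 1)
  Y <- as_sparse_numeric(Y, "Y")
  if (nrow(Y) == 0) stop("empty training set", call. = FALSE)
  Xd <- as.matrix(X)
  m <- ncol(Y)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "negative_mask"), length(mask) == m)
  }
  fits <- vector("list", m)
  n_instances <- integer(m)
  withr::with_seed(seed, {
    for (l in seq_len(m)) {
      pos <- as.numeric(Y[, l]) == 1
      keep <- seq_len(nrow(Xd))
      if (!is.null(mask) && length(mask[[l]])) {
        drop <- setdiff(mask[[l]], which(pos))  # only negatives are masked
        keep <- setdiff(keep, drop)
      }
      yl <- pos[keep]
      n_instances[l] <- length(keep)
      if (all(yl) || !any(yl)) {
        if (!any(yl)) {
          message("label ", l, " has no positive training documents; ",
                  "constant always-negative scorer")
        }
        fits[[l]] <- list(type = "constant", value = if (all(yl)) 1 else -1)
      } else if (base == "linear-svm") {
        fits[[l]] <- fit_linear_binary(Xd[keep, , drop = FALSE], yl, C)
      } else {
        fits[[l]] <- fit_forest_binary(Xd[keep, , drop = FALSE], yl, n_trees)
      }
    }
  })
  structure(
    list(fits = fits, base = base, C = C, n_trees = n_trees,
         b = if (base == "linear-svm") rep(0, m) else rep(0.5, m),
         n_features = ncol(Xd), n_instances = n_instances,
         label_names = colnames(Y) %||% paste0("label_", seq_len(m)),
         seed = seed),
    class = "br_model"
  )
}

fit_linear_binary <- function(X, y, C) {
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  fit <- e1071::svm(X, yf, kernel = "linear", cost = C, scale = FALSE)
  dv <- attr(stats::predict(fit, X[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  # libsvm orients the decision value toward the first label it saw;
  # normalize so that larger score always means "pos"
  flip <- if (colnames(dv)[1] == "pos/neg") 1 else -1
  list(type = "svm", fit = fit, flip = flip)
}

fit_forest_binary <- function(X, y, n_trees) {
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  fit <- randomForest::randomForest(
    X, yf, ntree = n_trees, mtry = max(1, floor(sqrt(ncol(X)))))
  list(type = "rf", fit = fit)
}

#' Per-label decision scores
#'
#' Raw scores of a Binary-Relevance model on new documents: the linear
#' decision value for `"linear-svm"`, the positive-vote fraction for
#' `"random-forest"`. Deterministic given a fitted model.
#'
#' @param model a [train_br()] fit.
#' @param X feature matrix (or `multilabel_dataset`) with matching feature
#'   dimension.
#' @return dense `n x m` score matrix.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "br_model"))
  if (inherits(X, "multilabel_dataset")) X <- X$X
  Xd <- as.matrix(X)
  if (ncol(Xd) != model$n_features) {
    stop("feature dimension mismatch: model expects ", model$n_features,
         ", got ", ncol(Xd), call. = FALSE)
  }
  S <- matrix(0, nrow(Xd), length(model$fits))
  for (l in seq_along(model$fits)) {
    f <- model$fits[[l]]
    S[, l] <- switch(f$type,
      constant = rep(f$value, nrow(Xd)),
      svm = {
        dv <- attr(stats::predict(f$fit, Xd, decision.values = TRUE),
                   "decision.values")
        f$flip * as.numeric(dv)
      },
      rf = stats::predict(f$fit, Xd, type = "prob")[, "pos"]
    )
  }
  colnames(S) <- model$label_names
  S
}

#' Predict label memberships
#'
#' Applies the per-label thresholds: document `d` gets label `l` iff
#' `score(d, l) >= b_l`.
#'
#' @param object a [train_br()] fit (thresholds possibly replaced by
#'   [tune_br()]).
#' @param X feature matrix or `multilabel_dataset`.
#' @param ... unused.
#' @return binary `n x m` matrix.
#' @export
predict.br_model <- function(object, X, ...) {
  S <- predict_scores(object, X)
  out <- (S >= matrix(object$b, nrow(S), ncol(S), byrow = TRUE)) * 1
  colnames(out) <- object$label_names
  out
}

#' Tune the cost parameter and per-label thresholds
#'
#' The tuning protocol of the experiments: for every `C` on the grid a
#' Binary-Relevance model is fit on the training set; on the development
#' set each label's threshold `b_l` is scanned over the sorted unique
#' scores of that label (plus a sentinel that predicts all-negative) and
#' set to the value maximizing that label's F1 (ties broken toward the
#' smaller `b_l`); the pair (`C`, `{b_l}`) maximizing the configured
#' aggregate F1 is returned, ties toward the smaller `C`. Aggregates:
#' `"micro"` (pooled cell counts, the reported-results metric) or
#' `"doc-F1"` (F1 averaged over documents).
#'
#' @param X,Y training features and labels (or `X` a `multilabel_dataset`).
#' @param dev_X,dev_Y development features and labels (or `dev_X` a
#'   `multilabel_dataset`).
#' @param C_grid candidate cost values.
#' @param tune_metric `"micro"` or `"doc-F1"`.
#' @inheritParams train_br
#' @return list with `C`, `b` (per-label thresholds), `dev_f1`, and `model`
#'   (the refitted model with tuned thresholds installed).
#' @export
tune_br <- function(X, Y = NULL, dev_X, dev_Y = NULL,
                    C_grid = 10^(-2:2), mask = NULL,
                    base = c("linear-svm", "random-forest"),
                    tune_metric = c("micro", "doc-F1"),
                    n_trees = 30, seed = 1L) {
  base <- match.arg(base)
  tune_metric <- match.arg(tune_metric)
  stopifnot(length(C_grid) >= 1)
  if (inherits(dev_X, "multilabel_dataset")) {
    dev_Y <- dev_X$Y
    dev_X <- dev_X$X
  }
  stopifnot(!is.null(dev_Y), nrow(dev_X) >= 1)
  dev_Yd <- as.matrix(dev_Y)
  if (sum(dev_Yd) == 0) {
    stop("degenerate development set: no positive labels", call. = FALSE)
  }
  best <- NULL
  for (C in sort(C_grid)) {
    model <- train_br(X, Y, mask = mask, base = base, C = C,
                      n_trees = n_trees, seed = seed)
    S <- predict_scores(model, dev_X)
    b <- vapply(seq_len(ncol(S)), function(l) {
      scan_threshold(S[, l], dev_Yd[, l])
    }, numeric(1))
    pred <- (S >= matrix(b, nrow(S), ncol(S), byrow = TRUE)) * 1
    f1 <- if (tune_metric == "micro") {
      micro_prf(dev_Yd, pred)$f1
    } else {
      doc_f1(dev_Yd, pred)
    }
    if (is.null(best) || f1 > best$dev_f1 + 1e-12) {
      model$b <- b
      best <- list(C = C, b = b, dev_f1 = f1, model = model)
    }
  }
  best
}

# best threshold for rule score >= b by exhaustive scan over the distinct
# scores (candidates where the prediction set actually changes), ties -> smaller b
scan_threshold <- function(scores, truth) {
  cand <- sort(unique(scores))
  cand <- c(cand, max(cand) + 1)  # sentinel: predict nothing
  n_pos <- sum(truth)
  best_b <- cand[1]
  best_f1 <- -1
  for (b in cand) {
    pred <- scores >= b
    tp <- sum(pred & truth == 1)
    fp <- sum(pred & truth == 0)
    fn <- n_pos - tp
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f1 > best_f1 + 1e-12) {
      best_f1 <- f1
      best_b <- b
    }
  }
  best_b
}

doc_f1 <- function(Y_true, Y_pred) {
  per_doc <- vapply(seq_len(nrow(Y_true)), function(d) {
    tp <- sum(Y_true[d, ] == 1 & Y_pred[d, ] == 1)
    denom <- sum(Y_true[d, ]) + sum(Y_pred[d, ])
    if (denom == 0) 1 else 2 * tp / denom
  }, numeric(1))
  mean(per_doc)
}

#' @export
print.br_model <- function(x, ...) {
  cat("<br_model> ", length(x$fits), " labels, base = ", x$base,
      if (x$base == "linear-svm") paste0(", C = ", x$C)
      else paste0(", trees = ", x$n_trees),
      "\n", sep = "")
  invisible(x)
}
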