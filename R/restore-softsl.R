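#' Kullback-Leibler divergence between two discrete distributions
#'
#' `sum(p * log(p / q))` with both arguments floored at `eps` before
#' evaluation (so zeros never hit the log); nonnegative, and zero iff the
#' floored distributions coincide.
#'
#' @param p,q numeric probability vectors of equal length (rows summing
#'   to 1).
#' @param eps probability floor.
#' @return divergence in nats, >= 0.
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5))  # ~ log(2)
#' @export
kl_divergence <- function(p, q, eps = 1e-10) {
  stopifnot(length(p) == length(q), eps > 0)
  p <- pmax(p, eps)
  q <- pmax(q, eps)
  sum(p * log(p / q))
}

#' Shannon entropy of a discrete distribution
#'
#' `-sum(p * log(p))` in nats; 0 for a degenerate distribution and `log(m)`
#' for the uniform one over `m` classes.
#'
#' @param p numeric probability vector.
#' @param eps probability floor applied before the log.
#' @return entropy in nats, in `[0, log(length(p))]`.
#' @export
entropy <- function(p, eps = 1e-10) {
  p <- pmax(p, eps)
  -sum(p * log(p))
}

#' SoftSL hyperparameters
#'
#' Controls the graph-regularized soft-supervised objective and its
#' minimization: `mu` weighs the graph-smoothness term, `nu` the (negative)
#' entropy regularizer, `T` the acceptance threshold on optimized class
#' probabilities. The defaults `T = 0.005` and `nu = 0` suit the usual
#' setting where every training document already carries some label, so the
#' uniformizing entropy term is unnecessary.
#'
#' @param k neighbour count for the graph.
#' @param mu graph-term weight, >= 0.
#' @param nu entropy-term weight, >= 0.
#' @param T acceptance threshold in \[0, 1\].
#' @param tol relative objective-decrease tolerance for convergence.
#' @param max_iter iteration cap.
#' @param eps probability floor.
#' @return list of class `softsl_params`.
#' @export
softsl_params <- function(k = 10, mu = 0.5, nu = 0, T = 0.005,
                          tol = 1e-6, max_iter = 200, eps = 1e-10) {
  stopifnot(k >= 1, mu >= 0, nu >= 0, T >= 0, tol > 0, max_iter >= 1,
            eps > 0, eps < 1e-2)
  structure(list(k = k, mu = mu, nu = nu, T = T, tol = tol,
                 max_iter = max_iter, eps = eps),
            class = "softsl_params")
}

#' SoftSL misalignment objective
#'
#' `C1(p) = sum_labeled KL(r_i, p_i) + mu * sum_i sum_{j in K(i)} w_ij KL(p_i, p_j)
#' - nu * sum_i H(p_i)`: fidelity to the expert reference distributions,
#' smoothness of adjacent distributions on the neighbour graph, and an
#' optional uniformizing entropy term.
#'
#' @param p `n x m` row-stochastic matrix of class-membership distributions.
#' @param r `n x m` row-stochastic expert reference distributions.
#' @param graph a [build_graph()] result over the same `n` documents.
#' @param params a [softsl_params()].
#' @param labeled logical or integer vector marking rows with expert labels
#'   (default: all rows).
#' @return objective value (scalar).
#' @export
softsl_objective <- function(p, r, graph, params = softsl_params(),
                             labeled = NULL) {
  stopifnot(inherits(graph, "neighbor_graph"),
            nrow(p) == graph$n, all(dim(p) == dim(r)))
  if (is.null(labeled)) labeled <- seq_len(nrow(p))
  eps <- params$eps
  pe <- pmax(p, eps)
  re <- pmax(r, eps)
  fid <- sum(re[labeled, , drop = FALSE] *
               (log(re[labeled, , drop = FALSE]) -
                log(pe[labeled, , drop = FALSE])))
  smooth <- 0
  if (params$mu > 0) {
    W <- graph_weight_matrix(graph)
    lp <- log(pe)
    deg <- Matrix::rowSums(W)
    # sum_i sum_j W_ij KL(p_i, p_j) = sum_i deg_i <p_i, log p_i> - sum p * (W log p)
    smooth <- sum(deg * rowSums(pe * lp)) -
      sum(pe * as.matrix(W %*% lp))
  }
  ent <- if (params$nu > 0) sum(pe * log(pe)) else 0
  fid + params$mu * smooth + params$nu * ent
}

graph_weight_matrix <- function(graph) {
  Matrix::sparseMatrix(
    i = rep(seq_len(graph$n), times = graph$k),
    j = as.integer(graph$idx),
    x = as.numeric(graph$w),
    dims = c(graph$n, graph$n)
  )
}

#' Minimize the SoftSL objective
#'
#' Projected multiplicative (exponentiated-gradient) descent on the
#' misalignment objective with backtracking line search: each step moves all
#' rows along `p * exp(-step * grad)` and renormalizes, accepting the step
#' only if the objective decreases, so the recorded objective trace is
#' monotone non-increasing and every iterate is row-stochastic. Stops when
#' the relative decrease falls below `tol` or at `max_iter` (then flagged as
#' non-converged).
#'
#' @param p0 initial `n x m` row-stochastic matrix.
#' @param r expert reference distributions (`n x m`, row-stochastic).
#' @inheritParams softsl_objective
#' @return list of class `softsl_fit`: `p` (optimized distributions),
#'   `trace` (objective per iteration, element 1 = at `p0`), `converged`,
#'   `iterations`.
#' @export
softsl_minimize <- function(p0, r, graph, params = softsl_params(),
                            labeled = NULL) {
  stopifnot(nrow(p0) == graph$n, all(dim(p0) == dim(r)))
  if (is.null(labeled)) labeled <- seq_len(nrow(p0))
  lab_mask <- rep(FALSE, nrow(p0))
  lab_mask[labeled] <- TRUE
  eps <- params$eps
  p <- p0 / rowSums(p0)
  obj <- softsl_objective(p, r, graph, params, labeled)
  trace <- obj
  step <- 1
  converged <- FALSE
  W <- graph_weight_matrix(graph)
  for (it in seq_len(params$max_iter)) {
    g <- softsl_gradient(p, r, params, lab_mask, W)
    improved <- FALSE
    while (step > 1e-12) {
      cand <- pmax(p * exp(-step * pmin(pmax(g, -50), 50)), eps)
      cand <- cand / rowSums(cand)
      cand_obj <- softsl_objective(cand, r, graph, params, labeled)
      if (cand_obj < obj) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) {
      converged <- TRUE
      break
    }
    rel <- (obj - cand_obj) / max(abs(obj), 1)
    p <- cand
    obj <- cand_obj
    trace <- c(trace, obj)
    step <- min(step * 2, 10)
    if (rel < params$tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(p = p, trace = trace, converged = converged,
                 iterations = length(trace) - 1L),
            class = "softsl_fit")
}

softsl_gradient <- function(p, r, params, lab_mask, W) {
  eps <- params$eps
  pe <- pmax(p, eps)
  lp <- log(pe)
  g <- matrix(0, nrow(p), ncol(p))
  g[lab_mask, ] <- -pmax(r[lab_mask, , drop = FALSE], 0) /
    pe[lab_mask, , drop = FALSE]
  if (params$mu > 0) {
    deg <- Matrix::rowSums(W)
    # out-edges: d/dp_i of sum_j w_ij KL(p_i, p_j)
    # in-edges:  d/dp_i of sum_j w_ji KL(p_j, p_i)
    g <- g + params$mu * (deg * (lp + 1) - as.matrix(W %*% lp)) -
      params$mu * as.matrix(Matrix::t(W) %*% pe) / pe
  }
  if (params$nu > 0) g <- g + params$nu * (lp + 1)
  g
}

#' Restore missing labels by soft supervised learning
#'
#' Builds the neighbour graph, sets the expert reference distribution `r_i`
#' of each document uniform over its assigned labels, minimizes the
#' graph-regularized KL misalignment objective with [softsl_minimize()]
#' (initialized at `p = r`), and proposes every unlabeled pair whose
#' optimized probability reaches `T`.
#'
#' @param X feature matrix or `multilabel_dataset`.
#' @param Y binary training label matrix (ignored if `X` is a dataset).
#' @param params a [softsl_params()].
#' @param graph optional prebuilt graph (overrides `params$k`).
#' @return tibble of class `relevance_pairs` (`doc`, `label`, `score` =
#'   optimized probability), descending score; attribute `"fit"` carries the
#'   [softsl_minimize()] result.
#' @examples
#' ds <- generate_multilabel(synthetic_spec(n_docs = 60, n_labels = 4,
#'                                          n_features = 20, seed = 5))
#' corr <- delete_labels(ds$Y, p = 0.3, seed = 9)
#' restore_softsl(ds$X, corr$Y_incomplete, softsl_params(k = 8, mu = 0.5))
#' @export
restore_softsl <- function(X, Y = NULL, params = softsl_params(),
                           graph = NULL) {
  if (inherits(X, "multilabel_dataset")) {
    Y <- X$Y
    X <- X$X
  }
  stopifnot(!is.null(Y), inherits(params, "softsl_params"))
  Y <- as_sparse_numeric(Y, "Y")
  assert_training_labels(Y)
  if (is.null(graph)) graph <- build_graph(X, params$k)
  Yd <- as.matrix(Y)
  r <- Yd / rowSums(Yd)
  fit <- softsl_minimize(r, r, graph, params)
  keep <- which(fit$p >= params$T & Yd == 0, arr.ind = TRUE)
  pairs <- tibble::tibble(
    doc = as.integer(keep[, 1]),
    label = as.integer(keep[, 2]),
    score = fit$p[keep]
  )
  pairs <- dplyr::arrange(pairs, dplyr::desc(.data$score), .data$doc,
                          .data$label)
  class(pairs) <- c("relevance_pairs", class(pairs))
  attr(pairs, "fit") <- fit
  pairs
}
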