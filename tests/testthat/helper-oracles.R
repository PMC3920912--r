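# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# exhaustive cosine kNN: full pairwise loop, sort, tie-break by index
brute_knn <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  cs <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }
  idx <- matrix(0L, n, k)
  w <- matrix(0, n, k)
  for (i in seq_len(n)) {
    sims <- vapply(seq_len(n), function(j) cs(X[i, ], X[j, ]), numeric(1))
    others <- setdiff(seq_len(n), i)
    o <- others[order(-sims[others], others)][seq_len(k)]
    idx[i, ] <- o
    w[i, ] <- sims[o]
  }
  list(idx = idx, w = w)
}

# direct evaluation of the weighted-vote score from the raw data
brute_wknn_score <- function(X, Y, d, cl, k) {
  nn <- brute_knn(X, k)
  wts <- nn$w[d, ]
  memb <- as.numeric(as.matrix(Y)[nn$idx[d, ], cl])
  if (sum(wts) <= 0) return(0)
  sum(wts * memb) / sum(wts)
}

# cell-by-cell micro counting
brute_micro <- function(Y_true, Y_pred) {
  Yt <- as.matrix(Y_true); Yp <- as.matrix(Y_pred)
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(Yt))) {
    for (j in seq_len(ncol(Yt))) {
      if (Yt[i, j] == 1 && Yp[i, j] == 1) tp <- tp + 1
      if (Yt[i, j] == 0 && Yp[i, j] == 1) fp <- fp + 1
      if (Yt[i, j] == 1 && Yp[i, j] == 0) fn <- fn + 1
    }
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f)
}

# quadrature oracle: area of a piecewise-constant ROC (tpr as a step
# function of fpr) on the exponentially rescaled x axis
quadrature_croc_auc <- function(tpr_of_x, alpha) {
  dxnew <- function(x) alpha * exp(-alpha * x) / (1 - exp(-alpha))
  stats::integrate(function(x) tpr_of_x(x) * dxnew(x), 0, 1,
                   subdivisions = 2000L, rel.tol = 1e-10)$value
}

# small random multilabel instance; every row gets >= 1 label
random_instance <- function(n, m, f, seed) {
  withr::with_seed(seed, {
    X <- matrix(round(stats::runif(n * f), 6), n, f)
    Y <- matrix(stats::rbinom(n * m, 1, 0.3), n, m)
    for (i in seq_len(n)) {
      if (sum(Y[i, ]) == 0) Y[i, sample.int(m, 1)] <- 1
    }
    list(X = X, Y = Y)
  })
}

random_row_stochastic <- function(n, m, seed) {
  withr::with_seed(seed, {
    p <- matrix(stats::runif(n * m), n, m)
    p / rowSums(p)
  })
}
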