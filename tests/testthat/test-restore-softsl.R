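test_that("kl_divergence: closed forms, nonnegativity, identity", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5), eps = 1e-14), log(2),
               tolerance = 1e-10)
  for (seed in 1:50) {
    p <- random_row_stochastic(1, 5, seed)[1, ]
    q <- random_row_stochastic(1, 5, seed + 1000)[1, ]
    expect_gte(kl_divergence(p, q), 0)
  }
})

test_that("entropy: degenerate, uniform and closed-form values", {
  expect_equal(entropy(c(1, 0, 0), eps = 1e-14), 0, tolerance = 1e-10)
  expect_equal(entropy(rep(1 / 4, 4)), log(4))
  # (0.5, 0.25, 0.25): 1.5 bits = 1.5 * log(2) nats
  expect_equal(entropy(c(0.5, 0.25, 0.25)), 1.5 * log(2), tolerance = 1e-10)
})

test_that("objective matches an independent term-by-term computation", {
  withr::with_seed(6, X <- matrix(runif(16), 4, 4))
  g <- build_graph(X, 2)
  p <- random_row_stochastic(4, 3, 21)
  r <- random_row_stochastic(4, 3, 22)
  prm <- softsl_params(k = 2, mu = 0.7, nu = 0.3)
  # brute-force: loop every term of the objective
  fid <- sum(vapply(1:4, function(i) kl_divergence(r[i, ], p[i, ]),
                    numeric(1)))
  smooth <- 0
  for (i in 1:4) {
    for (t in 1:2) {
      j <- g$idx[i, t]
      smooth <- smooth + g$w[i, t] * kl_divergence(p[i, ], p[j, ])
    }
  }
  ent <- sum(vapply(1:4, function(i) entropy(p[i, ]), numeric(1)))
  expect_equal(softsl_objective(p, r, g, prm),
               fid + 0.7 * smooth - 0.3 * ent, tolerance = 1e-8)

  # p = r with mu = nu = 0: objective is exactly 0
  prm0 <- softsl_params(k = 2, mu = 0, nu = 0)
  expect_equal(softsl_objective(r, r, g, prm0), 0)
  expect_error(softsl_objective(p[1:3, ], r, g, prm), "nrow")
})

test_that("minimization decreases the objective monotonically", {
  for (seed in 1:5) {
    inst <- random_instance(20, 4, 6, seed + 300)
    g <- build_graph(inst$X, 4)
    r <- inst$Y / rowSums(inst$Y)
    prm <- softsl_params(k = 4, mu = 0.8, nu = 0.1)
    fit <- softsl_minimize(r, r, g, prm)
    expect_true(all(diff(fit$trace) <= 1e-9))
    expect_true(all(abs(rowSums(fit$p) - 1) < 1e-8))
    expect_true(all(fit$p >= 0))
    expect_lte(fit$trace[length(fit$trace)], fit$trace[1])
    # beats 100 random row-stochastic tables
    rand_best <- min(vapply(1:100, function(s) {
      softsl_objective(random_row_stochastic(20, 4, s), r, g, prm)
    }, numeric(1)))
    expect_lte(fit$trace[length(fit$trace)], rand_best)
  }
})

test_that("mu = nu = 0 keeps the objective-zero start p = r", {
  inst <- random_instance(15, 3, 5, 71)
  g <- build_graph(inst$X, 3)
  r <- inst$Y / rowSums(inst$Y)
  fit <- softsl_minimize(r, r, g, softsl_params(k = 3, mu = 0, nu = 0))
  expect_equal(fit$trace[1], 0)
  expect_equal(as.numeric(fit$p), as.numeric(r), tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("duplicate documents with identical references optimize identically", {
  # complete graph (k = n - 1): every document keeps both duplicates in its
  # neighbour list, so the duplicates' in-edges are symmetric. (With k < n-1
  # the deterministic tie rule routes tied edges to the lower index, which
  # legitimately breaks exact symmetry between duplicates.)
  withr::with_seed(9, X <- matrix(runif(40), 10, 4))
  X[2, ] <- X[1, ]
  Y <- matrix(rbinom(30, 1, 0.5), 10, 3)
  Y[rowSums(Y) == 0, 1] <- 1
  Y[2, ] <- Y[1, ]
  pc <- restore_softsl(X, Y, softsl_params(k = 9, mu = 0.5))
  fit <- attr(pc, "fit")
  expect_equal(fit$p[1, ], fit$p[2, ], tolerance = 1e-8)
})

test_that("larger mu pulls adjacent distributions together", {
  inst <- random_instance(15, 3, 5, 83)
  g <- build_graph(inst$X, 3)
  r <- inst$Y / rowSums(inst$Y)
  adj_kl <- function(mu) {
    fit <- softsl_minimize(r, r, g, softsl_params(k = 3, mu = mu,
                                                  max_iter = 400))
    max(vapply(seq_len(g$n), function(i) {
      max(vapply(seq_len(g$k), function(t) {
        kl_divergence(fit$p[i, ], fit$p[g$idx[i, t], ])
      }, numeric(1)))
    }, numeric(1)))
  }
  expect_lt(adj_kl(20), adj_kl(0.2))
})

test_that("restoration proposals behave at the threshold extremes", {
  inst <- random_instance(25, 4, 6, 17)
  pcs <- restore_softsl(inst$X, inst$Y,
                        softsl_params(k = 5, mu = 0.5, T = 1 + 1e-9))
  expect_equal(nrow(pcs), 0L)
  # fully, identically labeled dataset: nothing unlabeled to propose
  Yfull <- matrix(1, 25, 4)
  pcf <- restore_softsl(inst$X, Yfull, softsl_params(k = 5, mu = 0.5))
  expect_equal(nrow(pcf), 0L)
})

test_that("a deleted label in a compact two-cluster instance is proposed", {
  ds <- generate_multilabel(synthetic_spec(n_docs = 40, n_labels = 2,
                                           n_features = 10, spread = 0.05,
                                           co_label_rate = 0.3, q = 1,
                                           seed = 12))
  corr <- delete_labels(ds$Y, 0.2, seed = 3)
  expect_gt(nrow(corr$deleted), 0)
  pc <- restore_softsl(ds$X, corr$Y_incomplete,
                       softsl_params(k = 8, mu = 0.5, T = 0.005))
  hits <- dplyr::inner_join(pc, corr$deleted, by = c("doc", "label"))
  expect_gt(nrow(hits) / nrow(corr$deleted), 0.5)
})

test_that("softsl proposals are monotone in T", {
  inst <- random_instance(30, 4, 8, 41)
  corr <- delete_labels(inst$Y, 0.3, seed = 2)
  g <- build_graph(inst$X, 5)
  key <- function(p) paste(p$doc, p$label)
  prev <- NULL
  for (T in c(0.4, 0.1, 0.005)) {
    cur <- restore_softsl(inst$X, corr$Y_incomplete,
                          softsl_params(k = 5, mu = 0.5, T = T), graph = g)
    if (!is.null(prev)) expect_true(all(key(prev) %in% key(cur)))
    prev <- cur
  }
})
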