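# small separable two-label fixture: two disjoint clusters in 2-D
separable_toy <- function(n_per = 20, seed = 5) {
  withr::with_seed(seed, {
    X <- rbind(
      cbind(runif(n_per, 0.8, 1), runif(n_per, 0, 0.2)),
      cbind(runif(n_per, 0, 0.2), runif(n_per, 0.8, 1))
    )
    Y <- rbind(
      matrix(rep(c(1, 0), n_per), ncol = 2, byrow = TRUE),
      matrix(rep(c(0, 1), n_per), ncol = 2, byrow = TRUE)
    )
  })
  list(X = X, Y = Y)
}

test_that("a separable toy is fit perfectly and scores are deterministic", {
  toy <- separable_toy()
  fit <- train_br(toy$X, toy$Y)
  pred <- predict(fit, toy$X)
  expect_equal(as.numeric(pred), as.numeric(toy$Y))
  S1 <- predict_scores(fit, toy$X)
  S2 <- predict_scores(fit, toy$X)
  expect_identical(S1, S2)
  # duplicate rows get identical score rows
  Xdup <- toy$X[c(1, 1, 30, 30), ]
  Sd <- predict_scores(fit, Xdup)
  expect_equal(Sd[1, ], Sd[2, ])
  expect_equal(Sd[3, ], Sd[4, ])
  # positives score above the (zero) linear threshold
  expect_true(all(S1[1:20, 1] >= 0))
})

test_that("del-mode masks shrink each label's binary problem exactly", {
  toy <- separable_toy()
  mask <- structure(list(c(25L, 26L, 27L), integer(0)),
                    class = "negative_mask")
  fit <- train_br(toy$X, toy$Y, mask = mask)
  expect_equal(fit$n_instances, c(40L - 3L, 40L))
  # masked documents that are positives of the label are NOT removed
  mask_pos <- structure(list(c(1L, 25L), integer(0)),
                        class = "negative_mask")
  fit2 <- train_br(toy$X, toy$Y, mask = mask_pos)
  expect_equal(fit2$n_instances, c(39L, 40L))  # doc 1 is a positive of label 1
})

test_that("labels with no positives produce an always-negative scorer", {
  toy <- separable_toy()
  Y3 <- cbind(toy$Y, 0)
  expect_message(fit <- train_br(toy$X, Y3), "no positive")
  pred <- predict(fit, toy$X)
  expect_true(all(pred[, 3] == 0))
  expect_true(tidy(fit)$constant[3])
})

test_that("forest configuration follows the 30-tree, sqrt-features recipe", {
  ds <- generate_multilabel(synthetic_spec(n_docs = 60, n_labels = 3,
                                           n_features = 26, seed = 6))
  fit <- train_br(ds, base = "random-forest", seed = 3)
  rf <- fit$fits[[1]]$fit
  expect_equal(rf$ntree, 30)
  expect_equal(rf$mtry, floor(sqrt(26)))
  # scores are vote fractions in [0, 1]; training deterministic per seed
  S <- predict_scores(fit, ds$X)
  expect_true(all(S >= 0 & S <= 1))
  fit2 <- train_br(ds, base = "random-forest", seed = 3)
  expect_equal(predict_scores(fit2, ds$X), S)
})

test_that("zero-vector input scores at the linear offset", {
  toy <- separable_toy()
  fit <- train_br(toy$X, toy$Y)
  s0 <- predict_scores(fit, matrix(0, 1, 2))
  # decision value of the origin = -rho (the offset term); just check it is
  # reproducible and finite
  expect_true(all(is.finite(s0)))
  expect_equal(s0, predict_scores(fit, matrix(0, 1, 2)))
})

test_that("threshold scan equals a brute-force scan over all cut-points", {
  withr::with_seed(10, {
    scores <- round(runif(30), 2)  # force ties
    truth <- rbinom(30, 1, 0.4)
  })
  truth[1] <- 1
  got_b <- mlrestore:::scan_threshold(scores, truth)
  # brute force over every candidate cut (all unique scores + sentinel)
  cands <- c(sort(unique(scores)), max(scores) + 1)
  f1s <- vapply(cands, function(b) {
    pred <- as.numeric(scores >= b)
    tp <- sum(pred == 1 & truth == 1)
    fp <- sum(pred == 1 & truth == 0)
    fn <- sum(pred == 0 & truth == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  best <- max(f1s)
  pred_got <- as.numeric(scores >= got_b)
  tp <- sum(pred_got == 1 & truth == 1)
  fp <- sum(pred_got == 1 & truth == 0)
  fn <- sum(pred_got == 0 & truth == 1)
  got_f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_equal(got_f1, best)
  expect_equal(got_b, cands[which(f1s > best - 1e-12)[1]])  # smallest b wins
})

test_that("tune_br picks the dev-F1-maximizing C with tie toward smaller C", {
  toy <- separable_toy()
  dev <- separable_toy(seed = 8)
  out <- tune_br(toy$X, toy$Y, dev$X, dev$Y, C_grid = c(0.01, 1))
  expect_true(out$C %in% c(0.01, 1))
  expect_equal(out$dev_f1, 1)          # separable: perfect dev F1
  expect_equal(out$C, 0.01)            # tie -> smaller C
  pred <- predict(out$model, dev$X)
  expect_equal(as.numeric(pred), as.numeric(dev$Y))
  expect_error(tune_br(toy$X, toy$Y, dev$X, matrix(0, 40, 2)), "degenerate")
})

test_that("feature-dimension mismatches are rejected", {
  toy <- separable_toy()
  fit <- train_br(toy$X, toy$Y)
  expect_error(predict_scores(fit, matrix(0, 2, 5)), "dimension mismatch")
})
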