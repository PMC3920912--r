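test_that("micro_prf matches hand counts and the cell-counting oracle", {
  Yt <- matrix(c(1, 1, 0, 1, 0, 0), 3, 2)  # crafted: TP=2, FP=1, FN=2 below
  Yp <- matrix(c(1, 0, 1, 1, 0, 1), 3, 2)
  # cells: (1,1) TP, (2,1) FN, (3,1) FP, (1,2) TP, (3,2) FP... recount via oracle
  got <- micro_prf(Yt, Yp)
  oracle <- brute_micro(Yt, Yp)
  expect_equal(got$tp, oracle[["tp"]])
  expect_equal(got$precision, oracle[["precision"]])
  expect_equal(got$f1, oracle[["f1"]])

  expect_equal(micro_prf(Yt, Yt)$f1, 1)
  deg <- micro_prf(Yt, matrix(0, 3, 2))
  expect_equal(c(deg$precision, deg$recall, deg$f1), c(0, 0, 0))

  # explicit hand count: TP=2, FP=1, FN=2 -> P=2/3, R=1/2, F1=4/7
  t2 <- matrix(c(1, 1, 1, 1, 0, 0), 3, 2)
  p2 <- matrix(c(1, 1, 0, 0, 1, 0), 3, 2)
  m2 <- micro_prf(t2, p2)
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$recall, 1 / 2)
  expect_equal(m2$f1, 4 / 7)

  for (seed in 1:20) {
    a <- random_instance(12, 4, 2, seed)
    b <- random_instance(12, 4, 2, seed + 500)
    expect_equal(as.numeric(micro_prf(a$Y, b$Y)[, 4:6]),
                 as.numeric(brute_micro(a$Y, b$Y)[4:6]))
  }
  expect_error(micro_prf(matrix(0, 2, 2), matrix(0, 3, 2)), "same shape")
})

test_that("croc_rescale fixes endpoints, is increasing and concave", {
  expect_equal(croc_rescale(0), 0)
  expect_equal(croc_rescale(1), 1)
  expect_equal(croc_rescale(0.5, 7), (1 - exp(-3.5)) / (1 - exp(-7)))
  xs <- seq(0, 1, by = 0.01)
  ys <- croc_rescale(xs, 7)
  expect_true(all(diff(ys) > 0))
  expect_true(all(diff(diff(ys)) < 0))
  expect_error(croc_rescale(0.5, alpha = -1), "positive")
  expect_error(croc_rescale(1.5), "x >= 0")
})

test_that("perfect and reversed rankers hit the AUC extremes", {
  truth <- c(rep(1, 5), rep(0, 10))
  scores <- 15:1
  expect_equal(croc_curve(scores, truth, alpha = 7)$auc, 1)
  expect_equal(croc_curve(scores, truth, alpha = 0.3)$auc, 1)
  rev <- croc_curve(-scores, truth, alpha = 7)
  # anti-perfect step curve has zero area on any monotone rescaling
  oracle <- quadrature_croc_auc(function(x) 0 * x, 7)
  expect_equal(rev$auc, oracle, tolerance = 1e-8)
})

test_that("AUC equals hand-computed rescaled polyline areas", {
  # documented convention: tied instances move together; the curve is the
  # polyline through the realized sweep points, integrated on the rescaled
  # axis
  truth <- c(rep(1, 6), rep(0, 6))
  # all scores tied: the curve collapses to the (0,0)-(1,1) chord
  cc_tied <- croc_curve(rep(0.5, 12), truth, alpha = 7)
  expect_equal(cc_tied$auc, 0.5, tolerance = 1e-12)
  # scores (3,2,2,1) / truth (1,0,1,0): sweep points (0,0), (0,1/2),
  # (1/2,1), (1,1); area on the rescaled axis = 1 - z/4 with z = x_new(1/2)
  cc4 <- croc_curve(c(3, 2, 2, 1), c(1, 0, 1, 0), alpha = 7)
  z <- (1 - exp(-3.5)) / (1 - exp(-7))
  expect_equal(cc4$auc, 1 - z / 4, tolerance = 1e-12)
  expect_equal(cc4$points$fpr, c(0, 0, 0.5, 1))
  expect_equal(cc4$points$tpr, c(0, 0.5, 1, 1))
})

test_that("AUC is invariant to monotone score transforms", {
  withr::with_seed(13, {
    scores <- runif(40)
    truth <- rbinom(40, 1, 0.4)
  })
  truth[1:2] <- c(0, 1)
  a <- croc_curve(scores, truth)$auc
  expect_equal(croc_curve(2 * scores + 3, truth)$auc, a, tolerance = 1e-12)
  expect_equal(croc_curve(exp(scores), truth)$auc, a, tolerance = 1e-12)
})

test_that("CROC converges to ROC as alpha -> 0+", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    scores <- runif(60)
    truth <- rbinom(60, 1, 0.5)
  })
  truth[1:2] <- c(0, 1)
  croc <- croc_curve(scores, truth, alpha = 1e-6)$auc
  roc <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(croc, roc, tolerance = 1e-4)
})

test_that("degenerate truth vectors are rejected", {
  expect_error(croc_curve(runif(5), rep(1, 5)), "positive and one negative")
  expect_error(croc_curve(runif(5), rep(0, 5)), "positive and one negative")
})

test_that("tidy/glance/autoplot surfaces work for curves and models", {
  cc <- croc_curve(c(0.9, 0.7, 0.3, 0.1), c(1, 0, 1, 0))
  td <- tidy(cc)
  expect_true(all(c("fpr", "x_new", "tpr") %in% names(td)))
  expect_true(all(diff(td$x_new) >= 0))
  gl <- glance(cc)
  expect_equal(gl$auc, cc$auc)
  p <- autoplot(cc)
  expect_s3_class(p, "ggplot")

  toy <- random_instance(30, 3, 6, 3)
  fit <- train_br(toy$X, toy$Y)
  expect_equal(nrow(tidy(fit)), 3)
  expect_equal(glance(fit)$n_labels, 3)
})
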