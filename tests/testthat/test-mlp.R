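test_that("class weights follow inverse-frequency normalization", {
  expect_equal(class_weights(c(10, 10, 10)), c(1, 1, 1))
  expect_equal(class_weights(c(30, 10)), c(2 / 3, 2))
  # absent classes get weight 0 and are excluded from the class count
  expect_equal(class_weights(c(5, 0, 5)), c(1, 0, 1))
  expect_error(class_weights(c(0, 0)))
  # weighted mean of weights over observed samples is 1 (property)
  withr::with_seed(8, {
    for (i in 1:20) {
      counts <- rpois(sample(2:10, 1), lambda = sample(1:50, 1))
      if (all(counts == 0)) counts[1] <- 1
      w <- class_weights(counts)
      expect_equal(sum(w * counts) / sum(counts), 1)
    }
  })
})

test_that("the MLP separates a learnable two-class fixture", {
  feats <- make_feature_fixture(400, 2, flip = 0.02, seed = 31)
  test <- stratified_kfold(feats$label, k = 5, seed = 1) == 1
  fit <- train_mlp(feats[!test, ], mlp_config(epochs = 30, batch_size = 64,
                                              seed = 7))
  pr <- predict_proba(fit, feats[test, ])
  acc <- mean(photocatr:::.top1(pr) == feats$label[test])
  expect_gte(acc, 0.95)
  # training loss decreased
  expect_lt(tail(fit$training_report$loss, 1), fit$training_report$loss[1])
  expect_true(all(is.finite(fit$training_report$loss)))
})

test_that("training is deterministic for a fixed seed", {
  feats <- make_feature_fixture(120, 3, seed = 9)
  cfg <- mlp_config(epochs = 5, batch_size = 32, seed = 42)
  f1 <- train_mlp(feats, cfg)
  f2 <- train_mlp(feats, cfg)
  expect_identical(f1$training_report, f2$training_report)
  expect_identical(predict_proba(f1, feats), predict_proba(f2, feats))
})

test_that("shuffled labels give chance-level held-out accuracy", {
  feats <- make_feature_fixture(600, 4, flip = 0.02, seed = 13)
  feats$label <- withr::with_seed(77, sample(feats$label))
  test <- stratified_kfold(feats$label, k = 4, seed = 2) == 1
  fit <- train_mlp(feats[!test, ], mlp_config(epochs = 15, batch_size = 64,
                                              seed = 3))
  pr <- predict_proba(fit, feats[test, ])
  acc <- mean(photocatr:::.top1(pr) == feats$label[test])
  n_test <- sum(test)
  sigma <- sqrt(0.25 * 0.75 / n_test)
  expect_lt(abs(acc - 0.25), 3 * sigma + 0.05)
})

test_that("predicted probabilities are softmax-normalized", {
  feats <- make_feature_fixture(60, 3, seed = 5)
  fit <- train_mlp(feats, mlp_config(epochs = 3, seed = 1))
  withr::with_seed(10, {
    for (i in 1:10) {
      row <- feats[sample(nrow(feats), 1), ]
      row[, -1] <- as.list(as.integer(runif(128) > 0.5))
      pr <- predict_proba(fit, row)
      expect_equal(sum(pr), 1, tolerance = 1e-6)
      expect_true(all(pr > 0 & pr < 1))
    }
  })
  # argmax equals the top-1 of the derived ranking
  pr <- predict_proba(fit, feats)
  rk <- ranking(pr[1, ])
  expect_equal(rk$index[1], photocatr:::.top1(pr[1, , drop = FALSE]))
})

test_that("degenerate training inputs are refused", {
  feats <- make_feature_fixture(40, 2, seed = 2)
  feats$label <- 0L
  expect_error(train_mlp(feats, mlp_config(epochs = 2)), "two classes")
  feats2 <- make_feature_fixture(40, 2, seed = 2)
  expect_error(train_mlp(feats2, mlp_config(epochs = 2), n_classes = 1),
               "out of range")
})

test_that("weighting raises macro F1 on a 95:5 imbalanced fixture", {
  accs <- vapply(1:5, function(s) {
    feats <- make_feature_fixture(500, 2, flip = 0.12,
                                  class_prob = c(0.95, 0.05), seed = 100 + s)
    test <- stratified_kfold(feats$label, k = 5, seed = s) == 1
    out <- vapply(c(TRUE, FALSE), function(wt) {
      fit <- train_mlp(feats[!test, ],
                       mlp_config(epochs = 40, batch_size = nrow(feats),
                                  learning_rate = 5e-3, weighted = wt,
                                  seed = s))
      pr <- predict_proba(fit, feats[test, ])
      f1_scores(feats$label[test], photocatr:::.top1(pr), 2)$macro
    }, 0)
    out
  }, numeric(2))
  expect_gte(median(accs[1, ]), median(accs[2, ]))
})
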