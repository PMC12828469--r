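test_that("rankings sort by probability with index tie-breaks", {
  reg <- pc_registry()
  p <- rep(1 / 31, 31)
  rk <- ranking(p, reg)
  expect_identical(rk$index, 0:30)        # all tied -> ascending index
  expect_identical(rk$rank, 1:31)
  p2 <- p; p2[15] <- 0.5; p2 <- p2 / sum(p2)
  rk2 <- ranking(p2, reg)
  expect_equal(rk2$index[1], 14)
  expect_true(all(diff(rk2$confidence) <= 0))
  t5 <- top_k(rk2)
  expect_equal(nrow(t5), 5)
  expect_error(top_k(rk2, 0))
  expect_error(top_k(rk2, 32))
})

test_that("stratified folds are balanced, disjoint and deterministic", {
  labels <- rep(c(0, 1), each = 50)
  fold <- stratified_kfold(labels, k = 5, seed = 3)
  expect_identical(sort(unique(fold)), 1:5)
  expect_true(all(table(fold) == 20))
  for (f in 1:5) expect_true(all(table(labels[fold == f]) == 10))
  expect_identical(fold, stratified_kfold(labels, k = 5, seed = 3))
  expect_false(identical(fold, stratified_kfold(labels, k = 5, seed = 4)))
})

test_that("classes rarer than k are spread over distinct folds with a warning", {
  labels <- c(rep("common", 47), rep("rare", 3))
  expect_warning(fold <- stratified_kfold(labels, k = 5, seed = 1),
                 class = "photocatr_rare_class")
  expect_length(unique(fold[labels == "rare"]), 3)
  expect_true(all(abs(table(fold) - 10) <= 1))
})

test_that("f1 scores match hand-computed confusion fixtures", {
  perfect <- f1_scores(c(0, 1, 2, 0), c(0, 1, 2, 0), 3)
  expect_equal(perfect$macro, 1)
  expect_equal(perfect$weighted, 1)

  r <- f1_scores(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(r$per_class$f1, c(2 / 3, 4 / 5))
  expect_equal(r$macro, 11 / 15)
  expect_equal(r$weighted, 11 / 15)

  # predictor that never emits the rarest class: its F1 is 0 and macro drops
  # below weighted
  true <- c(rep(0, 8), rep(1, 8), rep(2, 2))
  pred <- c(rep(0, 8), rep(1, 8), rep(0, 2))
  r2 <- f1_scores(true, pred, 3)
  expect_equal(r2$per_class$f1[3], 0)
  expect_lt(r2$macro, r2$weighted)
  expect_error(f1_scores(integer(0), integer(0), 2))
})

test_that("top-k accuracy obeys its boundary identities", {
  withr::with_seed(6, {
    prob <- matrix(runif(40 * 7), 40)
    prob <- prob / rowSums(prob)
    true <- sample(0:6, 40, TRUE)
  })
  expect_equal(topk_accuracy(prob, true, 7), 1)
  acc1 <- topk_accuracy(prob, true, 1)
  expect_equal(acc1, mean(photocatr:::.top1(prob) == true))
  curve <- vapply(1:7, function(k) topk_accuracy(prob, true, k), 0)
  expect_true(all(diff(curve) >= 0))
  expect_error(topk_accuracy(prob, true, 0))
  expect_error(topk_accuracy(prob, true, 8))
})

test_that("top-k on uniform random probabilities matches the binomial null", {
  n <- 4000
  withr::with_seed(11, {
    prob <- matrix(runif(n * 31), n)
    prob <- prob / rowSums(prob)
    true <- sample(0:30, n, TRUE)
  })
  top5 <- topk_accuracy(prob, true, 5)
  p0 <- 5 / 31
  sigma <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(top5 - p0), 3 * sigma)
})

test_that("cross-validation reports are deterministic and well-formed", {
  feats <- make_feature_fixture(250, 3, flip = 0.01, seed = 17)
  builder <- mlp_builder(mlp_config(epochs = 20, batch_size = 50, seed = 5))
  cv1 <- cross_validate(feats, builder, k = 5, seed = 2)
  cv2 <- cross_validate(feats, builder, k = 5, seed = 2)
  expect_equal(cv1$per_fold, cv2$per_fold)
  expect_equal(nrow(cv1$per_fold), 5)
  expect_identical(cv1$summary$metric, c("accuracy", "f1_weighted", "f1_macro"))
  # noiseless, separable -> near-perfect recovery, and sd collapses
  expect_gte(cv1$summary$mean[1], 0.95)
  expect_true(all(cv1$topk_mean[length(cv1$topk_mean)] == 1))
  expect_true(all(diff(cv1$topk_mean) >= -1e-12))
  # serialization
  path <- tempfile(fileext = ".json")
  write_metrics(cv1, path)
  j <- jsonlite::fromJSON(path)
  expect_equal(j$k, 5)
  expect_equal(nrow(j$per_fold), 5)
  expect_equal(j$summary$mean[1], cv1$summary$mean[1])
})

test_that("tidy and glance summarize fitted objects", {
  feats <- make_feature_fixture(100, 2, seed = 23)
  fit <- train_mlp(feats, mlp_config(epochs = 4, seed = 1))
  td <- tidy(fit)
  expect_identical(names(td), c("epoch", "loss"))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(gl$epochs, 4)
  expect_gt(gl$n_parameters, 0)
  cv <- cross_validate(feats, mlp_builder(mlp_config(epochs = 4, seed = 1)),
                       k = 3, seed = 1)
  expect_equal(nrow(tidy(cv)), 3)
  expect_true(all(c("accuracy_mean", "top4") %in% names(glance(cv))))
})

test_that("the pooled confusion matrix is exported as CSV", {
  feats <- make_feature_fixture(150, 3, flip = 0.01, seed = 29)
  cv <- cross_validate(feats, mlp_builder(mlp_config(epochs = 10, seed = 2)),
                       k = 3, seed = 1)
  expect_equal(sum(cv$confusion), 150)
  expect_equal(dim(cv$confusion), c(3L, 3L))
  path <- tempfile(fileext = ".csv")
  write_confusion(cv, path)
  m <- read.csv(path)
  expect_equal(nrow(m), 3)
  expect_equal(sum(m[, -1]), 150)
})
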