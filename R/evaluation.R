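# Stratified k-fold cross-validation and the metric suite used to judge the
# recommenders: accuracy, weighted/macro F1 and top-k accuracy, plus the
# per-reaction ranking construction shared by every model.

.top1 <- function(prob) max.col(prob, ties.method = "first") - 1L

#' Build a catalyst ranking from a probability vector
#'
#' Catalysts sorted by descending probability; exact ties are broken by
#' ascending registry index so rankings are deterministic.
#'
#' @param probabilities numeric vector over the registry (sums to 1).
#' @param registry `pc_registry` supplying names; optional.
#' @return a `pc_ranking` tibble: `rank`, `index`, `name`, `confidence`.
#' @export
ranking <- function(probabilities, registry = NULL) {
  C <- length(probabilities)
  ord <- order(-probabilities, seq_len(C))
  out <- tibble::tibble(
    rank = seq_len(C),
    index = ord - 1L,
    name = if (!is.null(registry)) registry$name[ord] else as.character(ord - 1L),
    confidence = as.numeric(probabilities[ord])
  )
  class(out) <- c("pc_ranking", class(out))
  out
}

#' @rdname ranking
#' @param x a `pc_ranking`.
#' @param k list length (default 5, the recommendation list size).
#' @export
top_k <- function(x, k = 5L) {
  stopifnot(inherits(x, "pc_ranking"), k >= 1, k <= nrow(x))
  x[seq_len(k), ]
}

#' Stratified k-fold assignment
#'
#' Folds are balanced within +-1 record overall and per class. Classes with
#' fewer than `k` members are merged into a single auxiliary stratum for
#' splitting only (with a warning), which still spreads their members over
#' distinct folds.
#'
#' @param labels class label per record (any atomic type).
#' @param k number of folds (default 5).
#' @param seed RNG seed; assignment is deterministic given `seed`.
#' @return integer fold id (1..k) per record.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  n <- length(labels)
  stopifnot(k >= 2, n >= k)
  tab <- table(labels)
  rare <- names(tab)[tab < k]
  if (length(rare))
    rlang::warn(sprintf(
      "%d class(es) with fewer than %d members merged into one stratum for splitting",
      length(rare), k), class = "photocatr_rare_class")
  strata <- as.character(labels)
  strata[strata %in% rare] <- ".rare."
  fold <- integer(n)
  offset <- 0L
  withr::with_seed(seed, {
    for (s in sort(unique(strata))) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- (offset + length(idx)) %% k
    }
  })
  fold
}

#' Per-class, weighted and macro F1 scores
#'
#' Per-class `F1 = 2PR/(P+R)` with the 0/0 -> 0 convention; macro F1 is the
#' unweighted mean over classes present in the true labels, weighted F1 the
#' support-weighted mean.
#'
#' @param true,pred equal-length 0-based integer label vectors.
#' @param n_classes number of classes (default: largest label + 1).
#' @return list: `per_class` tibble (class, precision, recall, f1, support),
#'   `macro`, `weighted`.
#' @export
f1_scores <- function(true, pred, n_classes = max(c(true, pred)) + 1L) {
  stopifnot(length(true) == length(pred))
  if (!length(true)) rlang::abort("empty label vectors")
  per <- vapply(seq_len(n_classes) - 1L, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f1, tp + fn)
  }, numeric(4))
  per_class <- tibble::tibble(class = seq_len(n_classes) - 1L,
                              precision = per[1, ], recall = per[2, ],
                              f1 = per[3, ], support = as.integer(per[4, ]))
  present <- per_class$support > 0
  list(per_class = per_class,
       macro = mean(per_class$f1[present]),
       weighted = sum(per_class$f1[present] * per_class$support[present]) /
         sum(per_class$support[present]))
}

#' Top-k accuracy
#'
#' Fraction of records whose true label appears among the first `k` entries
#' of the row's ranking (descending probability, ties by ascending index).
#'
#' @param prob numeric matrix of row-normalized probabilities.
#' @param true 0-based integer labels.
#' @param k ranking depth, `1 <= k <= ncol(prob)`.
#' @return fraction in [0, 1].
#' @export
topk_accuracy <- function(prob, true, k) {
  C <- ncol(prob)
  if (k < 1 || k > C) rlang::abort("k out of range")
  hits <- vapply(seq_len(nrow(prob)), function(r) {
    ord <- order(-prob[r, ], seq_len(C))
    (true[r] + 1L) %in% ord[seq_len(k)]
  }, TRUE)
  mean(hits)
}

.topk_curve <- function(prob, true) {
  vapply(seq_len(ncol(prob)), function(k) topk_accuracy(prob, true, k), 0)
}

#' Stratified k-fold cross-validation of a model builder
#'
#' Trains `builder` on each training split, scores held-out predictions, and
#' aggregates per-fold accuracy, weighted/macro F1 and the full top-k curve
#' into mean +- sd (the headline reporting shape), alongside pooled
#' out-of-fold metrics.
#'
#' @param features labeled feature/record tibble; rows are records.
#' @param builder function(train_tibble) returning a fitted model understood
#'   by [predict_proba()] (e.g. [mlp_builder()]).
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param n_classes number of classes (default: largest label + 1).
#' @return a `pc_metrics` object; see [tidy()], [glance()],
#'   [ggplot2::autoplot()].
#' @export
cross_validate <- function(features, builder, k = 5L, seed = 1L,
                           n_classes = NULL) {
  y <- features$label
  if (is.null(n_classes)) n_classes <- max(y) + 1L
  fold <- stratified_kfold(y, k = k, seed = seed)
  per_fold <- vector("list", k)
  pooled_prob <- matrix(NA_real_, length(y), n_classes)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- builder(features[!test, , drop = FALSE])
    pr <- predict_proba(fit, features[test, , drop = FALSE])
    pooled_prob[test, ] <- pr
    pred <- .top1(pr)
    f1 <- f1_scores(y[test], pred, n_classes)
    per_fold[[f]] <- tibble::tibble(
      fold = f, n_test = sum(test),
      accuracy = mean(pred == y[test]),
      f1_weighted = f1$weighted, f1_macro = f1$macro,
      topk = list(.topk_curve(pr, y[test]))
    )
  }
  per_fold <- dplyr::bind_rows(per_fold)
  pooled_pred <- .top1(pooled_prob)
  pooled_f1 <- f1_scores(y, pooled_pred, n_classes)
  out <- list(
    per_fold = per_fold,
    summary = tibble::tibble(
      metric = c("accuracy", "f1_weighted", "f1_macro"),
      mean = c(mean(per_fold$accuracy), mean(per_fold$f1_weighted),
               mean(per_fold$f1_macro)),
      sd = c(stats::sd(per_fold$accuracy), stats::sd(per_fold$f1_weighted),
             stats::sd(per_fold$f1_macro))
    ),
    topk_mean = colMeans(do.call(rbind, per_fold$topk)),
    pooled = tibble::tibble(accuracy = mean(pooled_pred == y),
                            f1_weighted = pooled_f1$weighted,
                            f1_macro = pooled_f1$macro),
    confusion = table(true = factor(y, levels = 0:(n_classes - 1)),
                      pred = factor(pooled_pred, levels = 0:(n_classes - 1))),
    pooled_topk = .topk_curve(pooled_prob, y),
    n_classes = n_classes, k = k, seed = seed
  )
  class(out) <- "pc_metrics"
  out
}

#' Builder closure for [cross_validate()]
#'
#' @inheritParams train_mlp
#' @return function mapping a training tibble to a fitted `pc_mlp`.
#' @export
mlp_builder <- function(config = mlp_config(), n_classes = NULL,
                        registry = NULL) {
  force(config); force(n_classes); force(registry)
  function(train) train_mlp(train, config, n_classes = n_classes,
                            registry = registry)
}

#' @export
print.pc_metrics <- function(x, ...) {
  cat(sprintf("<pc_metrics: %d-fold CV, %d classes>\n", x$k, x$n_classes))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f +- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  cat(sprintf("  top-1/3/5 (fold mean): %.3f / %.3f / %.3f\n",
              x$topk_mean[1], x$topk_mean[min(3, length(x$topk_mean))],
              x$topk_mean[min(5, length(x$topk_mean))]))
  invisible(x)
}

#' @method tidy pc_metrics
#' @export
tidy.pc_metrics <- function(x, ...) {
  dplyr::select(x$per_fold, -"topk")
}

#' @method glance pc_metrics
#' @export
glance.pc_metrics <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    accuracy_mean = x$summary$mean[1], accuracy_sd = x$summary$sd[1],
    f1_weighted_mean = x$summary$mean[2], f1_weighted_sd = x$summary$sd[2],
    f1_macro_mean = x$summary$mean[3], f1_macro_sd = x$summary$sd[3],
    top1 = x$topk_mean[1],
    top4 = x$topk_mean[min(4, length(x$topk_mean))],
    pooled_accuracy = x$pooled$accuracy
  )
}

#' Write the pooled out-of-fold confusion matrix as CSV
#'
#' Rows are true classes, columns predicted classes (0-based registry
#' indices).
#'
#' @param x a `pc_metrics`.
#' @param path output CSV file.
#' @export
write_confusion <- function(x, path) {
  m <- as.data.frame.matrix(x$confusion)
  utils::write.csv(cbind(true = rownames(m), m), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a metrics report to JSON
#'
#' @param x a `pc_metrics`.
#' @param path output file.
#' @export
write_metrics <- function(x, path) {
  jsonlite::write_json(list(
    k = x$k, n_classes = x$n_classes,
    per_fold = dplyr::select(x$per_fold, -"topk"),
    per_fold_topk = do.call(rbind, x$per_fold$topk),
    summary = x$summary, topk_mean = x$topk_mean,
    pooled = x$pooled, pooled_topk = x$pooled_topk
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
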