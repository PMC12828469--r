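# Dual-input multilayer perceptron over (Morgan, DRFP) fingerprints.
#
# Architecture: each 64-bit input passes through its own hidden layer; the
# two hidden representations are concatenated, followed by two further
# hidden layers and a linear output layer producing one logit per registry
# entry; softmax turns logits into the ranking probabilities. Training uses
# weighted cross-entropy to counter class imbalance. All arithmetic is plain
# BLAS matrix algebra with a fixed seed, so reference mode is deterministic.

#' MLP configuration
#'
#' Hidden sizes, activation and merge follow fixed defaults (the published
#' model tuned these by search without reporting winners); every knob is
#' exposed here.
#'
#' @param hidden_dim_morgan,hidden_dim_drfp width of the per-input hidden
#'   layers.
#' @param hidden_dims_post widths of the two post-merge hidden layers.
#' @param activation `"relu"` (only supported value).
#' @param merge `"concatenate"` (only supported value).
#' @param epochs,batch_size,learning_rate Adam training scalars.
#' @param weighted use inverse-frequency class weights in the loss.
#' @param seed RNG seed for initialization and shuffling.
#' @export
mlp_config <- function(hidden_dim_morgan = 128L, hidden_dim_drfp = 128L,
                       hidden_dims_post = c(128L, 64L), activation = "relu",
                       merge = "concatenate", epochs = 50L, batch_size = 256L,
                       learning_rate = 1e-3, weighted = TRUE, seed = 1L) {
  stopifnot(length(hidden_dims_post) == 2, all(hidden_dims_post >= 1),
            hidden_dim_morgan >= 1, hidden_dim_drfp >= 1,
            activation == "relu", merge == "concatenate")
  structure(list(hidden_dim_morgan = hidden_dim_morgan,
                 hidden_dim_drfp = hidden_dim_drfp,
                 hidden_dims_post = hidden_dims_post, activation = activation,
                 merge = merge, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weighted = weighted,
                 seed = as.integer(seed)),
            class = "pc_mlp_config")
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (C_nonzero * n_c)` for observed classes, 0 for absent classes,
#' where `N` is the total count and `C_nonzero` the number of observed
#' classes. The weighted mean of the weights over observed samples is 1.
#'
#' @param label_counts non-negative per-class counts (at least one nonzero).
#' @return per-class weights.
#' @export
#' @examples
#' class_weights(c(30, 10))   # c(2/3, 2)
class_weights <- function(label_counts) {
  stopifnot(all(label_counts >= 0))
  if (all(label_counts == 0)) rlang::abort("all class counts are zero")
  N <- sum(label_counts)
  Cnz <- sum(label_counts > 0)
  ifelse(label_counts > 0, N / (Cnz * label_counts), 0)
}

.relu <- function(x) (x > 0) * x

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.init_mat <- function(nin, nout) {
  lim <- 1 / sqrt(nin)
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

.feature_matrices <- function(features) {
  mcols <- grep("^m[0-9]+$", names(features), value = TRUE)
  dcols <- grep("^d[0-9]+$", names(features), value = TRUE)
  if (!length(mcols) || !length(dcols))
    rlang::abort("feature table must contain m*/d* fingerprint columns (see featurize_reactions)")
  list(M = as.matrix(features[, mcols]), D = as.matrix(features[, dcols]))
}

.mlp_forward <- function(p, M, D) {
  H1 <- .relu(sweep(M %*% p$Wm, 2, p$bm, `+`))
  H2 <- .relu(sweep(D %*% p$Wd, 2, p$bd, `+`))
  X <- cbind(H1, H2)
  P1 <- .relu(sweep(X %*% p$W1, 2, p$b1, `+`))
  P2 <- .relu(sweep(P1 %*% p$W2, 2, p$b2, `+`))
  logits <- sweep(P2 %*% p$W3, 2, p$b3, `+`)
  list(H1 = H1, H2 = H2, X = X, P1 = P1, P2 = P2, logits = logits)
}

#' Train the dual-input MLP photocatalyst classifier
#'
#' @param features feature tibble from [featurize_reactions()] (binary `m*`
#'   and `d*` columns plus an integer `label` column of 0-based registry
#'   indices), or any tibble with those columns.
#' @param config an [mlp_config()].
#' @param n_classes output dimensionality; defaults to the registry size
#'   (31) when `registry` is supplied, else `max(label) + 1`.
#' @param registry optional `pc_registry` fixing the output dimension and
#'   names.
#' @return a `pc_mlp` with the learned weights and a per-epoch
#'   `training_report`; see [predict_proba()].
#' @export
train_mlp <- function(features, config = mlp_config(), n_classes = NULL,
                      registry = NULL) {
  fm <- .feature_matrices(features)
  y <- features$label
  stopifnot(!anyNA(y), all(y >= 0))
  if (is.null(n_classes))
    n_classes <- if (!is.null(registry)) nrow(registry) else max(y) + 1L
  if (length(unique(y)) < 2)
    rlang::abort("training data must contain at least two classes")
  if (max(y) >= n_classes) rlang::abort("label out of range for n_classes")

  counts <- tabulate(y + 1L, nbins = n_classes)
  w_class <- if (config$weighted) class_weights(counts) else rep(1, n_classes)

  n <- nrow(fm$M)
  withr::with_seed(config$seed, {
    p <- list(
      Wm = .init_mat(ncol(fm$M), config$hidden_dim_morgan),
      bm = numeric(config$hidden_dim_morgan),
      Wd = .init_mat(ncol(fm$D), config$hidden_dim_drfp),
      bd = numeric(config$hidden_dim_drfp),
      W1 = .init_mat(config$hidden_dim_morgan + config$hidden_dim_drfp,
                     config$hidden_dims_post[1]),
      b1 = numeric(config$hidden_dims_post[1]),
      W2 = .init_mat(config$hidden_dims_post[1], config$hidden_dims_post[2]),
      b2 = numeric(config$hidden_dims_post[2]),
      W3 = .init_mat(config$hidden_dims_post[2], n_classes),
      b3 = numeric(n_classes)
    )
    opt <- adam_init(p, lr = config$learning_rate)
    losses <- numeric(config$epochs)

    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_wsum <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        M <- fm$M[idx, , drop = FALSE]; D <- fm$D[idx, , drop = FALSE]
        yb <- y[idx]
        fw <- .mlp_forward(p, M, D)
        prob <- .softmax_rows(fw$logits)
        wb <- w_class[yb + 1L]
        pick <- cbind(seq_along(yb), yb + 1L)
        loss <- -sum(wb * log(pmax(prob[pick], 1e-12))) / sum(wb)
        if (!is.finite(loss))
          rlang::abort("non-finite training loss; lower the learning rate")
        ep_loss <- ep_loss + loss * sum(wb); ep_wsum <- ep_wsum + sum(wb)

        dlogits <- prob
        dlogits[pick] <- dlogits[pick] - 1
        dlogits <- dlogits * (wb / sum(wb))
        g <- list()
        g$W3 <- t(fw$P2) %*% dlogits; g$b3 <- colSums(dlogits)
        dP2 <- (dlogits %*% t(p$W3)) * (fw$P2 > 0)
        g$W2 <- t(fw$P1) %*% dP2; g$b2 <- colSums(dP2)
        dP1 <- (dP2 %*% t(p$W2)) * (fw$P1 > 0)
        g$W1 <- t(fw$X) %*% dP1; g$b1 <- colSums(dP1)
        dX <- dP1 %*% t(p$W1)
        h1 <- seq_len(config$hidden_dim_morgan)
        dH1 <- dX[, h1, drop = FALSE] * (fw$H1 > 0)
        dH2 <- dX[, -h1, drop = FALSE] * (fw$H2 > 0)
        g$Wm <- t(M) %*% dH1; g$bm <- colSums(dH1)
        g$Wd <- t(D) %*% dH2; g$bd <- colSums(dH2)
        upd <- adam_step(opt, p, g)
        p <- upd$params; opt <- upd$state
      }
      losses[ep] <- ep_loss / ep_wsum
    }
  })

  structure(list(params = p, config = config, n_classes = n_classes,
                 registry = registry, class_weights = w_class,
                 training_report = tibble::tibble(epoch = seq_len(config$epochs),
                                                  loss = losses)),
            class = "pc_mlp")
}

#' Class-probability predictions
#'
#' Softmax over the model logits: every row lies in (0,1) and sums to 1.
#'
#' @param model a fitted `pc_mlp` or `pc_lm_classifier`.
#' @param features feature tibble (for the MLP) or record/pair tibble (for
#'   the transformer classifier).
#' @return numeric matrix, one row per input, `n_classes` columns.
#' @export
predict_proba <- function(model, features) UseMethod("predict_proba")

#' @export
predict_proba.pc_mlp <- function(model, features) {
  fm <- .feature_matrices(features)
  if (ncol(fm$M) != nrow(model$params$Wm) || ncol(fm$D) != nrow(model$params$Wd))
    rlang::abort("feature dimensionality does not match the trained model")
  fw <- .mlp_forward(model$params, fm$M, fm$D)
  pr <- .softmax_rows(fw$logits)
  if (!is.null(model$registry)) colnames(pr) <- model$registry$name
  pr
}

#' @export
print.pc_mlp <- function(x, ...) {
  cat(sprintf(
    "<pc_mlp: %d classes, hidden %d+%d -> [%s], %d epochs, final loss %.4f>\n",
    x$n_classes, x$config$hidden_dim_morgan, x$config$hidden_dim_drfp,
    paste(x$config$hidden_dims_post, collapse = ", "),
    x$config$epochs, utils::tail(x$training_report$loss, 1)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy pc_mlp
#' @export
tidy.pc_mlp <- function(x, ...) x$training_report

#' @method glance pc_mlp
#' @export
glance.pc_mlp <- function(x, ...) {
  tibble::tibble(
    n_classes = x$n_classes,
    epochs = x$config$epochs,
    n_parameters = sum(vapply(x$params, length, 0L)),
    first_epoch_loss = x$training_report$loss[1],
    final_loss = utils::tail(x$training_report$loss, 1)
  )
}

#' Small random search over MLP hyperparameters
#'
#' Optional helper mirroring the kind of search used to fix the defaults:
#' samples hidden sizes and learning rates, scores each draw by held-out
#' accuracy on a stratified 80/20 split, and returns the draws ranked.
#'
#' @param features labeled feature tibble.
#' @param n_draws number of configurations to try.
#' @param seed RNG seed.
#' @inheritParams train_mlp
#' @return tibble of sampled configurations with held-out accuracy.
#' @export
mlp_random_search <- function(features, n_draws = 5L, seed = 1L,
                              n_classes = NULL, registry = NULL) {
  draws <- withr::with_seed(seed, tibble::tibble(
    hidden = sample(c(32L, 64L, 128L, 256L), n_draws, replace = TRUE),
    post1 = sample(c(64L, 128L), n_draws, replace = TRUE),
    post2 = sample(c(32L, 64L), n_draws, replace = TRUE),
    lr = 10^stats::runif(n_draws, -3.5, -2.5)
  ))
  folds <- stratified_kfold(features$label, k = 5L, seed = seed)
  test <- folds == 1L
  acc <- vapply(seq_len(n_draws), function(i) {
    cfg <- mlp_config(hidden_dim_morgan = draws$hidden[i],
                      hidden_dim_drfp = draws$hidden[i],
                      hidden_dims_post = c(draws$post1[i], draws$post2[i]),
                      learning_rate = draws$lr[i], epochs = 30L, seed = seed)
    fit <- train_mlp(features[!test, ], cfg, n_classes = n_classes,
                     registry = registry)
    pr <- predict_proba(fit, features[test, ])
    mean(.top1(pr) == features$label[test])
  }, 0)
  dplyr::arrange(dplyr::mutate(draws, accuracy = acc), dplyr::desc(.data$accuracy))
}
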