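# Scaled-down RoBERTa-style masked-language-model pipeline: two-sentence
# (core, reaction) encoding, static masking, transformer encoder with
# learned positional and segment embeddings, MLM pretraining head and a
# classification head over the catalyst registry. Forward and backward
# passes are explicit matrix algebra (single-threaded BLAS), so training is
# bit-reproducible for a fixed seed.

#' Language-model configuration
#'
#' Reference defaults are deliberately small (2 layers, 2 heads, embedding
#' 64, input length 128) so that pretraining plus fine-tuning on the
#' synthetic corpus runs in minutes on one CPU; the published input length
#' of 1024 and larger encoders are reachable through these fields.
#'
#' @param layers,heads,embed_dim,ffn_dim transformer encoder sizes
#'   (`embed_dim` divisible by `heads`).
#' @param max_len padded input length in tokens.
#' @param vocab_size tokenizer vocabulary size.
#' @param mask_rate fraction of non-special tokens statically masked
#'   (default 0.15).
#' @param pretrain_epochs MLM pretraining epochs (default 2).
#' @param finetune_epochs classification fine-tuning epochs (default 10).
#' @param learning_rate,batch_size Adam training scalars.
#' @param weighted use inverse-frequency class weights during fine-tuning
#'   (default off).
#' @param bert_split use the BERT-style 80/10/10 mask/random/keep split
#'   instead of pure mask-token replacement.
#' @param seed RNG seed.
#' @export
lm_config <- function(layers = 2L, heads = 2L, embed_dim = 64L,
                      ffn_dim = 128L, max_len = 128L, vocab_size = 288L,
                      mask_rate = 0.15, pretrain_epochs = 2L,
                      finetune_epochs = 10L, learning_rate = 1e-3,
                      batch_size = 8L, weighted = FALSE, bert_split = FALSE,
                      seed = 1L) {
  stopifnot(mask_rate > 0, mask_rate < 1, embed_dim %% heads == 0,
            layers >= 1, max_len >= 8)
  structure(list(layers = as.integer(layers), heads = as.integer(heads),
                 embed_dim = as.integer(embed_dim), ffn_dim = as.integer(ffn_dim),
                 max_len = as.integer(max_len), vocab_size = as.integer(vocab_size),
                 mask_rate = mask_rate, pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 weighted = weighted, bert_split = bert_split,
                 seed = as.integer(seed)),
            class = "pc_lm_config")
}

#' Two-sentence encoding of a (core, reaction) pair
#'
#' Layout `[CLS] core [SEP] reaction [SEP] [PAD]...`, padded to `max_len`.
#' An empty core (identity reaction) degenerates to `[CLS][SEP] reaction
#' [SEP]`. Over-length inputs are truncated on the right of the reaction
#' sentence only, never the core.
#'
#' @param core_smiles core reaction SMILES (sentence A; may be empty).
#' @param reaction_smiles full reaction SMILES (sentence B).
#' @param tok a `pc_tokenizer`.
#' @param max_len padded length.
#' @return a `pc_encoding`: list with 0-based `ids` (length `max_len`),
#'   `seg` (0 = sentence A, 1 = sentence B), `special` (logical),
#'   `len` (non-pad length), `truncated`.
#' @export
encode_two_sentence <- function(core_smiles, reaction_smiles, tok,
                                max_len = 128L) {
  sp <- tok$specials
  a <- if (nzchar(core_smiles)) tokenizer_encode(tok, core_smiles) else integer(0)
  b <- tokenizer_encode(tok, reaction_smiles)
  if (length(a) + 3L > max_len)
    rlang::abort("core sentence alone exceeds max_len; raise max_len")
  avail <- max_len - 3L - length(a)
  truncated <- length(b) > avail
  if (truncated) b <- b[seq_len(avail)]
  ids <- c(sp[["[CLS]"]], a, sp[["[SEP]"]], b, sp[["[SEP]"]])
  len <- length(ids)
  seg <- c(rep(0L, length(a) + 2L), rep(1L, length(b) + 1L))
  special <- c(TRUE, rep(FALSE, length(a)), TRUE, rep(FALSE, length(b)), TRUE)
  pad <- max_len - len
  structure(list(ids = c(ids, rep(sp[["[PAD]"]], pad)),
                 seg = c(seg, rep(0L, pad)),
                 special = c(special, rep(TRUE, pad)),
                 len = len, truncated = truncated),
            class = "pc_encoding")
}

#' Statically mask an encoding
#'
#' Each non-special token position is masked independently with probability
#' `mask_rate`; masked positions are replaced by the mask token (pure
#' replacement by default; BERT-style 80/10/10 behind `bert_split`) and the
#' original ids become the prediction labels. The selection is drawn once
#' per corpus build (static masking): rebuilding with the same seed yields
#' identical mask positions.
#'
#' @param enc a `pc_encoding`.
#' @param tok the `pc_tokenizer` (supplies the mask token id).
#' @param mask_rate masking probability (default 0.15).
#' @param bert_split 80/10/10 split flag.
#' @return the encoding with `input_ids`, `labels` (NA except at masked
#'   positions) and `mask_positions` added.
#' @export
apply_static_mask <- function(enc, tok, mask_rate = 0.15, bert_split = FALSE) {
  cand <- which(!enc$special)
  input <- enc$ids
  labels <- rep(NA_integer_, length(input))
  sel <- integer(0)
  if (length(cand)) {
    sel <- cand[stats::runif(length(cand)) < mask_rate]
    if (length(sel)) {
      labels[sel] <- input[sel]
      if (!bert_split) {
        input[sel] <- tok$specials[["[MASK]"]]
      } else {
        u <- stats::runif(length(sel))
        mask_it <- u < 0.8
        rand_it <- u >= 0.8 & u < 0.9
        input[sel[mask_it]] <- tok$specials[["[MASK]"]]
        if (any(rand_it))
          input[sel[rand_it]] <- sample.int(tok$vocab_size, sum(rand_it)) - 1L
      }
    }
  } else {
    rlang::warn("encoding has no non-special tokens; nothing masked")
  }
  enc$input_ids <- input
  enc$labels <- labels
  enc$mask_positions <- sel
  enc
}

#' @rdname apply_static_mask
#' @param encodings list of `pc_encoding`.
#' @param seed RNG seed for the one-off static selection.
#' @export
build_masked_corpus <- function(encodings, tok, mask_rate = 0.15, seed = 1L,
                                bert_split = FALSE) {
  withr::with_seed(seed, lapply(encodings, apply_static_mask, tok = tok,
                                mask_rate = mask_rate,
                                bert_split = bert_split))
}

# ---- transformer internals ---------------------------------------------------

.lm_init_params <- function(cfg, n_classes = NULL) {
  d <- cfg$embed_dim; f <- cfg$ffn_dim; V <- cfg$vocab_size
  nm <- function(r, c) matrix(stats::rnorm(r * c, sd = 0.02), r, c)
  p <- list(E = nm(V, d), P = nm(cfg$max_len, d), S = nm(2, d))
  for (l in seq_len(cfg$layers)) {
    p[[paste0("l", l, "_Wq")]] <- nm(d, d)
    p[[paste0("l", l, "_Wk")]] <- nm(d, d)
    p[[paste0("l", l, "_Wv")]] <- nm(d, d)
    p[[paste0("l", l, "_Wo")]] <- nm(d, d)
    p[[paste0("l", l, "_g1")]] <- rep(1, d)
    p[[paste0("l", l, "_b1")]] <- rep(0, d)
    p[[paste0("l", l, "_W1")]] <- nm(d, f)
    p[[paste0("l", l, "_c1")]] <- rep(0, f)
    p[[paste0("l", l, "_W2")]] <- nm(f, d)
    p[[paste0("l", l, "_c2")]] <- rep(0, d)
    p[[paste0("l", l, "_g2")]] <- rep(1, d)
    p[[paste0("l", l, "_b2")]] <- rep(0, d)
  }
  p$Wm <- nm(d, V); p$bm <- rep(0, V)
  if (!is.null(n_classes)) { p$Wc <- nm(d, n_classes); p$bc <- rep(0, n_classes) }
  p
}

.ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  v <- rowMeans((x - mu)^2)
  sd <- sqrt(v + eps)
  xhat <- (x - mu) / sd
  list(y = sweep(sweep(xhat, 2, g, `*`), 2, b, `+`), xhat = xhat, sd = sd)
}

.ln_backward <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- (dxhat - m1 - cache$xhat * m2) / cache$sd
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

.lm_forward <- function(p, cfg, enc_ids, seg, T) {
  d <- cfg$embed_dim; H <- cfg$heads; dh <- d %/% H
  ids1 <- enc_ids[seq_len(T)] + 1L
  seg1 <- seg[seq_len(T)] + 1L
  X <- p$E[ids1, , drop = FALSE] + p$P[seq_len(T), , drop = FALSE] +
    p$S[seg1, , drop = FALSE]
  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    pre <- function(s) p[[paste0("l", l, "_", s)]]
    Q <- X %*% pre("Wq"); K <- X %*% pre("Wk"); V <- X %*% pre("Wv")
    Aout <- matrix(0, T, d)
    Ahat <- vector("list", H)
    for (h in seq_len(H)) {
      ix <- ((h - 1L) * dh + 1L):(h * dh)
      Z <- (Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE])) / sqrt(dh)
      Z <- Z - apply(Z, 1, max)
      A <- exp(Z); A <- A / rowSums(A)
      Ahat[[h]] <- A
      Aout[, ix] <- A %*% V[, ix, drop = FALSE]
    }
    O <- Aout %*% pre("Wo")
    R1 <- X + O
    ln1 <- .ln_forward(R1, pre("g1"), pre("b1"))
    X1 <- ln1$y
    Hpre <- sweep(X1 %*% pre("W1"), 2, pre("c1"), `+`)
    Hact <- .relu(Hpre)
    Fout <- sweep(Hact %*% pre("W2"), 2, pre("c2"), `+`)
    R2 <- X1 + Fout
    ln2 <- .ln_forward(R2, pre("g2"), pre("b2"))
    caches[[l]] <- list(X = X, Q = Q, K = K, V = V, Ahat = Ahat, Aout = Aout,
                        ln1 = ln1, X1 = X1, Hpre = Hpre, Hact = Hact,
                        ln2 = ln2)
    X <- ln2$y
  }
  list(X = X, caches = caches, ids1 = ids1, seg1 = seg1, T = T)
}

# dX: gradient at the encoder output; accumulates into `acc` (environment of
# zero-initialized grads with the same names as params).
.lm_backward <- function(p, cfg, fw, dX, acc) {
  d <- cfg$embed_dim; H <- cfg$heads; dh <- d %/% H
  T <- fw$T
  for (l in rev(seq_len(cfg$layers))) {
    nm <- function(s) paste0("l", l, "_", s)
    pre <- function(s) p[[nm(s)]]
    cc <- fw$caches[[l]]
    ln2b <- .ln_backward(dX, cc$ln2, pre("g2"))
    acc[[nm("g2")]] <- acc[[nm("g2")]] + ln2b$dg
    acc[[nm("b2")]] <- acc[[nm("b2")]] + ln2b$db
    dR2 <- ln2b$dx
    dFout <- dR2
    acc[[nm("W2")]] <- acc[[nm("W2")]] + t(cc$Hact) %*% dFout
    acc[[nm("c2")]] <- acc[[nm("c2")]] + colSums(dFout)
    dHact <- dFout %*% t(pre("W2"))
    dHpre <- dHact * (cc$Hpre > 0)
    acc[[nm("W1")]] <- acc[[nm("W1")]] + t(cc$X1) %*% dHpre
    acc[[nm("c1")]] <- acc[[nm("c1")]] + colSums(dHpre)
    dX1 <- dR2 + dHpre %*% t(pre("W1"))
    ln1b <- .ln_backward(dX1, cc$ln1, pre("g1"))
    acc[[nm("g1")]] <- acc[[nm("g1")]] + ln1b$dg
    acc[[nm("b1")]] <- acc[[nm("b1")]] + ln1b$db
    dR1 <- ln1b$dx
    dO <- dR1
    acc[[nm("Wo")]] <- acc[[nm("Wo")]] + t(cc$Aout) %*% dO
    dAout <- dO %*% t(pre("Wo"))
    dQ <- matrix(0, T, d); dK <- matrix(0, T, d); dV <- matrix(0, T, d)
    for (h in seq_len(H)) {
      ix <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cc$Ahat[[h]]
      dAh <- dAout[, ix, drop = FALSE]
      dVh <- t(A) %*% dAh
      dA <- dAh %*% t(cc$V[, ix, drop = FALSE])
      dZ <- A * (dA - rowSums(dA * A))
      dQ[, ix] <- (dZ %*% cc$K[, ix, drop = FALSE]) / sqrt(dh)
      dK[, ix] <- (t(dZ) %*% cc$Q[, ix, drop = FALSE]) / sqrt(dh)
      dV[, ix] <- dVh
    }
    acc[[nm("Wq")]] <- acc[[nm("Wq")]] + t(cc$X) %*% dQ
    acc[[nm("Wk")]] <- acc[[nm("Wk")]] + t(cc$X) %*% dK
    acc[[nm("Wv")]] <- acc[[nm("Wv")]] + t(cc$X) %*% dV
    dX <- dR1 + dQ %*% t(pre("Wq")) + dK %*% t(pre("Wk")) + dV %*% t(pre("Wv"))
  }
  # embeddings
  for (t in seq_len(T)) {
    acc$E[fw$ids1[t], ] <- acc$E[fw$ids1[t], ] + dX[t, ]
    acc$S[fw$seg1[t], ] <- acc$S[fw$seg1[t], ] + dX[t, ]
  }
  acc$P[seq_len(T), ] <- acc$P[seq_len(T), , drop = FALSE] + dX
  invisible(acc)
}

.zero_grads <- function(p) {
  acc <- new.env(parent = emptyenv())
  for (nm in names(p)) acc[[nm]] <- p[[nm]] * 0
  acc
}

.grads_list <- function(acc, p) {
  out <- lapply(names(p), function(nm) acc[[nm]])
  names(out) <- names(p)
  out
}

.softmax_vecrows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# masked-token cross-entropy (and gradient at the encoder output if acc
# is supplied) for one masked encoding
.mlm_example <- function(p, cfg, menc, acc = NULL, scale = 1) {
  pos <- menc$mask_positions
  pos <- pos[pos <= menc$len]
  if (!length(pos)) return(list(loss = 0, n = 0L, correct = 0L))
  fw <- .lm_forward(p, cfg, menc$input_ids, menc$seg, menc$len)
  Xp <- fw$X[pos, , drop = FALSE]
  logits <- sweep(Xp %*% p$Wm, 2, p$bm, `+`)
  pr <- .softmax_vecrows(logits)
  tgt <- menc$labels[pos] + 1L
  pick <- cbind(seq_along(pos), tgt)
  loss <- -sum(log(pmax(pr[pick], 1e-12)))
  correct <- sum(max.col(pr, ties.method = "first") == tgt)
  if (!is.null(acc)) {
    dlog <- pr
    dlog[pick] <- dlog[pick] - 1
    dlog <- dlog * scale
    acc$Wm <- acc$Wm + t(Xp) %*% dlog
    acc$bm <- acc$bm + colSums(dlog)
    dX <- matrix(0, fw$T, cfg$embed_dim)
    dX[pos, ] <- dlog %*% t(p$Wm)
    .lm_backward(p, cfg, fw, dX, acc)
  }
  list(loss = loss, n = length(pos), correct = correct)
}

.cls_example <- function(p, cfg, enc, label1 = NULL, acc = NULL, scale = 1,
                         weight = 1) {
  ids <- enc$input_ids %||% enc$ids
  fw <- .lm_forward(p, cfg, ids, enc$seg, enc$len)
  h <- fw$X[1, , drop = FALSE]
  logits <- h %*% p$Wc + matrix(p$bc, 1)
  pr <- .softmax_vecrows(logits)
  out <- list(prob = as.numeric(pr))
  if (!is.null(label1)) {
    out$loss <- -weight * log(max(pr[1, label1], 1e-12))
    if (!is.null(acc)) {
      dlog <- pr
      dlog[1, label1] <- dlog[1, label1] - 1
      dlog <- dlog * scale * weight
      acc$Wc <- acc$Wc + t(h) %*% dlog
      acc$bc <- acc$bc + colSums(dlog)
      dX <- matrix(0, fw$T, cfg$embed_dim)
      dX[1, ] <- dlog %*% t(p$Wc)
      .lm_backward(p, cfg, fw, dX, acc)
    }
  }
  out
}

# ---- training entry points ---------------------------------------------------

#' Masked-language-model pretraining on (core, reaction) pairs
#'
#' Trains the tokenizer (unless given), builds two-sentence encodings,
#' statically masks 15% of non-special tokens once, and minimizes
#' masked-token cross-entropy for `pretrain_epochs` epochs. Held-out pairs
#' (the `holdout` column of [corpus_for_pretraining()], or a trailing 10%
#' slice) are never trained on; their masked loss is evaluated for the
#' untrained model (epoch-0 baseline) and after every epoch.
#'
#' @param pairs tibble with `core_smiles`, `reaction_smiles` and optional
#'   logical `holdout`.
#' @param config an [lm_config()].
#' @param tokenizer optional pre-trained `pc_tokenizer`.
#' @return a `pc_lm`: encoder weights, tokenizer, config, per-epoch report
#'   (`train_loss`, `holdout_loss`, `holdout_acc`).
#' @export
pretrain_mlm <- function(pairs, config = lm_config(), tokenizer = NULL) {
  stopifnot(nrow(pairs) > 0)
  tok <- tokenizer %||%
    train_tokenizer(unique(c(pairs$core_smiles, pairs$reaction_smiles)),
                    vocab_size = config$vocab_size)
  if (tok$vocab_size != config$vocab_size)
    config$vocab_size <- tok$vocab_size
  encs <- purrr::map2(pairs$core_smiles, pairs$reaction_smiles,
                      encode_two_sentence, tok = tok,
                      max_len = config$max_len)
  masked <- build_masked_corpus(encs, tok, mask_rate = config$mask_rate,
                                seed = config$seed)
  hold <- if ("holdout" %in% names(pairs)) which(pairs$holdout)
    else utils::tail(seq_len(nrow(pairs)), max(1L, nrow(pairs) %/% 10L))
  train_ix <- setdiff(seq_len(nrow(pairs)), hold)

  withr::with_seed(config$seed, {
    p <- .lm_init_params(config)
    opt <- adam_init(p, lr = config$learning_rate)
    eval_hold <- function() {
      tot <- 0; nn <- 0L; cor <- 0L
      for (i in hold) {
        r <- .mlm_example(p, config, masked[[i]])
        tot <- tot + r$loss; nn <- nn + r$n; cor <- cor + r$correct
      }
      c(loss = tot / max(1L, nn), acc = cor / max(1L, nn))
    }
    base <- eval_hold()
    report <- tibble::tibble(epoch = 0L, train_loss = NA_real_,
                             holdout_loss = base[["loss"]],
                             holdout_acc = base[["acc"]])
    for (ep in seq_len(config$pretrain_epochs)) {
      ord <- sample(train_ix)
      ep_loss <- 0; ep_n <- 0L
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, length(ord))]
        acc <- .zero_grads(p)
        n_masked <- sum(vapply(masked[idx], function(m)
          length(m$mask_positions), 0L))
        if (n_masked == 0L) next
        for (i in idx) {
          r <- .mlm_example(p, config, masked[[i]], acc, scale = 1 / n_masked)
          ep_loss <- ep_loss + r$loss; ep_n <- ep_n + r$n
        }
        upd <- adam_step(opt, p, .grads_list(acc, p))
        p <- upd$params; opt <- upd$state
      }
      tr <- ep_loss / max(1L, ep_n)
      if (!is.finite(tr) || tr > 10 * base[["loss"]])
        rlang::abort("masked-LM training diverged")
      h <- eval_hold()
      report <- dplyr::bind_rows(report, tibble::tibble(
        epoch = ep, train_loss = tr, holdout_loss = h[["loss"]],
        holdout_acc = h[["acc"]]))
    }
  })

  structure(list(params = p, config = config, tokenizer = tok,
                 report = report), class = "pc_lm")
}

#' Masked-token loss of a model on masked encodings
#'
#' @param model a `pc_lm` (or `pc_lm_classifier` carrying encoder weights).
#' @param masked list of masked encodings from [build_masked_corpus()].
#' @return tibble with `loss` (mean masked cross-entropy) and `accuracy`
#'   (masked-token top-1 recovery).
#' @export
lm_masked_loss <- function(model, masked) {
  tot <- 0; nn <- 0L; cor <- 0L
  for (m in masked) {
    r <- .mlm_example(model$params, model$config, m)
    tot <- tot + r$loss; nn <- nn + r$n; cor <- cor + r$correct
  }
  tibble::tibble(loss = tot / max(1L, nn), accuracy = cor / max(1L, nn))
}

#' Fine-tune a catalyst classifier
#'
#' Adds a linear head on the pooled first-position representation and trains
#' for `finetune_epochs` epochs with (optionally class-weighted)
#' cross-entropy. Starting from a pretrained encoder is the intended path;
#' `pretrained = NULL` trains from random initialization (the ablation
#' baseline), in which case a tokenizer must be supplied or is trained on
#' the fine-tuning strings.
#'
#' @param data tibble with `core_smiles`, `reaction_smiles` and 0-based
#'   integer `label`.
#' @param registry `pc_registry` defining the output dimension.
#' @param config an [lm_config()]; when `pretrained` is given its encoder
#'   sizes override these fields.
#' @param pretrained optional `pc_lm` from [pretrain_mlm()].
#' @param tokenizer tokenizer override when `pretrained = NULL`.
#' @return a `pc_lm_classifier`.
#' @export
finetune_classifier <- function(data, registry, config = lm_config(),
                                pretrained = NULL, tokenizer = NULL) {
  stopifnot(all(data$label >= 0), all(data$label < nrow(registry)))
  n_classes <- nrow(registry)
  if (!is.null(pretrained)) {
    tok <- pretrained$tokenizer
    base_cfg <- pretrained$config
    base_cfg$finetune_epochs <- config$finetune_epochs
    base_cfg$learning_rate <- config$learning_rate
    base_cfg$batch_size <- config$batch_size
    base_cfg$weighted <- config$weighted
    base_cfg$seed <- config$seed
    config <- base_cfg
  } else {
    tok <- tokenizer %||%
      train_tokenizer(unique(c(data$core_smiles, data$reaction_smiles)),
                      vocab_size = config$vocab_size)
    config$vocab_size <- tok$vocab_size
  }
  encs <- purrr::map2(data$core_smiles, data$reaction_smiles,
                      encode_two_sentence, tok = tok,
                      max_len = config$max_len)
  y1 <- data$label + 1L
  counts <- tabulate(y1, nbins = n_classes)
  w_class <- if (config$weighted) class_weights(counts) else rep(1, n_classes)

  withr::with_seed(config$seed, {
    p <- .lm_init_params(config, n_classes = n_classes)
    if (!is.null(pretrained)) {
      for (nm in names(pretrained$params)) p[[nm]] <- pretrained$params[[nm]]
    }
    opt <- adam_init(p, lr = config$learning_rate)
    losses <- numeric(config$finetune_epochs)
    n <- nrow(data)
    for (ep in seq_len(config$finetune_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_w <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        acc <- .zero_grads(p)
        wsum <- sum(w_class[y1[idx]])
        for (i in idx) {
          r <- .cls_example(p, config, encs[[i]], label1 = y1[i], acc = acc,
                            scale = 1 / wsum, weight = w_class[y1[i]])
          ep_loss <- ep_loss + r$loss
        }
        ep_w <- ep_w + wsum
        upd <- adam_step(opt, p, .grads_list(acc, p))
        p <- upd$params; opt <- upd$state
      }
      losses[ep] <- ep_loss / ep_w
      if (!is.finite(losses[ep])) rlang::abort("fine-tuning diverged")
    }
  })

  structure(list(params = p, config = config, tokenizer = tok,
                 registry = registry, n_classes = n_classes,
                 training_report = tibble::tibble(
                   epoch = seq_len(config$finetune_epochs), loss = losses),
                 pretrained = !is.null(pretrained)),
            class = "pc_lm_classifier")
}

#' @export
predict_proba.pc_lm_classifier <- function(model, features) {
  encs <- purrr::map2(features$core_smiles, features$reaction_smiles,
                      encode_two_sentence, tok = model$tokenizer,
                      max_len = model$config$max_len)
  out <- t(vapply(encs, function(e)
    .cls_example(model$params, model$config, e)$prob,
    numeric(model$n_classes)))
  colnames(out) <- model$registry$name
  out
}

#' @export
print.pc_lm <- function(x, ...) {
  last <- utils::tail(x$report, 1)
  cat(sprintf(
    "<pc_lm: %d layers, %d heads, embed %d; holdout masked loss %.3f -> %.3f>\n",
    x$config$layers, x$config$heads, x$config$embed_dim,
    x$report$holdout_loss[1], last$holdout_loss))
  invisible(x)
}

#' @method tidy pc_lm
#' @export
tidy.pc_lm <- function(x, ...) x$report

#' @export
print.pc_lm_classifier <- function(x, ...) {
  cat(sprintf("<pc_lm_classifier: %d classes, %s encoder, final loss %.4f>\n",
              x$n_classes,
              if (x$pretrained) "pretrained" else "randomly initialized",
              utils::tail(x$training_report$loss, 1)))
  invisible(x)
}

#' @method tidy pc_lm_classifier
#' @export
tidy.pc_lm_classifier <- function(x, ...) x$training_report

#' Save / load language-model objects
#'
#' Checkpoints are self-describing single-file archives (config, tokenizer,
#' registry when present, and weights); reloading reproduces evaluation
#' losses exactly.
#'
#' @param model a `pc_lm` or `pc_lm_classifier`.
#' @param path file path.
#' @export
write_lm <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_lm
#' @export
read_lm <- function(path) readRDS(path)
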