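test_that("two-sentence encodings have the documented layout", {
  tok <- train_tokenizer(c("CCO>>CC=O", "CC>>C=C"), vocab_size = 265)
  sp <- tok$specials
  enc <- encode_two_sentence("C>>C=O", "CCO>>CC=O", tok, max_len = 48)
  expect_length(enc$ids, 48)
  expect_equal(enc$ids[1], sp[["[CLS]"]])
  expect_equal(sum(enc$ids[seq_len(enc$len)] == sp[["[SEP]"]]), 2)
  expect_equal(enc$ids[enc$len], sp[["[SEP]"]])
  expect_true(all(enc$ids[(enc$len + 1):48] == sp[["[PAD]"]]))
  # segments: sentence A (with [CLS] and first [SEP]) is 0, sentence B is 1
  expect_equal(enc$seg[1], 0)
  expect_equal(enc$seg[enc$len], 1)

  # identity reaction: empty core degenerates to [CLS][SEP] reaction [SEP]
  enc0 <- encode_two_sentence("", "CCO>>CCO", tok, max_len = 48)
  expect_equal(enc0$ids[2], sp[["[SEP]"]])
  expect_false(enc0$truncated)

  # over-length input truncates sentence B only
  long_b <- paste(rep("CCO.", 40), collapse = "")
  encT <- encode_two_sentence("C>>C=O", long_b, tok, max_len = 32)
  expect_true(encT$truncated)
  expect_equal(encT$len, 32)
  a_ids <- tokenizer_encode(tok, "C>>C=O")
  expect_identical(encT$ids[2:(1 + length(a_ids))], a_ids)  # core intact
  expect_error(encode_two_sentence(strrep("C", 60), "CC>>CC", tok,
                                   max_len = 32), "max_len")
})

test_that("static masking is rate-faithful, seed-stable and avoids specials", {
  tok <- train_tokenizer(c("CCO>>CC=O"), vocab_size = 263)
  enc <- encode_two_sentence("C>>C=O", "CCO>>CC=O", tok, max_len = 64)
  none <- withr::with_seed(1, apply_static_mask(enc, tok, mask_rate = 1e-9))
  expect_length(none$mask_positions, 0)

  m1 <- build_masked_corpus(list(enc, enc, enc), tok, mask_rate = 0.3,
                            seed = 9)
  m2 <- build_masked_corpus(list(enc, enc, enc), tok, mask_rate = 0.3,
                            seed = 9)
  expect_identical(lapply(m1, `[[`, "mask_positions"),
                   lapply(m2, `[[`, "mask_positions"))
  for (m in m1) {
    expect_false(any(enc$special[m$mask_positions]))
    expect_true(all(m$input_ids[m$mask_positions] == tok$specials[["[MASK]"]]))
    expect_identical(m$labels[m$mask_positions], enc$ids[m$mask_positions])
    expect_true(all(is.na(m$labels[-m$mask_positions])))
  }
})

test_that("transformer gradients match finite differences", {
  cfg <- lm_config(layers = 2, heads = 2, embed_dim = 8, ffn_dim = 12,
                   max_len = 16, vocab_size = 264, seed = 7)
  tok <- train_tokenizer(c("CCO>>CC=O", "CC>>C=C"), vocab_size = 264)
  enc <- encode_two_sentence("CC>>C=C", "CCO>>CC=O", tok, max_len = 16)
  menc <- withr::with_seed(3, apply_static_mask(enc, tok, mask_rate = 0.4))
  p <- withr::with_seed(11, photocatr:::.lm_init_params(cfg))
  acc <- photocatr:::.zero_grads(p)
  photocatr:::.mlm_example(p, cfg, menc, acc, scale = 1)
  loss_fn <- function(pp) photocatr:::.mlm_example(pp, cfg, menc)$loss
  eps <- 1e-5
  withr::with_seed(5, {
    for (nm in c("E", "P", "S", "l1_Wq", "l1_Wo", "l1_g1", "l1_W1", "l2_W2",
                 "l2_g2", "Wm", "bm")) {
      for (rep in 1:2) {
        i <- sample(length(p[[nm]]), 1)
        p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
        p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
        num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
        ana <- acc[[nm]][i]
        if (abs(num) > 1e-6)
          expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 1e-4,
                    label = sprintf("%s[%d]", nm, i))
      }
    }
  })
})

test_that("pretraining lowers held-out masked loss below the untrained baseline", {
  pairs <- lm_small_corpus(n = 90, seed = 5)
  cfg <- lm_config(layers = 2, heads = 2, embed_dim = 32, ffn_dim = 64,
                   max_len = 96, vocab_size = 280, pretrain_epochs = 2,
                   batch_size = 8, seed = 3)
  lm <- pretrain_mlm(pairs, cfg)
  rep <- lm$report
  base <- rep$holdout_loss[rep$epoch == 0]
  final <- tail(rep$holdout_loss, 1)
  expect_lt(final, base)
  # masked-token recovery beats the chance level 1/vocab
  expect_gt(tail(rep$holdout_acc, 1), 1 / cfg$vocab_size)
  # checkpoint round-trip reproduces the evaluation exactly
  encs <- purrr::map2(pairs$core_smiles, pairs$reaction_smiles,
                      encode_two_sentence, tok = lm$tokenizer,
                      max_len = cfg$max_len)
  masked <- build_masked_corpus(encs[pairs$holdout], lm$tokenizer,
                                mask_rate = 0.15, seed = 21)
  l1 <- lm_masked_loss(lm, masked)
  path <- tempfile(fileext = ".rds")
  write_lm(lm, path)
  l2 <- lm_masked_loss(read_lm(path), masked)
  expect_identical(l1, l2)
})

test_that("fine-tuned classifiers emit normalized, deterministic probabilities", {
  reg <- pc_registry()
  cfg_gen <- generator_config(n_records = 60, n_templates = 4,
                              label_noise = 0, seed = 8)
  recs <- generate_reactions(cfg_gen)
  cores <- vapply(recs$mapped_smiles, function(ms)
    extract_core(ms)$core_smiles, "", USE.NAMES = FALSE)
  data <- tibble::tibble(core_smiles = cores,
                         reaction_smiles = recs$reaction_smiles,
                         label = encode_label(recs$catalyst, reg))
  cfg <- lm_config(layers = 1, heads = 2, embed_dim = 24, ffn_dim = 48,
                   max_len = 96, vocab_size = 280, finetune_epochs = 2,
                   batch_size = 8, seed = 4)
  clf <- finetune_classifier(data, reg, cfg)
  pr <- predict_proba(clf, data[1:10, ])
  expect_equal(dim(pr), c(10L, 31L))
  expect_equal(rowSums(pr), rep(1, 10), tolerance = 1e-6)
  expect_true(all(pr > 0 & pr < 1))
  clf2 <- finetune_classifier(data, reg, cfg)
  expect_identical(predict_proba(clf2, data[1:5, ]), pr[1:5, ])
})
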