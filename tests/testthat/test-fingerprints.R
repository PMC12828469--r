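test_that("the string hash matches published FNV-1a 32-bit test vectors", {
  # independent reference values for the FNV-1a 32-bit algorithm
  expect_equal(photocatr:::fnv1a32(""), 2166136261)
  expect_equal(photocatr:::fnv1a32("a"), 0xe40c292c)
  expect_equal(photocatr:::fnv1a32("foobar"), 0xbf9cf968)
})

test_that("shingle sets enumerate circular environments with set semantics", {
  expect_identical(shingle_set("C", radius = 0), "C")
  # ethanol, radius 1: three radius-0 atom environments plus three distinct
  # radius-1 environments (hand enumeration)
  sh <- shingle_set("CCO", radius = 1)
  expect_setequal(sh, c("[CH3]", "[CH2]", "[OH]", "[CH2]C", "[CH2]O", "C(C)O"))
  # nesting in the radius
  for (s in c("CCO", "c1ccccc1C", "CC(=O)OC")) {
    for (r in 0:2)
      expect_true(all(shingle_set(s, r) %in% shingle_set(s, r + 1)), label = s)
  }
})

test_that("morgan fingerprints are deterministic, folded environment hashes", {
  fp <- morgan_fp("C", 64, 2)
  expect_gte(sum(fp), 1)
  expect_identical(morgan_fp("CCO", 64, 2), morgan_fp("CCO", 64, 2))
  # folding consistency on ethanol: every set bit is the fold of at least one
  # enumerated environment hash, and every environment hash sets its bit
  envs <- shingle_set("CCO", radius = 2)
  bits <- unique(photocatr:::fnv1a32(envs) %% 64)
  fp <- morgan_fp("CCO", 64, 2)
  expect_setequal(which(fp == 1) - 1, bits)
  # substrate order never matters
  expect_identical(morgan_fp("CCO.CC(=O)O", 64, 2),
                   morgan_fp("CC(=O)O.CCO", 64, 2))
})

test_that("drfp is the folded symmetric shingle difference", {
  expect_identical(sum(drfp("CCO>>CCO")), 0L)
  expect_identical(sum(drfp("CCO.CC>>CC.CCO")), 0L)
  expect_identical(drfp("CCO>>CC=O"), drfp("CC=O>>CCO"))

  # brute-force oracle on the toy esterification: explicit set difference,
  # hashed and folded by hand
  rxn <- "CCO.CC(=O)O>>CC(=O)OCC"
  lhs <- shingle_set("CCO.CC(=O)O", 3)
  rhs <- shingle_set("CC(=O)OCC", 3)
  sym <- c(setdiff(lhs, rhs), setdiff(rhs, lhs))
  expected <- integer(64)
  expected[unique(photocatr:::fnv1a32(sym) %% 64) + 1] <- 1L
  expect_identical(as.integer(drfp(rxn, 64, 3)), expected)
  expect_gte(sum(expected), 1)
})

test_that("refolding a 128-bit drfp modulo 64 reproduces the 64-bit vector", {
  for (rxn in c("CCO>>CC=O", "CCBr.OC>>CCOC", "CC(=O)O.CCO>>CC(=O)OCC")) {
    f128 <- drfp(rxn, 128)
    f64 <- drfp(rxn, 64)
    refold <- integer(64)
    refold[unique((which(f128 == 1) - 1) %% 64) + 1] <- 1L
    expect_identical(refold, as.integer(f64), label = rxn)
    m128 <- morgan_fp(rxn <- "CCOC(C)=O", 128)
    m64 <- morgan_fp("CCOC(C)=O", 64)
    refold <- integer(64)
    refold[unique((which(m128 == 1) - 1) %% 64) + 1] <- 1L
    expect_identical(refold, as.integer(m64))
  }
})

test_that("featurize_reactions produces labeled 64+64-bit feature rows", {
  reg <- pc_registry()
  recs <- generate_reactions(generator_config(n_records = 15, seed = 4))
  feats <- featurize_reactions(recs, reg)
  expect_equal(nrow(feats), 15)
  expect_length(grep("^m[0-9]+$", names(feats)), 64)
  expect_length(grep("^d[0-9]+$", names(feats)), 64)
  expect_true(all(feats$label %in% 0:30))
  expect_identical(feats$label, encode_label(recs$catalyst, reg))
  # DRFP of the core is constant within a template
  truth <- ground_truth(recs)
  dcols <- grep("^d[0-9]+$", names(feats))
  for (tid in unique(truth$template_id)) {
    rows <- which(truth$template_id == tid)
    expect_equal(nrow(unique(feats[rows, dcols])), 1, label = tid)
  }
})

test_that("reordering molecules within a side never changes a fingerprint", {
  expect_identical(drfp("CCO.CCBr>>CCOCC"), drfp("CCBr.CCO>>CCOCC"))
  expect_identical(morgan_fp(c("CCO", "CC=O"), 64, 2),
                   morgan_fp(c("CC=O", "CCO"), 64, 2))
})
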