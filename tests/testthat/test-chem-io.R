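test_that("parse_reaction handles both reaction SMILES dialects", {
  rec <- parse_reaction("CCO.CC(=O)O>>CC(=O)OCC")
  expect_equal(rec$n_reactants, 2L)
  expect_identical(rec$product, canonicalize_smiles("CC(=O)OCC"))

  expect_warning(rec3 <- parse_reaction("CCO>agent>CCO"),
                 class = "photocatr_agents_dropped")
  expect_equal(rec3$n_reactants, 1L)
  expect_identical(rec3$product, canonicalize_smiles("CCO"))

  expect_error(parse_reaction("C1CC>>C"), class = "photocatr_parse_error")
  expect_error(parse_reaction("CCO>>"), class = "photocatr_parse_error")
  expect_error(parse_reaction("CCO>>C>>C"), class = "photocatr_parse_error")
})

test_that("multi-product records are rejected unless the largest is kept", {
  expect_error(parse_reaction("CCBr.O>>CCO.Br"),
               class = "photocatr_parse_error")
  rec <- parse_reaction("CCBr.O>>CCO.Br", keep_largest_product = TRUE)
  expect_identical(rec$product, canonicalize_smiles("CCO"))
})

test_that("mapped reactions validate mapping integrity", {
  rec <- parse_reaction("[CH3:1][Br:2].[OH2:3]>>[CH3:1][OH:3]")
  expect_false(is.na(rec$mapped_smiles))
  # product map absent from reactants
  expect_error(parse_reaction("[CH3:1]O>>[CH3:1][OH:9]"),
               class = "photocatr_parse_error")
  # duplicate map within a side
  expect_error(parse_reaction("[CH3:1][CH3:1]>>[CH3:1][CH3:2]"),
               class = "photocatr_parse_error")
})

test_that("the default registry has 31 well-formed entries", {
  reg <- pc_registry()
  expect_s3_class(reg, "pc_registry")
  expect_equal(nrow(reg), 31L)
  expect_identical(reg$index, 0:30)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_true("4CzIPN" %in% reg$name)
})

test_that("label encoding is a bijection over the registry", {
  reg <- pc_registry()
  idx <- encode_label(reg$name, reg)
  expect_identical(idx, 0:30)
  expect_identical(decode_label(idx, reg), reg$name)
  expect_identical(decode_label(encode_label("4CzIPN", reg), reg), "4CzIPN")
  expect_error(encode_label("NotACatalyst", reg),
               class = "photocatr_lookup_error")
  expect_error(decode_label(31L, reg), class = "photocatr_lookup_error")
  expect_error(decode_label(-1L, reg), class = "photocatr_lookup_error")
})

test_that("registry files with schema problems are rejected", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("index,name,smiles", "0,A,C", "2,B,CC"), bad)
  expect_error(pc_registry(bad), class = "photocatr_schema_error")
  writeLines(c("name,smiles", "A,C"), bad)
  expect_error(pc_registry(bad), class = "photocatr_schema_error")
})

test_that("datasets round-trip losslessly through CSV and JSONL", {
  reg <- pc_registry()
  recs <- generate_reactions(generator_config(n_records = 14, seed = 3))
  recs <- validate_reactions(recs, reg)   # canonical, deduplicated
  for (ext in c(".csv", ".jsonl")) {
    path <- tempfile(fileext = ext)
    write_reactions(recs, path)
    back <- read_reactions(path, reg)
    expect_equal(nrow(back), nrow(recs), label = ext)
    expect_identical(back$reaction_smiles, recs$reaction_smiles, label = ext)
    expect_identical(back$catalyst, recs$catalyst, label = ext)
    expect_identical(back$mapped_smiles, recs$mapped_smiles, label = ext)
  }
})

test_that("invalid rows are dropped and counted in the load report", {
  reg <- pc_registry()
  path <- tempfile(fileext = ".csv")
  df <- data.frame(
    id = paste0("r", 1:5),
    reaction_smiles = c("CCO>>CC=O", "CCBr>>CCO", "C1CC>>C",
                        "CC=O>>CCO", "CCO>>CC=O"),
    catalyst = c("4CzIPN", "NotACatalyst", "EY", "EY", "4CzIPN"),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE)
  out <- read_reactions(path, reg)
  # r2 unknown catalyst, r3 unparsable, r5 duplicate of r1 -> 2 survive
  expect_equal(nrow(out), 2L)
  rep <- load_report(out)
  expect_equal(sum(rep$n), 3L)
  expect_true(any(grepl("catalyst", rep$reason)))
  expect_true(any(grepl("invalid", rep$reason)))
  expect_true(any(grepl("duplicate", rep$reason)))
})

test_that("an empty dataset file yields an empty tibble with a warning", {
  path <- tempfile(fileext = ".csv")
  writeLines("id,reaction_smiles,catalyst", path)
  expect_warning(out <- read_reactions(path, pc_registry()))
  expect_equal(nrow(out), 0L)
})

test_that("schema violations abort loading", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("foo,bar", "1,2"), path)
  expect_error(read_reactions(path), class = "photocatr_schema_error")
})

test_that("split tags survive the dataset round trip", {
  reg <- pc_registry()
  recs <- generate_reactions(generator_config(n_records = 8, seed = 12))
  recs$split_tag <- paste0("fold", rep(1:2, each = 4))
  path <- tempfile(fileext = ".csv")
  write_reactions(recs, path)
  back <- read_reactions(path, reg)
  expect_true("split_tag" %in% names(back))
  expect_identical(back$split_tag, recs$split_tag[match(back$id, recs$id)])
})
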