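test_that("changed atoms match hand-derived sets on the toy reactions", {
  for (nm in names(toy_reactions())) {
    toy <- toy_reactions()[[nm]]
    rxn <- mapped_reaction(toy$smiles)
    expect_identical(find_changed_atoms(rxn), toy$changed, label = nm)
  }
})

test_that("changed atoms agree with the brute-force adjacency oracle", {
  fixtures <- c(
    vapply(toy_reactions(), `[[`, "", "smiles"),
    # a few extra hand-mapped cases incl. leaving group and charge changes
    "[CH3:1][O:2][CH3:3]>>[CH3:1][OH:2]",
    "[CH2:1]=[O:2].[NH3:3]>>[CH2:1]=[NH:3]",
    "[CH3:1][S:2][CH3:3].[OH:4][OH:5]>>[CH3:1][S+:2]([O-:4])[CH3:3]"
  )
  for (s in fixtures) {
    rxn <- mapped_reaction(s)
    expect_identical(find_changed_atoms(rxn), sort(oracle_changed_atoms(s)),
                     label = s)
  }
})

test_that("core expansion is a breadth-first radius search", {
  chain <- mapped_reaction(paste0(
    "[CH3:1][CH2:2][CH2:3][CH2:4][CH2:5][CH2:6][CH2:7][CH3:8]>>",
    "[CH3:1][CH2:2][CH2:3][CH2:4][CH2:5][CH2:6][CH2:7][CH3:8]"))
  expect_identical(expand_core(chain, 1L, radius = 0), 1L)
  expect_identical(expand_core(chain, 1L, radius = 3), 1:4)
  expect_identical(expand_core(chain, 1:8, radius = 2), 1:8)
  expect_identical(expand_core(chain, integer(0), radius = 3), integer(0))
})

test_that("core atom sets are monotone in the radius", {
  recs <- generate_reactions(generator_config(n_records = 12, seed = 9))
  for (ms in unique(recs$mapped_smiles)[1:8]) {
    rxn <- mapped_reaction(ms)
    changed <- find_changed_atoms(rxn)
    prev <- integer(0)
    for (r in 0:4) {
      cur <- expand_core(rxn, changed, radius = r)
      expect_true(all(prev %in% cur), label = sprintf("%s r=%d", ms, r))
      expect_true(all(changed %in% cur))
      prev <- cur
    }
  }
})

test_that("identity reactions yield a flagged empty core", {
  core <- extract_core("[CH3:1][OH:2]>>[CH3:1][OH:2]")
  expect_true(core$is_identity)
  expect_identical(core$core_smiles, "")
  expect_length(core$changed_atoms, 0)
})

test_that("the same transformation on different substrates shares a core key", {
  e1 <- paste0("[CH3:20][CH2:21][CH2:22][CH2:23][CH2:24][OH:4].",
               "[CH3:10][C:1](=[O:2])[OH:3]>>",
               "[CH3:20][CH2:21][CH2:22][CH2:23][CH2:24][O:4][C:1](=[O:2])[CH3:10]")
  e2 <- paste0("[CH3:30][CH:31]([CH3:32])[CH2:33][CH2:34][CH2:35][CH2:24][OH:4].",
               "[CH3:10][C:1](=[O:2])[OH:3]>>",
               "[CH3:30][CH:31]([CH3:32])[CH2:33][CH2:34][CH2:35][CH2:24][O:4][C:1](=[O:2])[CH3:10]")
  c1 <- extract_core(e1); c2 <- extract_core(e2)
  expect_identical(c1$core_key, c2$core_key)
  expect_true(nzchar(c1$core_key))
  expect_true(all(c1$changed_atoms %in% c1$core_atoms))
})

test_that("distinct core keys over a generated set equal the template count", {
  cfg <- generator_config(n_records = 50, n_templates = 6, seed = 21)
  recs <- generate_reactions(cfg)
  keys <- vapply(unique(recs$mapped_smiles),
                 function(ms) extract_core(ms)$core_key, "", USE.NAMES = FALSE)
  n_used <- length(unique(ground_truth(recs)$template_id))
  expect_equal(length(unique(keys)), n_used)
})

test_that("mapping-integrity violations are rejected", {
  expect_error(mapped_reaction("[CH3:1][CH3:1]>>[CH3:1][CH3:1]"),
               class = "photocatr_parse_error")
  expect_error(mapped_reaction("[CH3:1]O>>[CH3:1][OH:5]"),
               class = "photocatr_parse_error")
  expect_error(mapped_reaction("CCO>>CCO"), class = "photocatr_parse_error")
})
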