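# Shared fixtures built in code.

# Hand-mapped toy reactions (<= 8 heavy atoms) with independently derived
# changed-atom sets. Derivations: compare, per map number, the (neighbor,
# bond-order) environment, charge and hydrogen count between sides by hand.
toy_reactions <- function() {
  list(
    identity = list(
      smiles = "[CH3:1][OH:2]>>[CH3:1][OH:2]",
      changed = integer(0)
    ),
    sn2 = list(
      # C1: neighbor Br -> O; Br2: loses C; O3: loses H, gains C
      smiles = "[CH3:1][Br:2].[OH2:3]>>[CH3:1][OH:3]",
      changed = c(1L, 2L, 3L)
    ),
    esterification = list(
      # C1: O3 -> O4 neighbor swap; O3 leaves; O4 loses an H, gains C1
      smiles = "[CH3:6][C:1](=[O:2])[OH:3].[OH:4][CH3:5]>>[CH3:6][C:1](=[O:2])[O:4][CH3:5]",
      changed = c(1L, 3L, 4L)
    ),
    oxidation = list(
      # C1 loses an H and its C-O bond order doubles; O2 loses its H
      smiles = "[CH3:3][CH2:1][OH:2]>>[CH3:3][CH:1]=[O:2]",
      changed = c(1L, 2L)
    ),
    addition = list(
      # double bond saturates; Br atoms attach
      smiles = "[CH2:1]=[CH2:2].[Br:3][Br:4]>>[CH2:1]([Br:3])[CH2:2][Br:4]",
      changed = c(1L, 2L, 3L, 4L)
    ),
    deprotonation = list(
      # charge and hydrogen count change on O, nothing else
      smiles = "[CH3:1][OH:2]>>[CH3:1][O-:2]",
      changed = c(2L)
    )
  )
}

# Brute-force oracle for changed atoms: build one adjacency matrix per side
# indexed by map number (bond orders as entries; unmapped neighbors summed
# into a dedicated slot per element) and diff rows plus charge/H columns.
# Independent of find_changed_atoms' neighbor-multiset bookkeeping.
oracle_changed_atoms <- function(mapped_smiles) {
  sides <- strsplit(mapped_smiles, ">>", fixed = TRUE)[[1]]
  side_info <- lapply(sides, function(s) {
    mol <- parse_smiles(s)
    maps <- mol$atoms$map
    list(mol = mol, maps = maps)
  })
  all_maps <- sort(unique(c(side_info[[1]]$maps, side_info[[2]]$maps)))
  all_maps <- all_maps[!is.na(all_maps)]
  mat_for <- function(info) {
    mol <- info$mol
    cols <- c(as.character(all_maps), unique(mol$atoms$symbol), "charge", "h")
    m <- matrix(0, length(all_maps), length(cols),
                dimnames = list(as.character(all_maps), cols))
    present <- rep(FALSE, length(all_maps))
    for (a in seq_len(mol$n)) {
      mp <- mol$atoms$map[a]
      if (is.na(mp)) next
      row <- as.character(mp)
      present[match(mp, all_maps)] <- TRUE
      m[row, "charge"] <- mol$atoms$charge[a]
      m[row, "h"] <- mol$atoms$hcount[a]
    }
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]; o <- mol$bonds$order[k]
      ma <- mol$atoms$map[a]; mb <- mol$atoms$map[b]
      if (!is.na(ma)) {
        col <- if (!is.na(mb)) as.character(mb) else mol$atoms$symbol[b]
        m[as.character(ma), col] <- m[as.character(ma), col] + o
      }
      if (!is.na(mb)) {
        col <- if (!is.na(ma)) as.character(ma) else mol$atoms$symbol[a]
        m[as.character(mb), col] <- m[as.character(mb), col] + o
      }
    }
    list(m = m, present = present)
  }
  r <- mat_for(side_info[[1]]); p <- mat_for(side_info[[2]])
  shared_cols <- intersect(colnames(r$m), colnames(p$m))
  changed <- vapply(seq_along(all_maps), function(i) {
    if (!r$present[i] || !p$present[i]) return(TRUE)
    !isTRUE(all.equal(r$m[i, shared_cols], p$m[i, shared_cols]))
  }, TRUE)
  all_maps[changed]
}

# small labeled binary-feature fixture with a class-dependent signal:
# each class has a template bit pattern; features flip bits with prob `flip`.
make_feature_fixture <- function(n, n_classes, n_bits = 64, flip = 0.02,
                                 class_prob = NULL, seed = 1) {
  withr::with_seed(seed, {
    patt_m <- matrix(rbinom(n_classes * n_bits, 1, 0.4), n_classes)
    patt_d <- matrix(rbinom(n_classes * n_bits, 1, 0.4), n_classes)
    y <- sample.int(n_classes, n, replace = TRUE, prob = class_prob) - 1L
    M <- patt_m[y + 1L, , drop = FALSE]
    D <- patt_d[y + 1L, , drop = FALSE]
    fl <- matrix(rbinom(n * n_bits, 1, flip), n)
    M <- abs(M - fl)
    fl <- matrix(rbinom(n * n_bits, 1, flip), n)
    D <- abs(D - fl)
  })
  colnames(M) <- paste0("m", seq_len(n_bits))
  colnames(D) <- paste0("d", seq_len(n_bits))
  dplyr::bind_cols(tibble::tibble(label = y), tibble::as_tibble(M),
                   tibble::as_tibble(D))
}

# tiny generated corpus shared by several LM tests (cached per session)
lm_fixture_env <- new.env()
lm_small_corpus <- function(n = 120, seed = 5) {
  key <- paste0("c", n, "_", seed)
  if (is.null(lm_fixture_env[[key]])) {
    cfg <- generator_config(n_records = n, n_templates = 8, seed = seed)
    lm_fixture_env[[key]] <- corpus_for_pretraining(cfg)
  }
  lm_fixture_env[[key]]
}
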