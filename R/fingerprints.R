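# 64-bit reaction representations for the MLP: a folded Morgan fingerprint of
# the concatenated substrates, and the differential reaction fingerprint
# (DRFP) of the (core) reaction: the symmetric difference between the
# reactant-side and product-side circular-substructure (shingle) sets, hashed
# and folded into a fixed-length binary vector.

# FNV-1a 32-bit string hash: fixed offset basis / prime, platform independent
# (pure double arithmetic mod 2^32, never a process-randomized hash), so
# fingerprints are reproducible across runs and machines.
.FNV_OFFSET <- 2166136261
.FNV_PRIME <- 16777619

fnv1a32 <- function(strings) {
  vapply(strings, function(s) {
    h <- .FNV_OFFSET
    for (byte in utf8ToInt(s)) {
      lo <- h %% 65536
      h <- (h - lo) + bitwXor(as.integer(lo), as.integer(byte %% 256))
      h <- ((h %% 65536) * .FNV_PRIME +
              (h %/% 65536) * ((.FNV_PRIME * 65536) %% 4294967296)) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

fold_bits <- function(hashes, n_bits) {
  v <- integer(n_bits)
  if (length(hashes)) v[unique(hashes %% n_bits) + 1L] <- 1L
  v
}

# Canonical SMILES of the circular environment of atom `a`: the induced
# subgraph on all atoms within `k` bonds. Atoms keep their full-molecule
# hydrogen counts, so an environment records substitution exactly.
.atom_env <- function(mol, dmat, a, k) {
  idx <- which(dmat[a, ] <= k)
  write_smiles(mol_subgraph(mol, idx))
}

.all_dists <- function(mol) {
  t(vapply(seq_len(mol$n), function(a) mol_dists(mol, a), numeric(mol$n)))
}

#' Circular-substructure shingle set of a molecule set
#'
#' For every atom of every molecule and every radius `k` in `0..radius`, the
#' canonical SMILES of the `k`-bond circular environment is collected; the
#' result has set semantics (deduplicated, sorted) and is deterministic for
#' a given molecule set and radius.
#'
#' @param molecules character vector of SMILES (one side of a reaction).
#' @param radius maximum environment radius in bonds (default 3).
#' @return sorted character vector of canonical environment SMILES.
#' @export
#' @examples
#' shingle_set("CCO", radius = 1)
shingle_set <- function(molecules, radius = 3L) {
  stopifnot(radius >= 0)
  out <- character(0)
  for (s in molecules) {
    mol <- parse_smiles(s)
    comp <- mol$atoms$frag
    for (f in unique(comp)) {
      sub <- mol_subgraph(mol, which(comp == f))
      dmat <- .all_dists(sub)
      for (a in seq_len(sub$n)) {
        for (k in 0:radius) out <- c(out, .atom_env(sub, dmat, a, k))
      }
    }
  }
  sort(unique(out))
}

#' Folded Morgan fingerprint of the reaction substrates
#'
#' Circular-environment identifiers of all substrate molecules (radii
#' `0..radius`) are hashed with a fixed 32-bit string hash and folded modulo
#' `n_bits` into a binary vector; environments from different substrates are
#' OR-combined. The published configuration fixes only the size (64); the
#' radius defaults to the conventional 2.
#'
#' @param substrates character vector of substrate SMILES.
#' @param n_bits fingerprint length (default 64).
#' @param radius circular-environment radius (default 2).
#' @return integer 0/1 vector of length `n_bits` with attribute `n_bits`.
#' @export
morgan_fp <- function(substrates, n_bits = 64L, radius = 2L) {
  stopifnot(n_bits >= 1)
  sh <- shingle_set(substrates, radius = radius)
  structure(fold_bits(fnv1a32(sh), n_bits), n_bits = n_bits)
}

#' Differential reaction fingerprint (DRFP)
#'
#' The symmetric difference between the reactant-side and product-side
#' shingle sets of a reaction, hashed (fixed FNV-1a 32-bit) and folded modulo
#' `n_bits` into a binary vector. By default applied to the extracted core
#' reaction SMILES, matching the representation fed to the recommender; pass
#' the full reaction SMILES to fingerprint the whole reaction.
#'
#' @param reaction reaction SMILES (`reactants>>products`).
#' @param n_bits vector size (default 64).
#' @param radius shingle radius (default 3).
#' @return integer 0/1 vector of length `n_bits`; the zero vector iff both
#'   sides have identical shingle sets (e.g. an identity reaction).
#' @export
#' @examples
#' drfp("CCO>>CCO")          # zero vector
drfp <- function(reaction, n_bits = 64L, radius = 3L) {
  stopifnot(n_bits >= 1)
  sides <- split_reaction(reaction)
  lhs <- shingle_set(sides$reactants, radius = radius)
  rhs <- shingle_set(sides$products, radius = radius)
  symdiff <- c(setdiff(lhs, rhs), setdiff(rhs, lhs))
  structure(fold_bits(fnv1a32(symdiff), n_bits), n_bits = n_bits)
}

#' Fingerprint feature table for a reaction dataset
#'
#' Computes, per record, the Morgan fingerprint of the substrates and the
#' DRFP of the extracted reaction core (requires `mapped_smiles`; records
#' whose core cannot be extracted fall back to the full reaction with a
#' warning when `drfp_on_core = TRUE`). Results are memoized within the call
#' on substrate sets and core keys, which makes template-generated corpora
#' cheap to featurize.
#'
#' @param data record tibble (`id`, `reaction_smiles`, `mapped_smiles`,
#'   `catalyst`).
#' @param registry `pc_registry` for label encoding; records without a label
#'   get `label = NA`.
#' @param n_bits fingerprint length for both representations (default 64).
#' @param morgan_radius Morgan environment radius (default 2).
#' @param drfp_radius DRFP shingle radius (default 3).
#' @param drfp_on_core fingerprint the extracted core (default) or the full
#'   reaction.
#' @param core_radius core expansion radius (default 3).
#' @return tibble: `id`, `catalyst`, `label`, `core_key`, then `m1..m<n>` and
#'   `d1..d<n>` binary feature columns.
#' @export
featurize_reactions <- function(data, registry = NULL, n_bits = 64L,
                                morgan_radius = 2L, drfp_radius = 3L,
                                drfp_on_core = TRUE, core_radius = 3L) {
  n <- nrow(data)
  morgan_cache <- new.env(parent = emptyenv())
  drfp_cache <- new.env(parent = emptyenv())
  core_cache <- new.env(parent = emptyenv())
  M <- matrix(0L, n, n_bits)
  D <- matrix(0L, n, n_bits)
  core_keys <- character(n)

  for (r in seq_len(n)) {
    sides <- split_reaction(data$reaction_smiles[r])
    subs <- sides$reactants
    mv <- morgan_cache[[subs]]
    if (is.null(mv)) {
      mv <- morgan_fp(subs, n_bits = n_bits, radius = morgan_radius)
      morgan_cache[[subs]] <- mv
    }
    M[r, ] <- mv

    target <- data$reaction_smiles[r]
    if (drfp_on_core) {
      ms <- data$mapped_smiles[r]
      if (!is.na(ms) && nzchar(ms)) {
        core <- core_cache[[ms]]
        if (is.null(core)) {
          core <- extract_core(ms, radius = core_radius)
          core_cache[[ms]] <- core
        }
        if (!core$is_identity) target <- core$core_smiles
        core_keys[r] <- core$core_key
      } else {
        rlang::warn("record without mapped_smiles: DRFP on full reaction")
      }
    }
    dv <- drfp_cache[[target]]
    if (is.null(dv)) {
      dv <- drfp(target, n_bits = n_bits, radius = drfp_radius)
      drfp_cache[[target]] <- dv
    }
    D[r, ] <- dv
  }

  colnames(M) <- paste0("m", seq_len(n_bits))
  colnames(D) <- paste0("d", seq_len(n_bits))
  label <- rep(NA_integer_, n)
  if (!is.null(registry)) {
    ok <- !is.na(data$catalyst)
    if (any(ok)) label[ok] <- encode_label(data$catalyst[ok], registry)
  }
  out <- tibble::tibble(id = data$id, catalyst = data$catalyst,
                        label = label, core_key = core_keys)
  dplyr::bind_cols(out, tibble::as_tibble(M), tibble::as_tibble(D))
}
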