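# Reaction-core extraction from atom-mapped reactions: the atoms whose
# bonding pattern changes between reactant and product side, expanded by a
# bond-distance radius (default 3), serialized as a canonical core reaction
# SMILES usable as a reaction-type key.

#' Build a mapped reaction from an atom-mapped reaction SMILES
#'
#' The package does not perform atom mapping itself; it requires mapped input
#' (from any external mapper, or the synthetic generator's exact maps).
#' Mapping integrity is enforced: map numbers unique within each side, every
#' product map present on the reactant side.
#'
#' @param mapped_smiles reaction SMILES with `[atom:N]` map numbers
#'   (`reactants>>product`; a 3-part form is accepted, agents ignored).
#' @return a `pc_mapped_rxn`: list with `reactant` and `product` `pc_mol`s.
#' @export
mapped_reaction <- function(mapped_smiles) {
  sides <- split_reaction(mapped_smiles)
  rmol <- parse_smiles(sides$reactants)
  pmol <- parse_smiles(sides$products)
  check_mapping(rmol, pmol)
  if (!any(!is.na(rmol$atoms$map)))
    pc_parse_error("reaction carries no atom-map numbers", mapped_smiles)
  structure(list(reactant = rmol, product = pmol, smiles = mapped_smiles),
            class = "pc_mapped_rxn")
}

# environment signature of one mapped atom on one side:
# (neighbor map, bond order) multiset + formal charge + total hydrogen count.
# Unmapped neighbors enter the multiset by element symbol.
.atom_signature <- function(mol, nb, a) {
  rows <- nb[[a]]
  nb_part <- if (is.null(rows)) "" else {
    ids <- ifelse(is.na(mol$atoms$map[rows[, 1]]),
                  paste0("u", mol$atoms$symbol[rows[, 1]]),
                  mol$atoms$map[rows[, 1]])
    paste(sort(paste0(ids, "~", rows[, 2])), collapse = "|")
  }
  paste(nb_part, mol$atoms$charge[a], mol$atoms$hcount[a], sep = ";")
}

#' Find the atoms that change their bonding pattern
#'
#' An atom counts as changed when, between its reactant- and product-side
#' occurrence, any of these differ: the multiset of (neighbor map number,
#' bond order) pairs, the formal charge, or the total hydrogen count. Atoms
#' present on only one side (leaving groups, incorporated reagents) are
#' always changed. Unmapped spectator atoms are treated as unchanged and
#' never returned.
#'
#' @param rxn a `pc_mapped_rxn`.
#' @return sorted integer vector of changed atom-map numbers.
#' @export
#' @examples
#' rxn <- mapped_reaction("[CH3:1][Br:2].[OH2:3]>>[CH3:1][OH:3]")
#' find_changed_atoms(rxn)
find_changed_atoms <- function(rxn) {
  stopifnot(inherits(rxn, "pc_mapped_rxn"))
  rmol <- rxn$reactant; pmol <- rxn$product
  rnb <- mol_adj(rmol); pnb <- mol_adj(pmol)
  rmaps <- rmol$atoms$map; pmaps <- pmol$atoms$map
  all_maps <- sort(unique(c(rmaps[!is.na(rmaps)], pmaps[!is.na(pmaps)])))
  changed <- integer(0)
  for (m in all_maps) {
    ra <- which(rmaps == m); pa <- which(pmaps == m)
    if (!length(ra) || !length(pa)) { changed <- c(changed, m); next }
    if (.atom_signature(rmol, rnb, ra) != .atom_signature(pmol, pnb, pa))
      changed <- c(changed, m)
  }
  changed
}

#' Expand a changed-atom set by a bond-distance radius
#'
#' Breadth-first expansion over bonds up to `radius` bonds from any changed
#' atom, on the reactant side for atoms present there and on the product side
#' for product-only atoms. Traversal runs through mapped atoms only
#' (unmapped spectators are excluded from cores).
#'
#' @param rxn a `pc_mapped_rxn`.
#' @param changed integer vector of changed map numbers.
#' @param radius non-negative bond-distance radius (default 3).
#' @return sorted map-number set: `changed` plus all mapped atoms within
#'   `radius` bonds.
#' @export
expand_core <- function(rxn, changed, radius = 3L) {
  stopifnot(radius >= 0)
  if (!length(changed)) return(integer(0))
  out <- integer(0)
  for (side in c("reactant", "product")) {
    mol <- rxn[[side]]
    maps <- mol$atoms$map
    seeds <- which(maps %in% changed)
    if (side == "product") {
      rmaps <- rxn$reactant$atoms$map
      prod_only <- setdiff(changed, rmaps[!is.na(rmaps)])
      seeds <- which(maps %in% changed)
      # product side only needs to expand around product-only atoms, but the
      # BFS frontier may pass through shared atoms; seeding all changed atoms
      # present on this side keeps the two sides consistent.
      if (!length(prod_only)) next
    }
    if (!length(seeds)) next
    mapped_idx <- which(!is.na(maps))
    d <- mol_dists(mol, seeds, within = mapped_idx)
    out <- c(out, maps[mapped_idx][d[mapped_idx] <= radius])
  }
  sort(unique(c(changed, out)))
}

#' Extract the reaction core
#'
#' Composes [find_changed_atoms()] and [expand_core()], then serializes the
#' induced subgraphs of both sides as a canonical, map-free core reaction
#' SMILES. Bonds severed at the core boundary leave the open valence
#' implicit: boundary atoms keep the hydrogen count they had in the full
#' molecule (written as bracket atoms where needed), so no dummy atoms are
#' introduced and identical transformations on different substrates yield a
#' string-identical `core_key`.
#'
#' @param rxn a `pc_mapped_rxn`, or an atom-mapped reaction SMILES.
#' @param radius bond-distance expansion radius (default 3).
#' @return a `pc_reaction_core`: list with `changed_atoms`, `core_atoms`
#'   (map numbers), `core_smiles`, `core_key` and `is_identity`. Identity
#'   reactions (no changed atoms) are flagged with an empty `core_smiles`.
#' @export
extract_core <- function(rxn, radius = 3L) {
  if (is.character(rxn)) rxn <- mapped_reaction(rxn)
  changed <- find_changed_atoms(rxn)
  if (!length(changed)) {
    return(structure(list(changed_atoms = integer(0), core_atoms = integer(0),
                          core_smiles = "", core_key = "",
                          is_identity = TRUE),
                     class = "pc_reaction_core"))
  }
  core <- expand_core(rxn, changed, radius = radius)
  side_smiles <- function(mol) {
    idx <- which(mol$atoms$map %in% core)
    if (!length(idx)) return("")
    write_smiles(mol_subgraph(mol, idx))
  }
  cs <- paste0(side_smiles(rxn$reactant), ">>", side_smiles(rxn$product))
  structure(list(changed_atoms = changed, core_atoms = core,
                 core_smiles = cs, core_key = cs, is_identity = FALSE),
            class = "pc_reaction_core")
}

#' @export
print.pc_reaction_core <- function(x, ...) {
  if (x$is_identity) cat("<reaction core: identity reaction (empty core)>\n")
  else cat(sprintf("<reaction core: %d changed, %d core atoms> %s\n",
                   length(x$changed_atoms), length(x$core_atoms),
                   x$core_smiles))
  invisible(x)
}
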