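# Molecular graphs parsed from (optionally atom-mapped) SMILES.
#
# A `pc_mol` is a list with
#   atoms: data.frame(symbol, aromatic, charge, hcount, map, frag)
#   bonds: data.frame(a1, a2, order)   # order in {1, 1.5, 2, 3}
# hcount is the *total* hydrogen count of the atom (explicit bracket count or
# the implicit count derived at parse time), so induced subgraphs keep the
# hydrogen environment of the parent molecule.

pc_parse_error <- function(msg, fragment = NULL) {
  if (!is.null(fragment)) msg <- sprintf("%s (in fragment '%s')", msg, fragment)
  rlang::abort(msg, class = "photocatr_parse_error")
}

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

.cap1 <- function(s) paste0(toupper(substr(s, 1, 1)), substring(s, 2))

.implicit_h <- function(symbol, bond_sum) {
  vals <- .DEFAULT_VALENCE[[symbol]]
  if (is.null(vals)) return(0L)
  bs <- as.integer(ceiling(bond_sum - 1e-9))
  ok <- vals[vals >= bs]
  if (!length(ok)) return(0L)
  as.integer(ok[1] - bs)
}

.parse_bracket <- function(tok, text) {
  body <- substr(tok, 2, nchar(tok) - 1)
  m <- regexec(
    "^([0-9]*)([A-Z][a-z]?|as|se|[a-z])(@{1,2})?(H([0-9]*))?(\\+\\+|--|[+-][0-9]*)?(:([0-9]+))?$",
    body
  )
  g <- regmatches(body, m)[[1]]
  if (!length(g)) pc_parse_error(sprintf("cannot parse bracket atom '%s'", tok), text)
  sym <- g[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "as", "se")
  hraw <- g[5]
  hcount <- if (!nzchar(hraw)) 0L else if (!nzchar(g[6])) 1L else as.integer(g[6])
  craw <- g[7]
  charge <- 0L
  if (nzchar(craw)) {
    charge <- switch(craw,
      "++" = 2L, "--" = -2L, "+" = 1L, "-" = -1L,
      as.integer(craw)
    )
  }
  map <- if (nzchar(g[8])) as.integer(g[9]) else NA_integer_
  list(symbol = sym, aromatic = aromatic, charge = charge,
       hcount = hcount, map = map)
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms with charge / explicit hydrogen
#' counts / atom-map numbers, aromatic lowercase atoms, ring closures
#' (including `%nn`), branches and dot-separated fragments. Stereochemistry
#' markers are accepted and ignored. Implicit hydrogen counts follow the
#' usual smallest-consistent-valence rule; aromatic bonds count 1.5 towards
#' the valence sum.
#'
#' @param text a single SMILES string (one side of a reaction; may contain
#'   `.`-separated fragments).
#' @return a `pc_mol` object.
#' @export
parse_smiles <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text))
    pc_parse_error("empty or non-character SMILES")
  n <- nchar(text)

  sym <- character(); arom <- logical(); chg <- integer()
  hspec <- integer(); map <- integer(); frg <- integer()
  b1 <- integer(); b2 <- integer(); bo <- numeric()

  prev <- NA_integer_
  stack <- integer()
  pending <- NA_real_
  ring <- list()
  frag <- 1L
  i <- 1L

  add_atom <- function(a) {
    sym <<- c(sym, a$symbol); arom <<- c(arom, a$aromatic)
    chg <<- c(chg, a$charge); hspec <<- c(hspec, a$hcount %||% NA_integer_)
    map <<- c(map, a$map); frg <<- c(frg, frag)
    idx <- length(sym)
    if (!is.na(prev)) {
      o <- pending
      if (is.na(o)) o <- if (arom[prev] && arom[idx]) 1.5 else 1
      b1 <<- c(b1, prev); b2 <<- c(b2, idx); bo <<- c(bo, o)
    }
    pending <<- NA_real_
    prev <<- idx
  }

  close_ring <- function(d) {
    key <- as.character(d)
    if (is.na(prev)) pc_parse_error("ring-closure digit before any atom", text)
    if (!is.null(ring[[key]])) {
      op <- ring[[key]]
      if (op$atom == prev) pc_parse_error("self ring closure", text)
      o <- pending
      if (is.na(o)) o <- op$order
      if (!is.na(op$order) && !is.na(pending) && op$order != pending)
        pc_parse_error("conflicting ring-bond orders", text)
      if (is.na(o)) o <- if (arom[op$atom] && arom[prev]) 1.5 else 1
      b1 <<- c(b1, op$atom); b2 <<- c(b2, prev); bo <<- c(bo, o)
      ring[[key]] <<- NULL
    } else {
      ring[[key]] <- list(atom = prev, order = pending)
      ring <<- ring
    }
    pending <<- NA_real_
  }

  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "(") {
      if (is.na(prev)) pc_parse_error("branch opened before any atom", text)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) pc_parse_error("unbalanced ')'", text)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch == ".") {
      if (length(stack)) pc_parse_error("'.' inside a branch", text)
      prev <- NA_integer_; pending <- NA_real_; frag <- frag + 1L; i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending <- 1; i <- i + 1L
    } else if (ch == "=") {
      pending <- 2; i <- i + 1L
    } else if (ch == "#") {
      pending <- 3; i <- i + 1L
    } else if (ch == ":") {
      pending <- 1.5; i <- i + 1L
    } else if (ch == "%") {
      dd <- substr(text, i + 1L, i + 2L)
      if (!grepl("^[0-9]{2}$", dd)) pc_parse_error("'%' not followed by two digits", text)
      close_ring(as.integer(dd)); i <- i + 3L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(as.integer(ch)); i <- i + 1L
    } else if (ch == "[") {
      j <- regexpr("]", substr(text, i, n), fixed = TRUE)
      if (j < 0) pc_parse_error("unclosed bracket atom", text)
      tok <- substr(text, i, i + j - 1L)
      add_atom(.parse_bracket(tok, text))
      i <- i + j
    } else if (grepl("^[A-Z]$", ch)) {
      two <- substr(text, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        add_atom(list(symbol = two, aromatic = FALSE, charge = 0L,
                      hcount = NA_integer_, map = NA_integer_))
        i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        add_atom(list(symbol = ch, aromatic = FALSE, charge = 0L,
                      hcount = NA_integer_, map = NA_integer_))
        i <- i + 1L
      } else pc_parse_error(sprintf("unknown atom symbol at '%s'", two), text)
    } else if (grepl("^[a-z]$", ch)) {
      if (!ch %in% c("b", "c", "n", "o", "p", "s"))
        pc_parse_error(sprintf("unknown aromatic symbol '%s'", ch), text)
      add_atom(list(symbol = ch, aromatic = TRUE, charge = 0L,
                    hcount = NA_integer_, map = NA_integer_))
      i <- i + 1L
    } else {
      pc_parse_error(sprintf("unexpected character '%s'", ch), text)
    }
  }
  if (length(stack)) pc_parse_error("unclosed branch '('", text)
  if (length(ring)) pc_parse_error("unclosed ring bond", text)
  if (!length(sym)) pc_parse_error("no atoms", text)

  na <- length(sym)
  bond_sum <- numeric(na)
  if (length(b1)) {
    for (k in seq_along(b1)) {
      bond_sum[b1[k]] <- bond_sum[b1[k]] + bo[k]
      bond_sum[b2[k]] <- bond_sum[b2[k]] + bo[k]
    }
  }
  hc <- hspec
  for (a in seq_len(na)) {
    if (is.na(hc[a])) hc[a] <- .implicit_h(.cap1(sym[a]), bond_sum[a])
  }

  structure(list(
    atoms = data.frame(symbol = sym, aromatic = arom, charge = chg,
                       hcount = as.integer(hc), map = map, frag = frg,
                       stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b1, a2 = b2, order = bo),
    n = na
  ), class = "pc_mol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pc_mol <- function(x, ...) {
  cat(sprintf("<pc_mol: %d atoms, %d bonds> %s\n", x$n, nrow(x$bonds),
              write_smiles(x, with_maps = TRUE)))
  invisible(x)
}

mol_adj <- function(mol) {
  nb <- vector("list", mol$n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]; o <- mol$bonds$order[k]
      nb[[i]] <- rbind(nb[[i]], c(j, o, k))
      nb[[j]] <- rbind(nb[[j]], c(i, o, k))
    }
  }
  nb
}

mol_components <- function(mol) {
  comp <- integer(mol$n)
  nb <- mol_adj(mol)
  cur <- 0L
  for (s in seq_len(mol$n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      rows <- nb[[a]]
      if (is.null(rows)) next
      for (j in rows[, 1]) {
        if (comp[j] == 0L) { comp[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  comp
}

# BFS bond distances from a set of atoms; atoms in `within` (if given)
# restrict traversal.
mol_dists <- function(mol, from, within = NULL) {
  d <- rep(Inf, mol$n)
  if (!length(from)) return(d)
  nb <- mol_adj(mol)
  allow <- rep(TRUE, mol$n)
  if (!is.null(within)) { allow[] <- FALSE; allow[within] <- TRUE }
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    if (is.null(nb[[a]])) next
    for (r in seq_len(nrow(nb[[a]]))) {
      j <- nb[[a]][r, 1]
      if (allow[j] && d[j] > d[a] + 1) { d[j] <- d[a] + 1; queue <- c(queue, j) }
    }
  }
  d
}

# Induced subgraph on the given atom indices; atom properties (including the
# stored total hydrogen count) are retained, so severed bonds leave an
# implicitly open valence rather than gaining hydrogens.
mol_subgraph <- function(mol, idx) {
  idx <- sort(unique(idx))
  keep <- mol$bonds$a1 %in% idx & mol$bonds$a2 %in% idx
  remap <- match(seq_len(mol$n), idx)
  bonds <- mol$bonds[keep, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  rownames(bonds) <- NULL
  atoms <- mol$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = bonds, n = length(idx)),
            class = "pc_mol")
}

# ---- canonical SMILES writing ------------------------------------------------

.canonical_ranks <- function(mol, nb, boost = NA_integer_) {
  at <- mol$atoms
  key <- paste(at$symbol, at$aromatic, at$charge, at$hcount,
               vapply(nb, function(x) if (is.null(x)) 0L else nrow(x), 0L))
  if (!is.na(boost)) key[boost] <- paste0("!", key[boost])
  rank <- match(key, sort(unique(key)))
  n <- mol$n
  repeat {
    nbkey <- vapply(seq_len(n), function(a) {
      if (is.null(nb[[a]])) return("")
      paste(sort(sprintf("%04.1f:%05d", nb[[a]][, 2], rank[nb[[a]][, 1]])),
            collapse = "|")
    }, "")
    # stable refinement: new labels ordered by (numeric old rank, nbkey), so
    # the partition refines monotonically and the loop always terminates
    ord <- order(rank, nbkey, method = "radix")
    newr <- integer(n)
    cur <- 1L
    newr[ord[1]] <- 1L
    if (n > 1) {
      for (i in 2:n) {
        if (rank[ord[i]] != rank[ord[i - 1]] || nbkey[ord[i]] != nbkey[ord[i - 1]])
          cur <- cur + 1L
        newr[ord[i]] <- cur
      }
    }
    if (identical(newr, rank)) break
    rank <- newr
  }
  rank
}

.bond_token <- function(order, arom1, arom2) {
  if (order == 2) return("=")
  if (order == 3) return("#")
  if (order == 1.5) return("")
  if (order == 1 && arom1 && arom2) return("-")
  ""
}

.atom_token <- function(mol, a, degree_written, bond_sum, with_maps) {
  at <- mol$atoms[a, ]
  sym <- at$symbol
  plain_ok <- .cap1(sym) %in% .ORGANIC_SUBSET &&
    at$charge == 0L && (!with_maps || is.na(at$map)) &&
    .implicit_h(.cap1(sym), bond_sum) == at$hcount
  if (plain_ok) return(sym)
  h <- at$hcount
  htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ctok <- if (at$charge == 0L) "" else if (at$charge == 1L) "+" else
    if (at$charge == -1L) "-" else sprintf("%+d", at$charge)
  mtok <- if (with_maps && !is.na(at$map)) paste0(":", at$map) else ""
  paste0("[", sym, htok, ctok, mtok, "]")
}

.write_component <- function(mol, nb, rank, root, with_maps) {
  n <- mol$n
  visited <- rep(FALSE, n)
  children <- vector("list", n)     # rows: child atom, order
  ringsets <- vector("list", n)     # rows: digit, order, is_opening
  ring_digit <- 0L
  bond_used <- rep(FALSE, max(1L, nrow(mol$bonds)))

  order_nbrs <- function(a, rows) {
    if (is.null(rows) || !nrow(rows)) return(rows)
    o <- order(rank[rows[, 1]], rows[, 2], mol$atoms$symbol[rows[, 1]])
    rows[o, , drop = FALSE]
  }

  # DFS building spanning tree + ring closures
  visited[root] <- TRUE
  dfs <- function(a) {
    rows <- order_nbrs(a, nb[[a]])
    if (is.null(rows)) return()
    for (r in seq_len(nrow(rows))) {
      j <- rows[r, 1]; o <- rows[r, 2]; bid <- rows[r, 3]
      if (bond_used[bid]) next
      if (visited[j]) {
        bond_used[bid] <<- TRUE
        ring_digit <<- ring_digit + 1L
        ringsets[[a]] <<- rbind(ringsets[[a]], c(ring_digit, o, 1))
        ringsets[[j]] <<- rbind(ringsets[[j]], c(ring_digit, o, 0))
      } else {
        bond_used[bid] <<- TRUE
        visited[j] <<- TRUE
        children[[a]] <<- rbind(children[[a]], c(j, o))
        dfs(j)
      }
    }
  }
  dfs(root)

  bond_sum_tot <- numeric(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      bond_sum_tot[mol$bonds$a1[k]] <- bond_sum_tot[mol$bonds$a1[k]] + mol$bonds$order[k]
      bond_sum_tot[mol$bonds$a2[k]] <- bond_sum_tot[mol$bonds$a2[k]] + mol$bonds$order[k]
    }
  }

  emit <- function(a) {
    out <- .atom_token(mol, a, 0L, bond_sum_tot[a], with_maps)
    rs <- ringsets[[a]]
    if (!is.null(rs)) {
      for (r in seq_len(nrow(rs))) {
        d <- rs[r, 1]; o <- rs[r, 2]
        btok <- if (rs[r, 3] == 1)
          .bond_token(o, mol$atoms$aromatic[a], TRUE) else ""
        dtok <- if (d > 9) sprintf("%%%02d", d) else as.character(d)
        out <- paste0(out, btok, dtok)
      }
    }
    ch <- children[[a]]
    if (!is.null(ch) && nrow(ch)) {
      for (r in seq_len(nrow(ch))) {
        j <- ch[r, 1]; o <- ch[r, 2]
        btok <- .bond_token(o, mol$atoms$aromatic[a], mol$atoms$aromatic[j])
        sub <- paste0(btok, emit(j))
        if (r < nrow(ch)) sub <- paste0("(", sub, ")")
        out <- paste0(out, sub)
      }
    }
    out
  }
  emit(root)
}

#' Write a molecular graph as SMILES
#'
#' Produces a canonical SMILES by Morgan-style iterative rank refinement with
#' root individualization: every atom in the minimal refined rank class of a
#' component is tried as DFS root and the lexicographically smallest string is
#' kept. Two graphs that are isomorphic (including hydrogen counts, charges
#' and aromaticity) therefore serialize identically. Atom-map numbers are
#' dropped unless `with_maps = TRUE`.
#'
#' @param mol a `pc_mol`.
#' @param with_maps keep atom-map numbers in the output.
#' @return a single SMILES string; dot-joined canonical components, sorted.
#' @export
write_smiles <- function(mol, with_maps = FALSE) {
  stopifnot(inherits(mol, "pc_mol"))
  comp <- mol_components(mol)
  out <- character(0)
  for (ci in sort(unique(comp))) {
    idx <- which(comp == ci)
    sub <- mol_subgraph(mol, idx)
    nb <- mol_adj(sub)
    base_rank <- .canonical_ranks(sub, nb)
    roots <- which(base_rank == min(base_rank))
    best <- NULL
    for (root in roots) {
      rk <- if (length(roots) > 1) .canonical_ranks(sub, nb, boost = root) else base_rank
      s <- .write_component(sub, nb, rk, root, with_maps)
      if (is.null(best) || s < best) best <- s
    }
    out <- c(out, best)
  }
  paste(sort(out), collapse = ".")
}

#' Canonicalize a SMILES string
#'
#' @param text SMILES string.
#' @param with_maps keep atom-map numbers.
#' @return canonical SMILES of the same molecular graph.
#' @export
canonicalize_smiles <- function(text, with_maps = FALSE) {
  write_smiles(parse_smiles(text), with_maps = with_maps)
}
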