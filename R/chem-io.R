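# Reaction records, the photocatalyst registry, and dataset IO.

#' Load a photocatalyst registry
#'
#' The registry is the ordered label space shared by every model in the
#' package: one row per photocatalyst class with a 0-based `index`, a unique
#' short `name` and the SMILES of the photoactive species. Charged
#' photocatalysts are stored as the ionic form only, without counterions.
#'
#' The shipped default has 31 entries. The full published set of archetypal
#' photocatalysts is only partially enumerated in the open literature we
#' reconstruct from, so the default file is a synthetic reconstruction
#' (named in the file as such): the catalysts named in the primary text plus
#' standard archetypes to complete the set. It is data, not hard-coded truth:
#' pass any CSV with columns `index,name,smiles` to use a different registry.
#'
#' @param path CSV file with columns `index,name,smiles`; `NULL` for the
#'   shipped default registry of 31 photocatalysts.
#' @return a tibble of class `pc_registry`.
#' @export
#' @examples
#' reg <- pc_registry()
#' nrow(reg)
#' decode_label(encode_label("4CzIPN", reg), reg)
pc_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "photocatalyst_registry_synthetic.csv",
                        package = "photocatr")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "name", "smiles")
  if (!all(need %in% names(df)))
    rlang::abort("registry file must have columns index,name,smiles",
                 class = "photocatr_schema_error")
  df <- df[order(df$index), need]
  if (!identical(as.integer(df$index), seq_len(nrow(df)) - 1L))
    rlang::abort("registry indices must be 0..size-1 with no gaps",
                 class = "photocatr_schema_error")
  if (anyDuplicated(df$name))
    rlang::abort("registry names must be unique",
                 class = "photocatr_schema_error")
  out <- tibble::as_tibble(df)
  class(out) <- c("pc_registry", class(out))
  out
}

#' Number of catalyst classes in a registry
#'
#' @param registry a `pc_registry`.
#' @return integer class count (31 for the shipped default).
#' @export
registry_size <- function(registry) nrow(registry)

#' Encode / decode photocatalyst labels
#'
#' Bijection between registry names and 0-based integer labels (the one-hot
#' class indices used by both models), stable for a given registry file.
#'
#' @param name catalyst name(s).
#' @param i 0-based integer label(s).
#' @param registry a `pc_registry`.
#' @return `encode_label`: integer label(s); `decode_label`: name(s).
#' @export
encode_label <- function(name, registry) {
  idx <- match(name, registry$name)
  if (anyNA(idx))
    rlang::abort(sprintf("unknown catalyst name(s): %s",
                         paste(name[is.na(idx)], collapse = ", ")),
                 class = "photocatr_lookup_error")
  registry$index[idx]
}

#' @rdname encode_label
#' @export
decode_label <- function(i, registry) {
  if (any(i < 0L | i >= nrow(registry)))
    rlang::abort("label index out of range", class = "photocatr_lookup_error")
  registry$name[match(i, registry$index)]
}

# Split a reaction SMILES into reactant / agent / product strings.
split_reaction <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text))
    pc_parse_error("reaction SMILES must be a single string")
  parts <- strsplit(text, ">", fixed = TRUE)[[1]]
  n_arrows <- lengths(regmatches(text, gregexpr(">", text, fixed = TRUE)))
  if (n_arrows != 2)
    pc_parse_error(sprintf(
      "expected one reaction arrow ('>>' or '>agents>'), found %d '>'", n_arrows),
      text)
  parts <- c(parts, rep("", 3 - length(parts)))[1:3]
  if (!nzchar(parts[1]) || !nzchar(parts[3]))
    pc_parse_error("reactant and product sides must be nonempty", text)
  list(reactants = parts[1], agents = parts[2], products = parts[3])
}

#' Parse a reaction SMILES into a reaction record
#'
#' Accepts the 2-part (`reactants>>product`) and 3-part
#' (`reactants>agents>product`) dialects; agents are parsed but dropped with
#' a warning, because the recommender carries no information about
#' co-catalysts or additives. Records with more than one product molecule are
#' rejected unless `keep_largest_product = TRUE`, in which case the product
#' with the most atoms is kept.
#'
#' @param text reaction SMILES; atom-map numbers are preserved into
#'   `mapped_smiles` when present.
#' @param id record identifier.
#' @param catalyst optional catalyst label (validated elsewhere against a
#'   registry).
#' @param keep_largest_product keep the largest of several product molecules
#'   instead of rejecting the record.
#' @return a one-row tibble: `id`, `reaction_smiles` (canonical, map-free),
#'   `mapped_smiles` (canonical with maps, or `NA`), `catalyst`,
#'   `n_reactants`, `product`.
#' @export
#' @examples
#' parse_reaction("CCO.CC(=O)O>>CC(=O)OCC")
parse_reaction <- function(text, id = NA_character_, catalyst = NA_character_,
                           keep_largest_product = FALSE) {
  sides <- split_reaction(text)
  if (nzchar(sides$agents))
    rlang::warn(sprintf("agents '%s' are ignored", sides$agents),
                class = "photocatr_agents_dropped")

  rmol <- parse_smiles(sides$reactants)
  pmol <- parse_smiles(sides$products)

  pfrags <- unique(pmol$atoms$frag)
  if (length(pfrags) > 1) {
    if (!keep_largest_product)
      pc_parse_error(sprintf("expected a single product molecule, found %d",
                             length(pfrags)), sides$products)
    sizes <- vapply(pfrags, function(f) sum(pmol$atoms$frag == f), 0L)
    keep <- pfrags[which.max(sizes)]
    pmol <- mol_subgraph(pmol, which(pmol$atoms$frag == keep))
  }

  has_maps <- any(!is.na(rmol$atoms$map)) || any(!is.na(pmol$atoms$map))
  mapped <- NA_character_
  if (has_maps) {
    check_mapping(rmol, pmol)
    mapped <- paste0(write_smiles(rmol, with_maps = TRUE), ">>",
                     write_smiles(pmol, with_maps = TRUE))
  }

  reactant_frags <- sort(vapply(
    unique(rmol$atoms$frag),
    function(f) write_smiles(mol_subgraph(rmol, which(rmol$atoms$frag == f))),
    ""
  ))
  product <- write_smiles(pmol)

  tibble::tibble(
    id = id,
    reaction_smiles = paste0(paste(reactant_frags, collapse = "."), ">>", product),
    mapped_smiles = mapped,
    catalyst = catalyst,
    n_reactants = length(reactant_frags),
    product = product
  )
}

# Mapping integrity: map numbers unique within each side, and every product
# map number present on the reactant side.
check_mapping <- function(rmol, pmol) {
  rmap <- rmol$atoms$map[!is.na(rmol$atoms$map)]
  pmap <- pmol$atoms$map[!is.na(pmol$atoms$map)]
  if (anyDuplicated(rmap) || anyDuplicated(pmap))
    pc_parse_error("duplicate atom-map numbers within one reaction side")
  missing <- setdiff(pmap, rmap)
  if (length(missing))
    pc_parse_error(sprintf(
      "product atom-map number(s) %s absent from the reactant side",
      paste(missing, collapse = ", ")))
  invisible(TRUE)
}

#' Load a reaction dataset from CSV or JSONL
#'
#' Expected columns/fields: `id`, `reaction_smiles`, optional `mapped_smiles`,
#' `catalyst`. Records that fail validation (unparsable SMILES, multiple
#' products, broken atom mapping, labels outside the registry) are dropped
#' and counted, and exact duplicates on (canonical reaction SMILES, label)
#' are removed, mirroring the curation filters used to assemble reaction
#' corpora. The drop report is attached as attribute `"report"` and printed
#' by [load_report()].
#'
#' @param path `.csv` or `.jsonl` file.
#' @param registry `pc_registry` used to validate labels; `NULL` skips label
#'   validation.
#' @param keep_largest_product forwarded to [parse_reaction()].
#' @return tibble of validated records with a `"report"` attribute.
#' @export
read_reactions <- function(path, registry = NULL, keep_largest_product = FALSE) {
  fmt <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  raw <- if (fmt == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) data.frame() else
      dplyr::bind_rows(lapply(lines, function(l)
        tibble::as_tibble(jsonlite::fromJSON(l))))
  }
  if (!nrow(raw)) {
    rlang::warn("empty dataset file")
    out <- empty_records()
    attr(out, "report") <- tibble::tibble(reason = character(), n = integer())
    return(out)
  }
  if (!all(c("id", "reaction_smiles") %in% names(raw)))
    rlang::abort("dataset must have columns id and reaction_smiles",
                 class = "photocatr_schema_error")
  if (!"catalyst" %in% names(raw)) raw$catalyst <- NA_character_
  if (!"mapped_smiles" %in% names(raw)) raw$mapped_smiles <- NA_character_
  for (cl in c("catalyst", "mapped_smiles")) {
    blank <- !is.na(raw[[cl]]) & !nzchar(raw[[cl]])
    raw[[cl]][blank] <- NA_character_
  }

  validate_reactions(tibble::as_tibble(raw), registry = registry,
                     keep_largest_product = keep_largest_product)
}

empty_records <- function() {
  tibble::tibble(id = character(), reaction_smiles = character(),
                 mapped_smiles = character(), catalyst = character())
}

#' Validate a table of reaction records
#'
#' @param data tibble with `id`, `reaction_smiles`, optional `mapped_smiles`,
#'   optional `catalyst`.
#' @inheritParams read_reactions
#' @return validated, deduplicated tibble with a `"report"` attribute.
#' @export
validate_reactions <- function(data, registry = NULL,
                               keep_largest_product = FALSE) {
  reasons <- character(0)
  keep <- vector("list", nrow(data))
  for (r in seq_len(nrow(data))) {
    src <- if (!is.na(data$mapped_smiles[r]) && nzchar(data$mapped_smiles[r]))
      data$mapped_smiles[r] else data$reaction_smiles[r]
    rec <- tryCatch(
      suppressWarnings(parse_reaction(src, id = data$id[r],
                                      catalyst = data$catalyst[r],
                                      keep_largest_product = keep_largest_product)),
      photocatr_parse_error = function(e) conditionMessage(e)
    )
    if (is.character(rec)) {
      reasons <- c(reasons, paste0("invalid: ", sub(" \\(in fragment.*", "", rec)))
      next
    }
    if (!is.null(registry) && !is.na(rec$catalyst) &&
        !rec$catalyst %in% registry$name) {
      reasons <- c(reasons, "catalyst not in registry")
      next
    }
    keep[[r]] <- rec
  }
  out <- dplyr::bind_rows(keep)
  if (!nrow(out)) out <- empty_records()
  if ("split_tag" %in% names(data) && nrow(out))
    out$split_tag <- data$split_tag[match(out$id, data$id)]
  dup <- duplicated(paste(out$reaction_smiles, out$catalyst, sep = "\r"))
  if (any(dup)) reasons <- c(reasons, rep("duplicate reaction", sum(dup)))
  out <- out[!dup, , drop = FALSE]
  rep_tbl <- if (length(reasons)) {
    dplyr::count(tibble::tibble(reason = reasons), .data$reason, name = "n")
  } else tibble::tibble(reason = character(), n = integer())
  attr(out, "report") <- rep_tbl
  out
}

#' @rdname read_reactions
#' @param x a tibble returned by [read_reactions()] or [validate_reactions()].
#' @export
load_report <- function(x) attr(x, "report")

#' Write a reaction dataset to CSV or JSONL
#'
#' Inverse of [read_reactions()]: writing then reading reproduces the records
#' field-for-field.
#'
#' @param data record tibble.
#' @param path output `.csv` or `.jsonl` path.
#' @export
write_reactions <- function(data, path) {
  cols <- intersect(c("id", "reaction_smiles", "mapped_smiles", "catalyst",
                      "split_tag"), names(data))
  df <- as.data.frame(data[, cols])
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (r in seq_len(nrow(df))) {
      row <- as.list(df[r, ])
      row <- row[!vapply(row, function(v) is.na(v), TRUE)]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE), con)
    }
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
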