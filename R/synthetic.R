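# Synthetic atom-mapped, catalyst-labeled reaction corpora.
#
# Real photocatalysis corpora (Reaxys extracts, the Open Reaction Database)
# are not redistributable, so every model in the package is exercised on
# generated data with the same statistical structure the recommender relies
# on: each record instantiates a transformation template (fixed mapped
# sub-reaction, hence a constant reaction core) on a random scaffold, each
# template prefers one photocatalyst, class frequencies follow a Zipf-like
# power law (heavy imbalance), and labels carry tunable uniform noise.
#
# Template chemistry is hand-authored fixture chemistry: simple polar
# transformations on a 4-atom linker, not real photocatalytic mechanisms.
# The linker keeps every changed atom at least 4 bonds away from the
# scaffold attachment point, so the radius-3 core never touches the
# scaffold and extract_core() returns one constant core_key per template.

.L4 <- "[CH2:1][CH2:2][CH2:3][CH2:4]"
.LO <- "[CH2:1][O:2][CH2:3][CH2:4]"

.TEMPLATES <- local({
  t <- function(id, rtail, ptail, linker = .L4)
    list(id = id, r = paste0("{R}", linker, rtail),
         p = paste0("{R}", linker, ptail))
  list(
    t("sn2_thioether",   "[Br:5].[S-:6][CH3:7]",                  "[S:6][CH3:7]"),
    t("sn2_hydroxyl",    "[Br:5].[OH2:6]",                        "[OH:6]"),
    t("alkene_hydration","[CH:5]=[CH2:6].[OH2:7]",                "[CH2:5][CH2:6][OH:7]"),
    t("aldehyde_red",    "[CH:5]=[O:6]",                          "[CH2:5][OH:6]"),
    t("alcohol_ox",      "[CH2:5][OH:6]",                         "[CH:5]=[O:6]"),
    t("esterification",  "[OH:5].[OH:6][C:7](=[O:8])[CH3:9]",     "[O:5][C:7](=[O:8])[CH3:9]"),
    t("amidation",       "[NH2:5].[OH:6][C:7](=[O:8])[CH3:9]",    "[NH:5][C:7](=[O:8])[CH3:9]"),
    t("cyanation",       "[Br:5].[C-:6]#[N:7]",                   "[C:6]#[N:7]"),
    t("azidation",       "[Br:5].[N-:6]=[N+:7]=[N-:8]",           "[N:6]=[N+:7]=[N-:8]"),
    t("amination",       "[Br:5].[NH2:6][CH3:7]",                 "[NH:6][CH3:7]"),
    t("williamson",      "[Br:5].[O-:6][CH3:7]",                  "[O:6][CH3:7]"),
    t("thiol_ene",       "[CH:5]=[CH2:6].[SH:7][CH3:8]",          "[CH2:5][CH2:6][S:7][CH3:8]"),
    t("halex",           "[Cl:5].[I-:6]",                         "[I:6]"),
    t("ester_hydrolysis","[C:5](=[O:6])[O:7][CH3:8].[OH2:9]",     "[C:5](=[O:6])[OH:9]"),
    t("imine_formation", "[C:5](=[O:6])[CH3:7].[NH2:8][CH3:9]",   "[C:5](=[N:8][CH3:9])[CH3:7]"),
    t("dibromination",   "[CH:5]=[CH2:6].[Br:7][Br:8]",           "[CH:5]([Br:7])[CH2:6][Br:8]"),
    t("epoxidation",     "[CH:5]=[CH2:6].[OH:7][OH:8]",           "[CH:5]1[O:7][CH2:6]1"),
    t("alkyne_semired",  "[C:5]#[CH:6]",                          "[CH:5]=[CH2:6]"),
    t("nitro_reduction", "[N+:5](=[O:6])[O-:7]",                  "[NH2:5]"),
    t("appel_bromide",   "[OH:5].[Br:6][Br:7]",                   "[Br:6]"),
    t("o_methylation",   "[OH:5].[I:6][CH3:7]",                   "[O:5][CH3:7]", .LO),
    t("sulfoxidation",   "[S:5][CH3:6].[OH:7][OH:8]",             "[S+:5]([O-:7])[CH3:6]", .LO),
    t("ketone_red",      "[C:5](=[O:6])[CH3:7]",                  "[CH:5]([OH:6])[CH3:7]", .LO),
    t("radical_bromination", "[CH3:5].[Br:6][Br:7]",              "[CH2:5][Br:6]", .LO)
  )
})

# attachment-first mapped scaffold fragments; the `{R}` slot of a template.
.SCAFFOLDS <- c(
  "[CH3:51]",
  "[CH2:51]([CH3:52])",
  "[CH2:51]([CH2:52][CH3:53])",
  "[CH:51]([CH3:52])([CH3:53])",
  "[CH2:51]([CH2:52][CH2:53][CH3:54])",
  "[CH2:51]([CH:52]([CH3:53])[CH3:54])",
  "[c:51]1([cH:52][cH:53][cH:54][cH:55][cH:56]1)",
  "[CH2:51]([O:52][CH3:53])",
  "[CH2:51]([CH2:52][c:53]2([cH:54][cH:55][cH:56][cH:57][cH:58]2))",
  "[CH2:51]([CH2:52][O:53][CH3:54])",
  "[CH:51]([CH3:52])([CH2:53][CH3:54])",
  "[CH2:51]([CH2:52][CH2:53][CH2:54][CH3:55])"
)

#' Shipped transformation templates
#'
#' @return tibble: `template_id`, `rank` (Zipf frequency rank as shipped),
#'   `reactant_pattern`, `product_pattern`, `preferred_catalyst` (index into
#'   the given registry).
#' @param registry `pc_registry` defining the label space.
#' @export
pc_templates <- function(registry = pc_registry()) {
  n <- length(.TEMPLATES)
  C <- nrow(registry)
  pref <- (7L * seq_len(n)) %% C
  tibble::tibble(
    template_id = vapply(.TEMPLATES, `[[`, "", "id"),
    rank = seq_len(n),
    reactant_pattern = vapply(.TEMPLATES, `[[`, "", "r"),
    product_pattern = vapply(.TEMPLATES, `[[`, "", "p"),
    preferred_catalyst = registry$name[pref + 1L]
  )
}

#' Generator configuration
#'
#' Defaults define the study conditions emulated throughout the package:
#' 20 transformation templates, Zipf imbalance exponent 1.1 over template
#' rank (heavy head/tail spread, echoing corpora where the commonest
#' photocatalyst has hundreds of times more records than the rarest), and
#' 10% uniform label noise.
#'
#' @param n_records number of reactions to generate.
#' @param n_templates number of templates used (<= number shipped, 24).
#' @param registry `pc_registry`.
#' @param imbalance_exponent positive Zipf exponent over template rank.
#' @param label_noise fraction of records whose label is resampled uniformly
#'   among the *other* catalysts; the Bayes top-1 ceiling is `1 - label_noise`.
#' @param seed RNG seed; identical config + seed reproduces output exactly.
#' @export
generator_config <- function(n_records = 1000L, n_templates = 20L,
                             registry = pc_registry(),
                             imbalance_exponent = 1.1, label_noise = 0.1,
                             seed = 1L) {
  if (n_templates < 1 || n_templates > length(.TEMPLATES))
    rlang::abort(sprintf("n_templates must be in 1..%d", length(.TEMPLATES)))
  if (label_noise < 0 || label_noise >= 1)
    rlang::abort("label_noise must be in [0, 1)")
  if (imbalance_exponent <= 0)
    rlang::abort("imbalance_exponent must be positive")
  structure(list(n_records = as.integer(n_records),
                 n_templates = as.integer(n_templates), registry = registry,
                 imbalance_exponent = imbalance_exponent,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "pc_generator_config")
}

.zipf_weights <- function(n, s) {
  w <- seq_len(n)^(-s)
  w / sum(w)
}

.instantiate <- function(template, scaffold) {
  list(r = sub("{R}", scaffold, template$r, fixed = TRUE),
       p = sub("{R}", scaffold, template$p, fixed = TRUE))
}

#' Generate a synthetic labeled reaction dataset
#'
#' Per record: a template is drawn with Zipf-rank probability, decorated with
#' a random scaffold, and emitted as a fully atom-mapped reaction (plus its
#' canonical unmapped reaction SMILES). The label is the template's preferred
#' catalyst with probability `1 - label_noise`, otherwise a uniformly random
#' *other* catalyst. All records pass [validate_reactions()] by construction.
#'
#' @param config a [generator_config()].
#' @return record tibble (`id`, `reaction_smiles`, `mapped_smiles`,
#'   `catalyst`) with the ground-truth table (id, template_id,
#'   true_catalyst) attached as attribute `"truth"`; see [ground_truth()].
#' @export
generate_reactions <- function(config = generator_config()) {
  reg <- config$registry
  tmpl <- pc_templates(reg)[seq_len(config$n_templates), ]
  w <- .zipf_weights(config$n_templates, config$imbalance_exponent)
  n <- config$n_records

  withr::with_seed(config$seed, {
    t_idx <- sample.int(config$n_templates, n, replace = TRUE, prob = w)
    s_idx <- sample.int(length(.SCAFFOLDS), n, replace = TRUE)
    noise <- stats::runif(n) < config$label_noise
    wrong <- sample.int(nrow(reg) - 1L, n, replace = TRUE)
  })

  mapped <- character(n); plain <- character(n); labels <- character(n)
  truth_cat <- character(n)
  side_cache <- new.env(parent = emptyenv())
  canon <- function(s, maps = FALSE) {
    key <- paste0(maps, "\r", s)
    v <- side_cache[[key]]
    if (is.null(v)) {
      v <- canonicalize_smiles(s, with_maps = maps)
      side_cache[[key]] <- v
    }
    v
  }
  for (r in seq_len(n)) {
    tp <- .TEMPLATES[[tmpl$rank[t_idx[r]]]]
    inst <- .instantiate(tp, .SCAFFOLDS[s_idx[r]])
    mapped[r] <- paste0(canon(inst$r, TRUE), ">>", canon(inst$p, TRUE))
    plain[r] <- paste0(canon(inst$r), ">>", canon(inst$p))
    pref <- tmpl$preferred_catalyst[t_idx[r]]
    truth_cat[r] <- pref
    if (noise[r]) {
      others <- setdiff(reg$name, pref)
      labels[r] <- others[wrong[r]]
    } else labels[r] <- pref
  }

  out <- tibble::tibble(
    id = sprintf("syn-%06d", seq_len(n)),
    reaction_smiles = plain,
    mapped_smiles = mapped,
    catalyst = labels
  )
  attr(out, "truth") <- tibble::tibble(
    id = out$id,
    template_id = tmpl$template_id[t_idx],
    true_catalyst = truth_cat
  )
  out
}

#' @rdname generate_reactions
#' @param x a tibble returned by [generate_reactions()].
#' @export
ground_truth <- function(x) attr(x, "truth")

#' Unlabeled (core, reaction) pairs for masked-LM pretraining
#'
#' Generates reactions as [generate_reactions()] (labels discarded), extracts
#' each core with [extract_core()], and returns the two-sentence pairs the
#' language model consumes, with a disjoint held-out slice marked.
#'
#' @param config a [generator_config()].
#' @param holdout_frac fraction of pairs marked as held out (default 0.1).
#' @return tibble: `id`, `core_smiles`, `reaction_smiles`, `holdout`.
#' @export
corpus_for_pretraining <- function(config = generator_config(),
                                   holdout_frac = 0.1) {
  recs <- generate_reactions(config)
  core_cache <- new.env(parent = emptyenv())
  cores <- vapply(recs$mapped_smiles, function(ms) {
    v <- core_cache[[ms]]
    if (is.null(v)) {
      v <- extract_core(ms)$core_smiles
      core_cache[[ms]] <- v
    }
    v
  }, "", USE.NAMES = FALSE)
  n <- nrow(recs)
  hold <- withr::with_seed(config$seed + 1L,
                           sample.int(n, max(1L, round(holdout_frac * n))))
  tibble::tibble(id = recs$id, core_smiles = cores,
                 reaction_smiles = recs$reaction_smiles,
                 holdout = seq_len(n) %in% hold)
}
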