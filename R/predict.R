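# The recommendation surface: reduce an input reaction to its core, score it
# with a trained model, and return the ranked top-k photocatalysts.

#' Recommend photocatalysts for a reaction
#'
#' Mirrors the interactive predictor contract: the input needs only
#' substrates and product separated by a reaction arrow. When the input
#' carries atom maps the reaction core is extracted and fingerprinted /
#' encoded; unmapped input falls back to the full reaction (with a warning),
#' since core extraction requires a mapped reaction.
#'
#' Two caveats are part of the contract and attached to the result: the
#' model ranks catalysts for *any* input reaction, including ones that are
#' not photocatalytic, and confidence values are internal model scores that
#' do not predict experimental yields.
#'
#' @param model a fitted `pc_mlp` or `pc_lm_classifier`.
#' @param reaction_smiles reaction SMILES (`substrates>>product`).
#' @param k recommendation list length (default 5).
#' @param registry `pc_registry` for catalyst names; defaults to the model's
#'   registry or the shipped default.
#' @return a `pc_prediction`: input canonical SMILES, core SMILES, and a
#'   `recommendations` tibble (`rank`, `name`, `confidence`).
#' @export
predict_reaction <- function(model, reaction_smiles, k = 5L, registry = NULL) {
  rec <- parse_reaction(reaction_smiles)
  registry <- registry %||% model$registry %||% pc_registry()
  core <- ""
  if (!is.na(rec$mapped_smiles)) {
    cr <- extract_core(rec$mapped_smiles)
    if (!cr$is_identity) core <- cr$core_smiles
  } else {
    rlang::warn("input has no atom maps: scoring the full reaction instead of its core",
                class = "photocatr_no_core")
  }

  if (inherits(model, "pc_mlp")) {
    n_bits <- nrow(model$params$Wm)
    sides <- split_reaction(rec$reaction_smiles)
    m <- morgan_fp(sides$reactants, n_bits = n_bits)
    d <- drfp(if (nzchar(core)) core else rec$reaction_smiles,
              n_bits = nrow(model$params$Wd))
    feat <- tibble::as_tibble(c(
      stats::setNames(as.list(m), paste0("m", seq_len(n_bits))),
      stats::setNames(as.list(d), paste0("d", seq_along(d)))))
    prob <- predict_proba(model, feat)[1, ]
  } else if (inherits(model, "pc_lm_classifier")) {
    prob <- predict_proba(model, tibble::tibble(
      core_smiles = core, reaction_smiles = rec$reaction_smiles))[1, ]
  } else {
    rlang::abort("model must be a pc_mlp or pc_lm_classifier")
  }

  if (length(prob) != nrow(registry))
    rlang::abort("model output dimension does not match the registry")
  rk <- top_k(ranking(prob, registry), k = k)
  structure(list(
    reaction = rec$reaction_smiles,
    core = core,
    recommendations = tibble::tibble(rank = rk$rank, catalyst = rk$name,
                                     confidence = rk$confidence)
  ), class = "pc_prediction")
}

#' @export
print.pc_prediction <- function(x, ...) {
  cat("Reaction:", x$reaction, "\n")
  cat("Core:    ", if (nzchar(x$core)) x$core else "(not available)", "\n")
  r <- x$recommendations
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %2d. %-10s %.4f\n", r$rank[i], r$catalyst[i],
                r$confidence[i]))
  cat("Note: suggestions are produced for any input reaction, photocatalytic or not.\n")
  cat("Note: confidence is an internal model score, not a yield predictor.\n")
  invisible(x)
}
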