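---
title: "Recommending photocatalysts from reaction SMILES: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending photocatalysts from reaction SMILES: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Choosing a photocatalyst (PC) for a new light-driven transformation is still
largely done by screening a handful of popular catalysts (4CzIPN, a few Ir
and Ru complexes), which wastes effort and biases the literature toward the
same compounds. `photocatr` treats the choice as a multiclass classification
problem: given a reaction written as SMILES (`substrates>>product`), rank a
fixed registry of 31 archetypal photocatalysts by the model's confidence
that each would catalyze the reaction. Two model families are implemented —
a dual-input multilayer perceptron over reaction fingerprints, and a
masked-language-model transformer over tokenized SMILES — together with the
evaluation protocol (stratified 5-fold cross-validation; accuracy, weighted
and macro F1, top-k accuracy) and a synthetic corpus generator that makes
the whole pipeline testable without access to proprietary reaction data.

Two caveats are part of the contract and printed with every prediction:
the models will rank catalysts for *any* input, including reactions that
cannot be performed photocatalytically (a known limitation of one-hot
catalyst encodings), and the confidence score is an internal model quantity
that does not predict experimental yield.

## Reaction representation

**Reaction cores.** For an atom-mapped reaction, an atom is *changed* when
its multiset of (neighbor map number, bond order) pairs, its formal charge,
or its total hydrogen count differs between the reactant and product sides;
atoms present on only one side (leaving groups, incorporated reagents) are
always changed. The *core* is the changed set expanded by breadth-first
search to a bond-distance radius of 3 (the default; `extract_core(radius=)`),
expanded on the side where each atom exists. The induced subgraphs of both
sides are serialized as a canonical, map-free reaction SMILES that doubles
as a reaction-type key: the same transformation applied to different
substrates yields a string-identical key whenever the template's full
context lies inside the radius.

Because no installed R package models atom-mapped reaction SMILES, the
package carries its own molecular-graph engine: a SMILES parser for the
organic subset plus bracket atoms (charges, explicit hydrogens, map
numbers, aromatic lowercase forms), and a canonical writer based on
Morgan-style iterative rank refinement with root individualization (every
atom in the minimal rank class is tried as the DFS root and the
lexicographically smallest string is kept). Stereochemistry is accepted on
input and ignored — change detection is constitution-level only. Severed
bonds at the core boundary are left as implicitly open valences: boundary
atoms keep the hydrogen count they had in the full molecule and are written
as bracket atoms where needed, so cores remain valid SMILES without dummy
atoms. Atom mapping itself is out of scope: mapped input is required (any
external mapper, or the generator's exact maps); unmapped predictions fall
back to full-reaction fingerprints with a warning.

**Fingerprints.** The MLP consumes two binary vectors of 64 bits each (the
published size): a folded Morgan fingerprint of the concatenated substrates
and a differential reaction fingerprint (DRFP) of the core. Circular
environments (radius 0..r around every atom, as canonical subgraph SMILES
with original hydrogen counts) are hashed with FNV-1a 32-bit — a fixed,
platform-independent string hash, never a process-randomized one — and
folded modulo the vector size. The DRFP is the folded *symmetric
difference* between the reactant-side and product-side environment sets, so
an identity reaction maps to the zero vector and the fingerprint is
symmetric in the reaction direction; folding commutes with the modulus
(computing at 128 bits and refolding modulo 64 reproduces the 64-bit
vector). The Morgan radius is not pinned by the published configuration
(only the size is); the conventional radius 2 is the default, and only the
substrates are fingerprinted (`include_product`-style ablations can be run
by fingerprinting the full reaction through `drfp(..., n_bits, radius)`
directly).

## The MLP recommender

Each input (Morgan, DRFP) passes through its own hidden layer; the two
representations are concatenated and followed by two further hidden layers
and a linear output of one logit per registry entry, turned into a ranking
by softmax. Defaults: hidden 128 + 128, post-merge 128 and 64, ReLU,
uniform fan-in initialization, Adam (learning rate 1e-3), 50 epochs, batch
256, all exposed in `mlp_config()`. A small `mlp_random_search()` utility
mirrors the kind of hyperparameter search used to fix such defaults but is
not needed for any result. Training is plain single-threaded matrix
algebra: the same seed gives bit-identical weights and reports.

**Class weighting.** To counter imbalance the loss is weighted
cross-entropy with `w_c = N / (C_nonzero * n_c)` (absent classes weight 0);
the weighted mean of the weights over observed samples is 1. One measured
property of this weighting deserves a warning. Under *uniform label noise*
eps, a class that receives only noise labels collects `n_c ≈ N·eps/(C-1)`
records and hence weight `w_c ≈ (C-1)/(C·eps)` — about 10 for eps = 0.1 and
C = 31. On a corpus whose substrate diversity is modest (the synthetic
generator produces a few hundred distinct (template, scaffold) cells), a
single high-weight noise record can outweigh the handful of correctly
labeled records in its cell, so the weighted optimum itself misclassifies
those cells and held-out top-1 accuracy saturates far below the noise
ceiling — we measured a plateau near 0.5 at full-batch convergence.
Balanced weighting deliberately trades top-1 accuracy for class balance.
Consequently the label-recovery benchmark is run with `weighted = FALSE`
(where the network recovers the `1 - eps` Bayes ceiling to within a few
points), while the benefit of weighting is demonstrated where it belongs,
as a macro-F1 improvement on a 95:5 imbalanced fixture. On large, diverse
real corpora the pathology is much weaker because per-cell memorization is
not attainable.

## The transformer recommender

The second model is a scaled-down RoBERTa-style pipeline:

1. **Tokenizer** — byte-level BPE trained on the corpus. The base
   vocabulary is the 5 special tokens plus all 256 byte values, so *any*
   string encodes with zero unknown tokens; merges (learned greedily, ties
   broken lexicographically) compress frequent SMILES substrings. Training
   is fully deterministic.
2. **Two-sentence encoding** — `[CLS] core [SEP] reaction [SEP]`, padded to
   `max_len`. The core is sentence A and the full reaction sentence B;
   over-length inputs are truncated from the right of sentence B only, so
   the core is never cut. An empty core (identity reaction) degenerates to
   `[CLS][SEP] reaction [SEP]`.
3. **Static masking** — 15% of non-special tokens are selected once per
   corpus build (not re-sampled per epoch) and replaced by the mask token.
   Pure mask-token replacement is the default; the BERT-style 80/10/10
   split sits behind `bert_split = TRUE`.
4. **Pretraining** — 2 epochs of masked-token cross-entropy; a held-out
   slice is scored before training (the untrained baseline) and after each
   epoch.
5. **Fine-tuning** — 10 epochs of cross-entropy on the pooled
   first-position representation through a linear head over the registry.
   Fine-tuning is unweighted by default (`weighted = TRUE` available).

The reference encoder is deliberately small — 2 layers, 2 heads, embedding
64 (32 in the test fixtures), maximum input length 128 — chosen so that
pretraining plus fine-tuning runs in minutes on one CPU in pure R; the
published input length of 1024 and deeper encoders are plain `lm_config()`
settings. Forward and backward passes are hand-written matrix algebra
(verified against finite differences in the test suite), so fixed seeds
give bit-identical checkpoints.

## Evaluation protocol

`stratified_kfold()` assigns folds balanced within one record overall and
per class; classes rarer than `k` are merged into a single auxiliary
stratum for splitting only (with a warning), which still spreads their
members across distinct folds. `cross_validate()` reports per-fold
accuracy, weighted F1, macro F1 and the full top-k curve, aggregated as
mean ± sd (the headline reporting shape) alongside pooled out-of-fold
metrics — both forms are emitted because either convention is defensible.
Rankings break exact probability ties by ascending registry index, making
top-k deterministic. Per-class F1 uses the 0/0 → 0 convention; macro F1
averages over classes present in the true labels.

## The synthetic generator

`generate_reactions()` emulates the statistical structure the recommender
relies on, not photocatalytic mechanism: ~24 hand-authored transformation
templates (halide displacements, ester/amide formation, small redox steps)
on a 4-atom linker, decorated with random alkyl/aryl/ether scaffolds. The
linker keeps every changed atom at least 4 bonds from the scaffold
attachment, so the radius-3 core — and therefore the DRFP — is constant per
template, giving the learnable core→catalyst signal. Class frequencies
follow a Zipf law over template rank (default exponent 1.1 over 20
templates, a largest/smallest ratio around 25–30, echoing corpora where
the commonest catalyst has orders of magnitude more records than the
rarest); each template prefers one catalyst, and labels are flipped to a
uniformly random *other* catalyst with probability `label_noise` (default
0.1), so the Bayes top-1 ceiling is `1 - label_noise` and trained models
are judged against that ceiling, not against 100%.

What the generator does *not* emulate: real substrate diversity (a few
hundred distinct substrate cells instead of tens of thousands), mechanism
(templates are generic polar chemistry, not photoredox steps), unbalanced
stoichiometry beyond simple byproduct omission, and any correlation between
catalyst and substrate *outside* the core. Passing tests therefore
demonstrate that the pipeline recovers template-determined signal under
imbalance and label noise — not that the shipped weights transfer to real
photocatalysis data, which requires retraining on a licensed corpus.

The shipped catalyst registry is itself a reconstruction (the file is
named `photocatalyst_registry_synthetic.csv`): the canonical set of 31
archetypal photocatalysts is only partially enumerated in the open
literature, so the registry combines the 20 catalysts that are named
openly with 11 standard archetypes, stores ionic forms without
counterions, and is deliberately editable data rather than hard-coded
truth.

## Numerical choices and degenerate inputs

* Canonicalization: iterative refinement ranks on (element, aromaticity,
  charge, H count, degree), refined by sorted neighbor (order, rank) keys
  with a numerically stable relabeling; among tied minimal-rank atoms every
  root is tried and the smallest string kept. Remaining ties inside a DFS
  are broken by rank, bond order, then element.
* Aromatic bonds count 1.5 toward valence; implicit hydrogens fill to the
  smallest standard valence. Multi-valence elements (N, P, S) use the
  smallest consistent valence.
* Softmax rows are normalized within 1e-6 and asserted in tests; ranking
  ties (exact float equality) go to the lower registry index.
* Identity reactions: empty changed set → flagged empty core; the
  fingerprint path falls back to the full reaction; the LM path encodes an
  empty sentence A.
* Degenerate training inputs (single-class data, labels out of range,
  non-finite losses) abort with explicit errors rather than degrade.
* Duplicate records are dropped on load keyed by (canonical reaction
  SMILES, label); multi-product records are rejected unless
  `keep_largest_product = TRUE`.

## Problem sizes used in the shipped checks

The test suite and the acceptance script size their fixtures for a
single-CPU run: label recovery uses 5 000 generated records (noise 0.1,
80/20 split and a 5-fold CV), the weighted-loss ablation 500-record 95:5
fixtures over five seeds, masking statistics ~1 000 encodings, and the
pretraining study a 600-pair corpus with a 2-epoch pretrain, a 10-epoch
fine-tune on 150–200 scarce-labeled records over 24 template classes, and
a 3–5-seed pretrained-vs-scratch comparison at embedding 32.
These sizes are the package's reference configuration for reproducible
desk-scale runs; all of them scale up through the same config objects.

## Known limitations

* The SMILES dialect covers organic-subset chemistry with charges,
  aromatic rings and atom maps; organometallic dative-bond SMILES (the
  registry entries for Ir/Ru complexes) are stored as metadata but not
  parsed by the graph engine.
* Stereochemistry is ignored throughout; cores and fingerprints are
  constitution-level.
* Confidence calibration is not attempted (plain softmax), matching the
  upstream observation that confidence does not track yields.
* The pure-R transformer is a reference implementation: correct and
  reproducible, but not fast; paper-scale pretraining would need a tensor
  backend.
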