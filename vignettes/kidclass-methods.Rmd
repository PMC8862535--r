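---
title: "kidclass: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kidclass: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the
classification model and its assumptions, the parameters that matter, what
the built-in simulator does and does not emulate, and the choices made where
the design was genuinely open. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The classification model

`kidclass` classifies single cells against a fixed, rooted identity tree.
The shipped tree covers the developing human kidney: five first-tier
lineages (stroma, nephron progenitors, nephron, ureteric epithelium,
endothelium), second-tier segments under stroma, nephron and ureteric
epithelium, and third-tier subtypes under the distal nephron, proximal
nephron and renal corpuscle. The tree is data — a JSON document under
`inst/extdata/` — so the same engine applies to any tissue whose identities
form a hierarchy.

Every internal node with at least two child identities owns one multi-class
model, trained only on the reference cells belonging to that node's subtree.
The per-node pipeline is:

1. **Log-normalization.** Raw counts are scaled per cell to a library size
   of 10,000 and natural-log transformed with pseudocount 1:
   $x_{cg} = \ln(1 + 10^4\, n_{cg} / \sum_g n_{cg})$. No other preprocessing
   is required of the user; `predict()` normalizes internally.
2. **Variable genes.** Up to `n_hvg` (default 10,000) genes ranked by
   mean-binned normalized dispersion: per-gene dispersion (variance/mean of
   the log-normalized values) is z-scored within 20 equal-frequency bins of
   the gene mean. Genes that are constant in the normalized layer rank last.
3. **PCA.** The top `n_pcs` (default 100, capped at `n_cells - 1`)
   components by exact eigendecomposition of the gene-gene (or cell-cell,
   whichever is smaller) covariance. Loadings carry a deterministic sign
   convention (largest-magnitude element positive) so results do not depend
   on LAPACK sign freedom.
4. **One round of harmonization** (only when a batch key is supplied) —
   see below.
5. **Calibrated one-vs-rest classifiers.** For each child identity a binary
   radial-kernel SVM (`e1071`, cost 1, gamma = 1 / (dimension × mean score
   variance), no feature scaling) is fitted. Cross-validated decision values
   (default 3 folds) feed a Platt sigmoid fitted by the damped Newton
   scheme of Platt/Lin — robust to perfectly separable folds, where an
   unpenalized logistic fit diverges — and the same held-out decisions give
   per-class AUROC/sensitivity/specificity, stored in the model and printed
   by `summary()`. `"logistic"` and `"mlp"` (single hidden layer, `nnet`)
   classifiers are available through the same interface for benchmarking.

One-vs-rest probabilities are deliberately **not renormalized** to sum to 1.
The rejection rule compares the maximum calibrated score against an absolute
threshold; renormalizing would inflate uniformly-low rows — precisely the
out-of-reference cells the threshold exists to reject.

### Tiered prediction and rejection

All query cells are scored by the first-tier model. A cell is assigned the
class of its highest score if that score is at least the threshold (default
0.7) and is `unassigned` otherwise; the boundary is read inclusively, a
documented choice where either convention is defensible, and ties go to the
first class in tree order. Assigned cells are routed to their lineage's
child model, where assignment at tiers 2 and 3 is pure argmax — no cell is
unassigned below tier 1. Unassigned cells are not evaluated further. Every
evaluated probability is recorded as a `p_<node>_<class>` column so the full
score structure stays available for threshold calibration
(`threshold_sweep()`, `probability_summary()`, `auroc()`, `auprc()`).

### NPC refinement

Organoids contain a population with an NPC-adjacent transcriptome but
little *PAX2* expression, best treated as an in vitro artefact rather than
true nephron progenitors. After classification, NPC-called cells are
re-embedded and re-clustered (Jaccard-weighted shared-nearest-neighbour
graph, k = 15, prune 0.2; Louvain at resolution 0.5), and every cluster in
which strictly fewer than 30% of cells have a nonzero raw PAX2 count is
relabelled `NPC-like` in the final identity. Design choices here:

* The subset re-embedding uses the top 200 genes by plain variance of the
  log-normalized values (10 components) rather than the binned-dispersion
  statistic used for node training: within an otherwise homogeneous
  population an on/off marker switch is simply a high-variance bimodal
  gene, and the binned statistic normalizes that signal away.
* The gate gene itself is excluded from the embedding, so the PAX2 fraction
  is measured on clusters rather than used to define them.
* The tier-1 label remains `NPC` for auditability; only `final_label`
  changes. Both NPC and NPC-like cells re-enter the subset on repeated
  calls, making refinement idempotent, and the operation only ever converts
  NPC to NPC-like.
* Fewer than three NPC cells are treated as a single cluster.

### One round of batch harmonization

When a batch key is given, each node applies a single
clustering-plus-correction cycle to its PCA scores: cells are clustered by
k-means (k = min(20, n/30), at least 2) and, within every cluster, each
batch's centroid is translated onto the cluster centroid. Two details
matter. First, the clustering runs on *batch-centered* scores (each batch's
global centroid translated onto the pooled centroid) — otherwise a strong
global batch displacement lets hard k-means isolate one batch into its own
clusters, leaving the correction with nothing to align. Second, the
corrected cluster centroids are stored so queries can be corrected against
the reference afterwards: query cells (per query batch, or as a single
batch) are globally centered the same way, assigned to their nearest stored
centroid, and translated per cluster. Exactly one round is run; the
clustering seed is a recorded parameter.

## The simulator

`simulate_kidney()` generates hierarchically structured counts so that
training, rejection, refinement and harmonization are all testable without
external data. Counts are negative binomial (dispersion 0.5, i.e. NB size
2) — the standard overdispersed model for UMI counts. Structure:

* **Baselines.** Per-gene baseline means are lognormal (sdlog 0.8) around
  the configured median (0.5), emulating the wide expression-level
  distribution of real transcriptomes. This heterogeneity is what makes
  variable-gene selection meaningful: with a flat baseline all markers
  would share one mean bin and the dispersion statistic would normalize
  them against each other.
* **Programs.** Every terminal identity has 20 private marker genes and
  inherits the 20-gene program of each internal ancestor, all at fold
  change 8 over baseline. Ancestor sharing makes sibling identities harder
  to separate than cross-lineage ones — the situation a tiered classifier
  is designed for.
* **Off-target identities** (e.g. muscle-like, immune-like) draw their
  programs from reserved genes disjoint from every tree program: a ground
  truth for rejection.
* **Batches** are assigned round-robin and scale every gene's mean by
  exp(N(0, log(batch_effect_scale))) — a purely technical effect, identical
  across identities within a batch.
* **NPC-like cells** carry the NPC program minus a 10-gene PAX2-linked
  sub-program (those genes revert to baseline) with PAX2 itself silenced.
  PAX2's baseline is pinned at the median so the expressing fraction in
  true NPCs is stable across seeds.

What the simulator does *not* emulate: doublets, ambient RNA, cell-cycle
structure, continuous differentiation trajectories, gene-gene correlation
beyond the block programs, and depth variation beyond NB sampling. Passing
tests therefore demonstrate that the engine's logic and numerics behave as
specified under its own assumptions — not that any particular accuracy will
transfer to real organoid data.

## Study conditions used by the tests and the acceptance script

Problem sizes were chosen once as the package's standard conditions: the
full 19-terminal tree at 300 cells per terminal and 2,000 genes for held-out
recovery and NPC refinement; 150 cells per terminal plus 300 off-target
cells for rejection; 100 cells per terminal, 1,500 genes, two batches at
batch_effect_scale 1.5 for the harmonization comparison; 40–60 cells per
terminal for the fast unit fixtures. Node training caps `n_pcs` at
`n_cells - 1`, so the same code paths run at every scale.

## Numerical and interface choices

* **Determinism.** Every stochastic step (fold assignment, k-means,
  Louvain, simulation) derives from an explicit seed. Training sorts cells
  bytewise by id first, so results are invariant to input order — and, by
  the same token, to the session's locale; stratified splits iterate strata
  in order of first appearance for the same reason.
* **Gene matching** across datasets is by exact identifier after whitespace
  stripping; no case folding, which silently merges distinct ids. Queries
  missing model genes have them imputed at the reference mean (zero after
  centering); below 80% overlap a warning is raised, below 50% an error.
* **Metrics.** AUROC is the rank-based (Mann–Whitney) statistic with half
  credit for ties; AUPRC is the step-function area with equal scores
  entering as one block and no interpolation — constant scores give the
  prevalence, as expected of an uninformative classifier.
* **Serialization.** A model bundle is a directory with a JSON manifest
  (format version, engine parameters, the identity tree and its digest) and
  one artifact per node, each checksummed; loading verifies version, digest
  and checksums, so corruption surfaces as an error rather than as silently
  wrong predictions.
* **Composition tables** at tiers 2–3 keep identities that terminate higher
  (NPC, Endo, unassigned) under their deepest label, so percentages always
  total 100 per sample; NPC-like replaces NPC wherever it was called.
  `dotplot_stats()` averages log-normalized expression over *all* cells of
  a group (zeros included), the dominant dot-plot convention.

## Known limitations

* The NPC-like split depends on the silenced sub-program being separable in
  the subset embedding; at small NPC counts (tens of cells) the Louvain
  partition can leave a mixed cluster above the 30% gate, under-calling
  NPC-like cells.
* The harmonization is a single hard-assignment round by design; it removes
  per-cluster batch displacement but not batch-specific variance or
  rotations.
* Rejection depends on off-target populations being far from every training
  class in the node feature space; an off-target population that mimics a
  training class's program would be absorbed, as with any
  reference-limited classifier.
* The identity tree is fixed at training time; cells from identities absent
  from the tree can only ever be `unassigned`.
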