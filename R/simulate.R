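#' Simulation configuration
#'
#' Describes a hierarchically structured scRNA-seq population: every
#' terminal identity of the tree receives its own marker program, every
#' internal node a lineage-shared program inherited by all its descendants,
#' so sibling identities are closer to each other than to other lineages —
#' the structure a tiered classifier assumes. Counts are negative binomial;
#' marker genes have their mean multiplied by `marker_fold_change` in the
#' cells that carry the program. Optional ingredients: batches with a pure
#' technical (identity-independent) multiplicative effect, off-target
#' identities drawn from reserved genes that share no program with the tree
#' (an unassigned-truth population), and an NPC-like subpopulation generated
#' from the NPC program with its PAX2-linked sub-program ablated.
#'
#' @param tree Identity tree (default [kidney_tree()]).
#' @param n_cells_per_leaf Cells simulated per terminal identity.
#' @param n_genes Total genes (marker demand must fit).
#' @param n_markers_per_leaf Genes in each terminal program.
#' @param n_markers_per_node Genes in each internal (lineage-shared) program.
#' @param marker_fold_change Mean fold change on program genes (default 8).
#' @param baseline_mean Median baseline NB mean; per-gene baselines are
#'   drawn from a lognormal around it (sdlog 0.8), emulating the wide
#'   expression-level distribution of real transcriptomes. The PAX2 gene is
#'   pinned at the median so its detection rate is stable.
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2);
#'   the NB size parameter is 1/phi.
#' @param n_batches Number of batches; cells are assigned round-robin.
#' @param batch_effect_scale Multiplicative batch effect: per batch and gene
#'   the mean is scaled by exp(N(0, log(batch_effect_scale))). 1 = none.
#' @param offtarget_leaves Names of off-target identities (e.g.
#'   `c("muscle-like", "immune-like")`).
#' @param n_offtarget_cells Total off-target cells, split evenly.
#' @param npc_like_fraction Fraction of NPC cells simulated with the
#'   PAX2-linked sub-program silenced.
#' @param npc_subprogram_size Genes in the PAX2-linked sub-program
#'   (PAX2 itself plus linked markers, all inside the NPC program).
#' @param pax2_gene Identifier given to the PAX2 gene.
#' @param seed Mandatory seed; the simulation is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree = kidney_tree(), n_cells_per_leaf = 300,
                       n_genes = 2000, n_markers_per_leaf = 20,
                       n_markers_per_node = 20, marker_fold_change = 8,
                       baseline_mean = 0.5, nb_dispersion = 0.5,
                       n_batches = 1, batch_effect_scale = 1,
                       offtarget_leaves = character(0),
                       n_offtarget_cells = 300,
                       npc_like_fraction = 0, npc_subprogram_size = 10,
                       pax2_gene = "PAX2", seed) {
  if (missing(seed)) kc_abort("sim_config requires an explicit seed", "parameter_error")
  stopifnot(n_cells_per_leaf > 0, n_genes > 0, marker_fold_change > 1,
            baseline_mean > 0, nb_dispersion > 0, n_batches >= 1,
            batch_effect_scale >= 1, npc_like_fraction >= 0,
            npc_like_fraction <= 1)
  cfg <- list(tree = tree, n_cells_per_leaf = n_cells_per_leaf,
              n_genes = n_genes, n_markers_per_leaf = n_markers_per_leaf,
              n_markers_per_node = n_markers_per_node,
              marker_fold_change = marker_fold_change,
              baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
              n_batches = n_batches, batch_effect_scale = batch_effect_scale,
              offtarget_leaves = offtarget_leaves,
              n_offtarget_cells = n_offtarget_cells,
              npc_like_fraction = npc_like_fraction,
              npc_subprogram_size = npc_subprogram_size,
              pax2_gene = pax2_gene, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Assign disjoint marker gene blocks: internal nodes first, then terminals,
# then off-target programs, from the front of the gene vector.
assign_programs <- function(cfg) {
  tree <- cfg$tree
  leaves <- tree_leaves(tree)
  internals <- setdiff(model_nodes(tree), tree$root)
  demand <- length(internals) * cfg$n_markers_per_node +
    length(leaves) * cfg$n_markers_per_leaf +
    length(cfg$offtarget_leaves) * cfg$n_markers_per_leaf
  if (demand > cfg$n_genes - 5)  # last 5 genes are reserved mito-tagged background
    kc_abort(sprintf("marker demand (%d genes) exceeds n_genes (%d)",
                     demand, cfg$n_genes), "parameter_error")
  programs <- list()
  nxt <- 1L
  take <- function(k) {
    i <- nxt:(nxt + k - 1L); nxt <<- nxt + k; i
  }
  for (nd in internals) programs[[nd]] <- take(cfg$n_markers_per_node)
  for (lf in leaves) programs[[lf]] <- take(cfg$n_markers_per_leaf)
  for (ot in cfg$offtarget_leaves) programs[[ot]] <- take(cfg$n_markers_per_leaf)
  programs
}

#' Simulate hierarchically structured single-cell counts
#'
#' Generates a labeled [kc_dataset()] under a [sim_config()]. Per-cell
#' ground truth is recorded in `cell_meta`: `label` (terminal identity or
#' off-target name), `batch`, `is_offtarget` and `is_npc_like`. The PAX2
#' gene is the first gene of the NPC program; NPC-like cells carry the NPC
#' program minus its PAX2-linked sub-program (those genes revert to the
#' baseline mean) and PAX2 itself is silenced.
#'
#' @param cfg A [sim_config()].
#' @return A [kc_dataset()] with ground-truth metadata.
#' @export
simulate_kidney <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- cfg$tree
  leaves <- tree_leaves(tree)
  programs <- assign_programs(cfg)
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  # a handful of mitochondrial-tagged background genes so QC has a target
  gene_ids[(cfg$n_genes - 4):cfg$n_genes] <-
    paste0("MT-G", seq_len(5))
  npc_prog <- programs[["NPC"]]
  pax2_idx <- npc_prog[1]
  gene_ids[pax2_idx] <- cfg$pax2_gene
  subprog <- npc_prog[seq_len(min(cfg$npc_subprogram_size, length(npc_prog)))]
  size <- 1 / cfg$nb_dispersion
  # per-gene baseline expression levels: lognormal around the configured
  # median, so markers spread across the expression range as in real data
  base_g <- stats::rlnorm(cfg$n_genes, meanlog = log(cfg$baseline_mean),
                          sdlog = 0.8)
  base_g[pax2_idx] <- cfg$baseline_mean
  batch_lfc <- matrix(0, nrow = cfg$n_batches, ncol = cfg$n_genes)
  if (cfg$n_batches > 1 && cfg$batch_effect_scale > 1)
    batch_lfc[] <- stats::rnorm(length(batch_lfc), 0,
                                log(cfg$batch_effect_scale))
  pop <- c(stats::setNames(rep(cfg$n_cells_per_leaf, length(leaves)), leaves))
  if (length(cfg$offtarget_leaves)) {
    per <- ceiling(cfg$n_offtarget_cells / length(cfg$offtarget_leaves))
    split_ot <- rep(per, length(cfg$offtarget_leaves))
    split_ot[length(split_ot)] <- cfg$n_offtarget_cells - per * (length(split_ot) - 1)
    pop <- c(pop, stats::setNames(split_ot, cfg$offtarget_leaves))
  }
  blocks <- list(); metas <- list()
  for (ident in names(pop)) {
    n <- pop[[ident]]
    in_tree <- ident %in% leaves
    prog <- if (in_tree) {
      unlist(programs[intersect(label_path(tree, ident), names(programs))],
             use.names = FALSE)
    } else programs[[ident]]
    mu0 <- base_g
    mu0[prog] <- mu0[prog] * cfg$marker_fold_change
    is_like <- rep(FALSE, n)
    if (in_tree && ident == "NPC" && cfg$npc_like_fraction > 0)
      is_like[seq_len(round(n * cfg$npc_like_fraction))] <- TRUE
    # NPC-like cells carry the NPC program minus the PAX2-linked sub-program:
    # sub-program genes revert to baseline and PAX2 itself is silenced.
    mu_like <- mu0
    mu_like[subprog] <- base_g[subprog]
    mu_like[pax2_idx] <- 0
    batch <- rep_len(seq_len(cfg$n_batches), n)
    cnt <- matrix(0L, nrow = n, ncol = cfg$n_genes)
    for (b in unique(batch)) {
      for (lk in unique(is_like)) {
        i <- which(batch == b & is_like == lk)
        if (!length(i)) next
        mu <- (if (lk) mu_like else mu0) * exp(batch_lfc[b, ])
        cnt[i, ] <- matrix(stats::rnbinom(length(i) * cfg$n_genes,
                                          mu = rep(mu, each = length(i)),
                                          size = size),
                           nrow = length(i))
      }
    }
    blocks[[ident]] <- Matrix::Matrix(cnt, sparse = TRUE)
    metas[[ident]] <- data.frame(label = ident, batch = paste0("b", batch),
                                 is_offtarget = !in_tree, is_npc_like = is_like,
                                 stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, blocks)
  meta <- do.call(rbind, metas)
  cell_ids <- sprintf("cell%06d", seq_len(nrow(counts)))
  rownames(meta) <- cell_ids
  ds <- kc_dataset(counts, gene_ids = gene_ids, cell_ids = cell_ids,
                   cell_meta = meta)
  attr(ds, "programs") <- programs
  attr(ds, "sim_config") <- cfg
  ds
}

#' Stratified train/test split
#'
#' Splits cells into two disjoint datasets, sampling `fraction` of each
#' stratum (default: the `label` column) into the training half, so every
#' class is represented on both sides whenever it has at least two cells.
#'
#' @param ds A labeled [kc_dataset()].
#' @param fraction Training fraction.
#' @param seed Seed.
#' @param stratify_col Metadata column defining strata.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(ds, fraction = 0.5, seed = 1,
                             stratify_col = "label") {
  stopifnot(fraction > 0, fraction < 1)
  strata <- as.character(ds$cell_meta[[stratify_col]])
  set.seed(seed)
  # strata iterate in order of first appearance: locale-independent, so the
  # split is reproducible regardless of the session's collation settings
  groups <- split(seq_along(strata), factor(strata, levels = unique(strata)))
  train_idx <- unlist(lapply(groups, function(i) {
    k <- max(1, round(length(i) * fraction))
    if (length(i) > 1 && k == length(i)) k <- length(i) - 1
    sample(i, k)
  }), use.names = FALSE)
  train_idx <- sort(train_idx)
  list(train = subset_cells(ds, train_idx),
       test = subset_cells(ds, setdiff(seq_len(nrow(ds$counts)), train_idx)))
}
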