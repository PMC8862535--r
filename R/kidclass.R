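#' Fit a hierarchical cell-type classifier
#'
#' Trains one probabilistic multi-class model per internal node of an
#' identity tree, each in its own PCA feature space restricted to the node's
#' cells, using labels lifted from the terminal identities in `label_col`.
#' The returned model classifies new datasets top-down (see
#' [predict.kidclass()]): first-tier calls are subject to a rejection
#' threshold, deeper tiers are threshold-free, and nephron progenitor calls
#' can be refined into an NPC-like class by a PAX2 expression gate.
#'
#' @param ref A labeled reference [kc_dataset()] with raw counts.
#' @param label_col Metadata column holding terminal identity labels.
#' @param tree The [identity_tree()] (default: [kidney_tree()]).
#' @param batch_col Optional metadata column naming the batch of each cell;
#'   when given, every node applies one round of harmonization.
#' @param params Node training parameters, see [node_params()].
#' @param seed Base seed used when `params` is not supplied.
#' @param verbose Log per-node progress.
#' @return An object of class `kidclass`.
#' @examples
#' \donttest{
#' sim <- simulate_kidney(sim_config(n_cells_per_leaf = 60, n_genes = 600,
#'                                   seed = 1))
#' sp <- split_train_test(sim, 0.5, seed = 1)
#' fit <- kidclass(sp$train, seed = 1)
#' ann <- predict(fit, sp$test)
#' table(ann$tier1)
#' }
#' @export
kidclass <- function(ref, label_col = "label", tree = kidney_tree(),
                     batch_col = NULL, params = NULL, seed = 1,
                     verbose = FALSE) {
  v <- validate_tree(tree)
  if (length(v)) kc_abort(paste("invalid tree:", v[1]), "tree_error")
  if (!label_col %in% colnames(ref$cell_meta))
    kc_abort(sprintf("no '%s' column in cell_meta", label_col), "label_error")
  params <- params %||% node_params(seed = seed)
  labels <- as.character(ref$cell_meta[[label_col]])
  bad <- setdiff(unique(labels), tree$preorder)
  if (length(bad))
    kc_abort(sprintf("labels not in the identity tree: %s",
                     paste(bad, collapse = ", ")), "label_error")
  ref <- normalize_if_needed(ref)
  batch <- if (!is.null(batch_col)) as.character(ref$cell_meta[[batch_col]])
  # per-cell ancestry paths, used to route cells to node training sets
  paths <- lapply(unique(labels), function(l) label_path(tree, l))
  names(paths) <- unique(labels)
  nodes <- list()
  for (node in model_nodes(tree)) {
    kids <- tree$children[[node]]
    # label at this node = the child identity on each cell's path
    lab_at <- vapply(labels, function(l) {
      p <- paths[[l]]
      hit <- p[p %in% kids]
      if (length(hit)) hit[1] else NA_character_
    }, character(1), USE.NAMES = FALSE)
    idx <- which(!is.na(lab_at))
    present <- kids[kids %in% lab_at[idx]]
    if (length(present) < 2) {
      if (verbose) message(sprintf("skipping node '%s' (%d class(es) present)",
                                   node, length(present)))
      next
    }
    if (verbose) message(sprintf("training node '%s' on %d cells (%s)",
                                 node, length(idx), paste(present, collapse = ", ")))
    nodes[[node]] <- train_node(subset_cells(ref, idx), lab_at[idx],
                                classes = present, params = params,
                                batch = if (!is.null(batch)) batch[idx],
                                node_name = node, verbose = verbose)
  }
  if (!length(nodes)) kc_abort("no trainable node had >= 2 classes", "label_error")
  structure(list(tree = tree, nodes = nodes, params = params,
                 label_col = label_col, batch_col = batch_col,
                 version = "1.0"),
            class = "kidclass")
}

normalize_if_needed <- function(ds) {
  if (is.null(ds$layers$lognorm)) normalize_log1p(ds) else ds
}

#' Threshold a probability matrix into labels with rejection
#'
#' Assigns each cell the class of its highest score when that score reaches
#' the threshold, and `"unassigned"` otherwise. The boundary is inclusive: a
#' maximum exactly equal to the threshold is assigned. Ties at the maximum go
#' to the first class in column (tree-declared) order.
#'
#' @param probs Cells x classes probability matrix.
#' @param threshold Rejection threshold in \[0, 1\]; the package default for
#'   first-tier classification is 0.7.
#' @return Character vector of labels.
#' @export
apply_threshold <- function(probs, threshold = 0.7) {
  probs <- as.matrix(probs)
  j <- max.col(probs, ties.method = "first")
  mx <- probs[cbind(seq_len(nrow(probs)), j)]
  ifelse(mx >= threshold, colnames(probs)[j], "unassigned")
}

#' Classify a dataset with a trained hierarchy
#'
#' Runs the tiered classification: raw counts are log-normalized internally
#' (no user preprocessing required), first-tier probabilities are computed
#' for every cell and thresholded with rejection, and assigned cells are
#' routed to their lineage's child models, where assignment is by pure
#' argmax (no rejection below tier 1). Every evaluated probability is
#' recorded as a `p_<node>_<class>` column; cells a node never evaluated
#' hold `NA` there. Unassigned cells are not evaluated below tier 1.
#'
#' @param object A `kidclass` model.
#' @param newdata A [kc_dataset()] with raw counts.
#' @param threshold First-tier rejection threshold (default 0.7).
#' @param refine_npc Apply the PAX2 gate to NPC calls (see [refine_npc()]).
#' @param npc_resolution,pax2_fraction_cutoff,pax2_gene Refinement
#'   parameters, passed to [refine_npc()].
#' @param batch_col Optional query-metadata batch column; used to correct
#'   query scores per batch at harmonized nodes.
#' @param seed Seed for the refinement clustering.
#' @param ... Unused.
#' @return A data.frame (one row per cell): `tier1`, `tier2`, `tier3`,
#'   `final_label` and the probability columns. `final_label` is the deepest
#'   assigned identity, or `"NPC-like"`/`"unassigned"`.
#' @export
predict.kidclass <- function(object, newdata, threshold = 0.7,
                             refine_npc = TRUE, npc_resolution = 0.5,
                             pax2_fraction_cutoff = 0.30, pax2_gene = "PAX2",
                             batch_col = NULL, seed = 1, ...) {
  ds <- normalize_if_needed(newdata)
  n <- nrow(ds$counts)
  batch <- if (!is.null(batch_col)) as.character(ds$cell_meta[[batch_col]])
  tree <- object$tree
  ann <- data.frame(tier1 = character(n), tier2 = character(n),
                    tier3 = character(n), row.names = ds$cell_ids,
                    stringsAsFactors = FALSE)
  probs_rec <- list()
  root <- tree$root
  if (is.null(object$nodes[[root]]))
    kc_abort("first-tier node model is missing from this model", "state_error")
  evaluate <- function(node, idx, tier) {
    nm <- object$nodes[[node]]
    p <- predict_node(nm, subset_cells(ds, idx),
                      batch = if (!is.null(batch)) batch[idx])
    for (cls in colnames(p)) {
      col <- paste0("p_", node, "_", cls)
      if (is.null(probs_rec[[col]])) probs_rec[[col]] <<- rep(NA_real_, n)
      probs_rec[[col]][idx] <<- p[, cls]
    }
    p
  }
  p1 <- evaluate(root, seq_len(n), 1)
  ann$tier1 <- apply_threshold(p1, threshold)
  for (tier in 2:3) {
    parent_lab <- ann[[paste0("tier", tier - 1)]]
    for (node in intersect(tree$preorder, unique(parent_lab))) {
      if (is.null(object$nodes[[node]])) next
      idx <- which(parent_lab == node)
      p <- evaluate(node, idx, tier)
      ann[[paste0("tier", tier)]][idx] <-
        colnames(p)[max.col(p, ties.method = "first")]
    }
  }
  ann$final_label <- ifelse(ann$tier3 != "", ann$tier3,
                     ifelse(ann$tier2 != "", ann$tier2, ann$tier1))
  ann <- cbind(ann, as.data.frame(probs_rec, row.names = ds$cell_ids))
  if (refine_npc)
    ann <- refine_npc(ann, ds, resolution = npc_resolution,
                      pax2_fraction_cutoff = pax2_fraction_cutoff,
                      pax2_gene = pax2_gene, seed = seed)
  class(ann) <- c("kidclass_annotation", "data.frame")
  ann
}

#' Classify a dataset and attach the annotation to its metadata
#'
#' Convenience wrapper around [predict.kidclass()] that returns the dataset
#' with the classification columns merged into `cell_meta`, ready for
#' [write_annotation_table()] and the comparison layer.
#'
#' @inheritParams predict.kidclass
#' @param model A `kidclass` model.
#' @param ds The query [kc_dataset()].
#' @param ... Passed to [predict.kidclass()].
#' @return The dataset with classification columns in `cell_meta`.
#' @export
classify <- function(ds, model, ...) {
  ann <- stats::predict(model, ds, ...)
  keep <- setdiff(colnames(ds$cell_meta), colnames(ann))
  ds$cell_meta <- cbind(ds$cell_meta[, keep, drop = FALSE],
                        as.data.frame(ann))
  ds
}

#' Refine nephron progenitor calls with a PAX2 expression gate
#'
#' Cells called NPC at tier 1 are subset, re-embedded (PCA on the NPC cells
#' only) and re-clustered by Louvain community detection on a k-nearest
#' neighbour graph at the given resolution. In every cluster the fraction of
#' cells with a raw PAX2 count above zero is computed; clusters in which
#' strictly fewer than `pax2_fraction_cutoff` (default 30%) of cells express
#' PAX2 are relabelled `"NPC-like"` in `final_label`. The tier-1 label is
#' left as NPC for auditability. The operation only ever converts NPC to
#' NPC-like, never the reverse, and is idempotent: both NPC and NPC-like
#' cells enter the reclustering, so repeated application reproduces the same
#' partition and the same calls.
#'
#' @param ann A `kidclass_annotation` data.frame (or a classified dataset's
#'   metadata).
#' @param ds The dataset the annotation belongs to (counts + lognorm used).
#' @param resolution Louvain resolution (default 0.5).
#' @param pax2_fraction_cutoff Strict lower bound on the expressing fraction.
#' @param pax2_gene Gene identifier of PAX2 in the dataset.
#' @param k Neighbours in the kNN graph (capped at n-1).
#' @param n_hvg,n_pcs Variable genes and principal components used for the
#'   subset re-embedding. Genes are ranked by plain variance of the
#'   log-normalized values (not the mean-binned dispersion used for node
#'   training): an on/off marker switch within an otherwise homogeneous
#'   population is a high-variance bimodal gene, and restricting the
#'   embedding to few such genes and components lets it dominate.
#' @param seed Clustering seed.
#' @return The annotation with refined `final_label`.
#' @export
refine_npc <- function(ann, ds, resolution = 0.5, pax2_fraction_cutoff = 0.30,
                       pax2_gene = "PAX2", k = 15, n_hvg = 200, n_pcs = 10,
                       seed = 1) {
  idx <- which(ann$tier1 == "NPC" & ann$final_label %in% c("NPC", "NPC-like"))
  if (!length(idx)) return(ann)
  gi <- match(pax2_gene, ds$gene_ids)
  if (is.na(gi)) {
    kc_warn(sprintf("gene '%s' not present; NPC refinement skipped", pax2_gene))
    return(ann)
  }
  nsub <- length(idx)
  if (nsub < 3) {
    cl <- rep(1L, nsub)
  } else {
    sub <- subset_cells(normalize_if_needed(ds), idx)
    # the gate gene is excluded from the embedding so the PAX2 fraction is
    # measured on clusters, not used to define them
    hv <- setdiff(top_variance_genes(sub, n_hvg + 1), pax2_gene)
    hv <- hv[seq_len(min(n_hvg, length(hv)))]
    npc <- min(n_pcs, nsub - 1, length(hv))
    space <- fit_feature_space(sub, genes = hv, n_pcs = npc, seed = seed)
    cl <- louvain_clusters(space$scores, k = min(k, nsub - 1),
                           resolution = resolution, seed = seed)
  }
  expressing <- as.numeric(ds$counts[idx, gi] > 0)
  for (g in unique(cl)) {
    i <- cl == g
    if (mean(expressing[i]) < pax2_fraction_cutoff)
      ann$final_label[idx[i]] <- "NPC-like"
  }
  ann
}

# Louvain communities on a Jaccard-weighted shared-nearest-neighbour graph,
# the standard graph construction for single-cell clustering. Edges between
# cells whose kNN sets (self included) share fewer than prune of their union
# are dropped.
louvain_clusters <- function(scores, k, resolution = 0.5, seed = 1,
                             prune = 0.2) {
  n <- nrow(scores)
  d <- as.matrix(stats::dist(scores))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  nn <- cbind(seq_len(n), nn)  # include self
  adj <- matrix(0L, n, n)
  adj[cbind(rep(seq_len(n), each = ncol(nn)), as.vector(t(nn)))] <- 1L
  shared <- adj %*% t(adj)
  kk <- ncol(nn)
  jac <- shared / (2 * kk - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
}

#' @export
#' @method print kidclass
print.kidclass <- function(x, ...) {
  cat(sprintf("<kidclass> hierarchical classifier (%s), %d node model(s)\n",
              x$params$model, length(x$nodes)))
  for (nm in names(x$nodes))
    cat(sprintf("  %s: %s\n", nm, paste(x$nodes[[nm]]$classes, collapse = ", ")))
  invisible(x)
}

#' Summarize a trained hierarchy
#'
#' Prints, per node and class, the held-out cross-validation AUROC,
#' sensitivity and specificity recorded at training time.
#' @param object A `kidclass` model.
#' @param ... Unused.
#' @export
#' @method summary kidclass
summary.kidclass <- function(object, ...) {
  rows <- list()
  for (nm in names(object$nodes)) {
    m <- object$nodes[[nm]]$cv_metrics
    if (is.null(m)) next
    rows[[nm]] <- data.frame(node = nm, class = rownames(m),
                             as.data.frame(m), row.names = NULL)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = character(0), class = character(0))
  class(out) <- c("summary.kidclass", "data.frame")
  out
}

#' @export
#' @method print summary.kidclass
print.summary.kidclass <- function(x, ...) {
  cat("Held-out cross-validation metrics per node model:\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}


# Genes ranked by plain variance of the lognorm layer (refinement embedding).
top_variance_genes <- function(ds, n) {
  ln <- lognorm_layer(ds)
  m <- Matrix::colMeans(ln)
  v <- (Matrix::colSums(ln^2) - nrow(ln) * m^2) / max(1, nrow(ln) - 1)
  ord <- order(-v, seq_along(v))
  ds$gene_ids[ord[seq_len(min(n, length(ord)))]]
}
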