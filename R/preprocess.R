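#' Quality-control filtering of cells
#'
#' Keeps cells expressing more than `min_genes` genes and with a
#' mitochondrial fraction below `max_mito`. The mitochondrial fraction of a
#' cell is the share of its total counts falling on genes whose identifier
#' matches `mito_prefix` (a regular expression; human symbols use `"^MT-"`).
#' Defaults mirror the quality thresholds typically applied to developing
#' kidney 10x data: > 1500 detected genes and < 30% mitochondrial counts.
#'
#' @param ds A [kc_dataset()] with raw counts.
#' @param min_genes Minimum detected-gene count (exclusive).
#' @param max_mito Maximum mitochondrial fraction (exclusive).
#' @param mito_prefix Regular expression matching mitochondrial gene ids.
#' @param verbose Print kept/removed counts.
#' @return Filtered [kc_dataset()].
#' @export
qc_filter <- function(ds, min_genes = 1500, max_mito = 0.30,
                      mito_prefix = "^MT-", verbose = TRUE) {
  detected <- Matrix::rowSums(ds$counts > 0)
  totals <- Matrix::rowSums(ds$counts)
  mito_idx <- grepl(mito_prefix, ds$gene_ids)
  if (!any(mito_idx)) {
    kc_warn(sprintf("no genes match mito_prefix '%s'; mitochondrial fraction treated as 0",
                    mito_prefix))
    mito_frac <- rep(0, nrow(ds$counts))
  } else {
    mito_frac <- Matrix::rowSums(ds$counts[, mito_idx, drop = FALSE]) /
      pmax(totals, 1)
  }
  keep <- detected > min_genes & mito_frac < max_mito
  if (!any(keep))
    kc_abort("QC filtering removed every cell", "empty_dataset_error")
  if (verbose)
    message(sprintf("qc_filter: kept %d / %d cells (removed %d)",
                    sum(keep), length(keep), sum(!keep)))
  subset_cells(ds, which(keep))
}

#' Log-normalize raw counts
#'
#' Each cell's counts are divided by the cell's total, multiplied by
#' `scale_factor` (default 10,000) and natural-log transformed with a
#' pseudocount of 1:
#' \deqn{x_{cg} = \ln(1 + 10^4 \, n_{cg} / \textstyle\sum_g n_{cg})}
#' The result is stored as the `"lognorm"` layer; raw counts are untouched.
#'
#' @param ds A [kc_dataset()].
#' @param scale_factor Library-size scale factor.
#' @return The dataset with a `"lognorm"` layer.
#' @export
normalize_log1p <- function(ds, scale_factor = 1e4) {
  totals <- Matrix::rowSums(ds$counts)
  if (any(totals == 0))
    kc_abort("cells with zero total counts present; run qc_filter() first",
             "zero_total_error")
  ln <- Matrix::Diagonal(x = scale_factor / totals) %*% ds$counts
  ln <- methods::as(ln, "CsparseMatrix")
  ln@x <- log1p(ln@x)
  dimnames(ln) <- dimnames(ds$counts)
  ds$layers$lognorm <- ln
  ds
}

lognorm_layer <- function(ds) {
  if (is.null(ds$layers$lognorm)) ds <- normalize_log1p(ds)
  ds$layers$lognorm
}

#' Select highly variable genes
#'
#' Ranks genes by mean-binned normalized dispersion of the log-normalized
#' layer: per-gene dispersion (variance / mean) is z-scored within 20
#' equal-frequency bins of the gene mean, and the top `n_hvg` genes are
#' returned. Constant genes rank last. Deterministic given the data.
#'
#' @param ds A [kc_dataset()] with a lognorm layer (computed if absent).
#' @param n_hvg Number of genes to keep (capped at the gene count).
#' @param n_bins Number of mean bins.
#' @return Character vector of gene ids, most variable first.
#' @export
select_hvg <- function(ds, n_hvg = 10000, n_bins = 20) {
  ln <- lognorm_layer(ds)
  n <- nrow(ln)
  mu <- Matrix::colMeans(ln)
  v <- (Matrix::colSums(ln^2) - n * mu^2) / max(1, n - 1)
  v[v < 0] <- 0
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = min(n_bins, length(mu)), labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  z[v == 0] <- -Inf  # constant genes can never outrank variable ones
  ord <- order(-z, seq_along(z))
  ds$gene_ids[ord[seq_len(min(n_hvg, length(ord)))]]
}

# ---- PCA feature space -----------------------------------------------------

#' Fit a PCA feature space (with optional one-round harmonization)
#'
#' Centers the selected genes of the lognorm layer and computes the top
#' `n_pcs` principal components by exact eigendecomposition. When
#' `batch` is given, a single round of batch harmonization is applied to the
#' training scores (see [harmonize_once()]) and the correction state is
#' retained so queries can be corrected against the reference.
#'
#' @param ds A [kc_dataset()] with a lognorm layer.
#' @param genes Genes spanning the space (default: all).
#' @param n_pcs Number of components.
#' @param batch Optional per-cell batch factor for harmonization.
#' @param seed Seed for the harmonization clustering.
#' @return A `feature_space` list: `gene_list`, `means`, `loadings`
#'   (genes x n_pcs, orthonormal), `scores` (training cells x n_pcs),
#'   `sdev`, and `harmony` state (or NULL).
#' @export
fit_feature_space <- function(ds, genes = ds$gene_ids, n_pcs = 100,
                              batch = NULL, seed = 1) {
  ln <- lognorm_layer(ds)
  X <- as.matrix(ln[, match(genes, ds$gene_ids), drop = FALSE])
  n <- nrow(X); p <- ncol(X)
  kmax <- min(n - 1, p)
  if (n_pcs > kmax)
    kc_abort(sprintf("n_pcs = %d exceeds min(n_cells - 1, n_genes) = %d",
                     n_pcs, kmax), "parameter_error")
  means <- colMeans(X)
  Xc <- sweep(X, 2, means)
  if (p <= n) {
    eg <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
    loadings <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
    ev <- eg$values[seq_len(n_pcs)]
  } else {
    eg <- eigen(tcrossprod(Xc) / (n - 1), symmetric = TRUE)
    ev <- eg$values[seq_len(n_pcs)]
    u <- eg$vectors[, seq_len(n_pcs), drop = FALSE]
    loadings <- crossprod(Xc, u) / rep(sqrt(pmax(ev, 1e-12) * (n - 1)), each = p)
  }
  # deterministic sign: largest-magnitude loading of each PC is positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- genes
  scores <- Xc %*% loadings
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  harmony <- NULL
  if (!is.null(batch) && length(unique(batch)) > 1) {
    h <- harmonize_once(scores, batch, seed = seed)
    scores <- h$scores
    harmony <- h$state
  }
  structure(list(gene_list = genes, means = means, loadings = loadings,
                 scores = scores, sdev = sqrt(pmax(ev, 0)), harmony = harmony,
                 seed = seed),
            class = "feature_space")
}

#' One round of batch harmonization in PC space
#'
#' A single clustering-plus-correction cycle: cells are clustered by k-means
#' on batch-centered PC scores (each batch's global centroid translated onto
#' the pooled centroid, so a strong global batch displacement cannot isolate
#' a batch into its own clusters), and within every cluster each batch's
#' centroid is then translated onto the cluster centroid. This removes the
#' batch displacement locally while leaving biological separation between
#' clusters intact. The returned state (corrected cluster centroids and the
#' global centroid) lets a query be corrected against the reference
#' afterwards.
#'
#' @param scores Cells x PCs score matrix.
#' @param batch Per-cell batch factor.
#' @param k Number of clusters (default `min(20, n/30)`, at least 2).
#' @param seed Seed for k-means.
#' @return List with corrected `scores` and `state` (`centroids`, `global`).
#' @export
harmonize_once <- function(scores, batch, k = NULL, seed = 1) {
  batch <- as.character(batch)
  if (length(unique(batch)) < 2)
    return(list(scores = scores, state = NULL))
  n <- nrow(scores)
  k <- k %||% max(2, min(20, floor(n / 30)))
  # cluster on batch-centered scores so a strong global batch displacement
  # cannot isolate one batch into its own clusters (which would leave the
  # correction with nothing to align)
  global <- colMeans(scores)
  centered <- scores
  for (b in unique(batch)) {
    i <- batch == b
    centered[i, ] <- sweep(scores[i, , drop = FALSE], 2,
                           colMeans(scores[i, , drop = FALSE]) - global)
  }
  set.seed(seed)
  km <- stats::kmeans(centered, centers = k, nstart = 5, iter.max = 50)
  corrected <- scores
  for (cl in seq_len(k)) {
    i <- which(km$cluster == cl)
    if (!length(i)) next
    cc <- colMeans(scores[i, , drop = FALSE])
    for (b in unique(batch[i])) {
      ib <- i[batch[i] == b]
      shift <- cc - colMeans(scores[ib, , drop = FALSE])
      corrected[ib, ] <- sweep(scores[ib, , drop = FALSE], 2, shift, `+`)
    }
  }
  centroids <- t(vapply(seq_len(k), function(cl) {
    colMeans(corrected[km$cluster == cl, , drop = FALSE])
  }, numeric(ncol(scores))))
  list(scores = corrected,
       state = list(centroids = centroids, global = colMeans(corrected)))
}

# Correct query scores against stored reference cluster centroids: each query
# cell joins its nearest reference cluster; per (cluster, query batch) the
# query centroid is translated onto the reference cluster centroid.
correct_query_scores <- function(scores, state, batch = NULL) {
  if (is.null(state)) return(scores)
  cen <- state$centroids
  batch <- if (is.null(batch)) rep("query", nrow(scores)) else as.character(batch)
  # remove each query batch's global displacement before cluster assignment,
  # mirroring the batch-centered clustering used at training time
  assign_on <- scores
  for (b in unique(batch)) {
    i <- batch == b
    assign_on[i, ] <- sweep(scores[i, , drop = FALSE], 2,
                            colMeans(scores[i, , drop = FALSE]) - state$global)
  }
  d2 <- outer(rowSums(assign_on^2), rep(1, nrow(cen))) -
    2 * assign_on %*% t(cen) + outer(rep(1, nrow(assign_on)), rowSums(cen^2))
  cl <- max.col(-d2, ties.method = "first")
  out <- scores
  for (g in unique(cl)) {
    i <- which(cl == g)
    for (b in unique(batch[i])) {
      ib <- i[batch[i] == b]
      shift <- cen[g, ] - colMeans(scores[ib, , drop = FALSE])
      out[ib, ] <- sweep(scores[ib, , drop = FALSE], 2, shift, `+`)
    }
  }
  out
}

#' Project a query dataset into a trained feature space
#'
#' Genes absent from the query are imputed at the reference mean (hence
#' contribute zero after centering). Requires at least 50% of the space's
#' genes to be present; below 80% a warning is raised. When the space holds
#' harmonization state, query scores are corrected against the reference
#' (one round), optionally per query batch.
#'
#' @param ds Query [kc_dataset()] (lognorm computed if absent).
#' @param space A `feature_space` from [fit_feature_space()].
#' @param batch Optional per-cell query batch factor.
#' @param min_overlap,warn_overlap Overlap thresholds.
#' @return Cells x n_pcs score matrix.
#' @export
project_query <- function(ds, space, batch = NULL,
                          min_overlap = 0.5, warn_overlap = 0.8) {
  present <- space$gene_list %in% ds$gene_ids
  frac <- mean(present)
  if (frac < min_overlap)
    kc_abort(sprintf("query shares only %.0f%% of the model's genes", 100 * frac),
             "gene_overlap_error")
  if (frac < warn_overlap)
    kc_warn(sprintf("query shares %.0f%% of the model's genes; scores may degrade",
                    100 * frac))
  ln <- lognorm_layer(ds)
  idx <- match(space$gene_list[present], ds$gene_ids)
  X <- as.matrix(ln[, idx, drop = FALSE])
  Xc <- sweep(X, 2, space$means[present])
  scores <- Xc %*% space$loadings[present, , drop = FALSE]
  colnames(scores) <- colnames(space$scores)
  rownames(scores) <- ds$cell_ids
  correct_query_scores(scores, space$harmony, batch = batch)
}
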