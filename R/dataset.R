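#' Construct a gene-expression dataset
#'
#' The canonical in-memory container for single-cell count data: a sparse
#' cells-by-genes matrix of raw UMI counts, unique cell and gene identifiers,
#' a per-cell metadata table and optional derived layers (e.g. the
#' log-normalized layer added by [normalize_log1p()]).
#'
#' Counts are stored cells x genes internally; 10x-style on-disk matrices are
#' genes x cells and are transposed on read by [read_mtx_triplet()].
#'
#' @param counts Non-negative integer matrix or sparse Matrix, cells x genes.
#' @param gene_ids Character vector of unique gene identifiers (columns).
#' @param cell_ids Character vector of unique cell identifiers (rows).
#' @param cell_meta Optional data.frame of per-cell annotations; rownames (or
#'   a `cell_id` column) must match `cell_ids`.
#' @param layers Optional named list of numeric matrices with the same shape
#'   as `counts`.
#' @return An object of class `kc_dataset`.
#' @export
kc_dataset <- function(counts, gene_ids = colnames(counts),
                       cell_ids = rownames(counts),
                       cell_meta = NULL, layers = list()) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  gene_ids <- trimws(as.character(gene_ids))
  cell_ids <- trimws(as.character(cell_ids))
  if (length(gene_ids) != ncol(counts))
    kc_abort("length(gene_ids) must equal ncol(counts)", "format_error")
  if (length(cell_ids) != nrow(counts))
    kc_abort("length(cell_ids) must equal nrow(counts)", "format_error")
  if (anyDuplicated(gene_ids))
    kc_abort(sprintf("duplicated gene ids (e.g. '%s')", gene_ids[duplicated(gene_ids)][1]),
             "format_error")
  if (anyDuplicated(cell_ids))
    kc_abort(sprintf("duplicated cell ids (e.g. '%s')", cell_ids[duplicated(cell_ids)][1]),
             "format_error")
  x <- counts@x
  if (length(x) && (min(x) < 0 || any(x != round(x))))
    kc_abort("counts must be non-negative integers", "format_error")
  dimnames(counts) <- list(cell_ids, gene_ids)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = cell_ids)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if ("cell_id" %in% colnames(cell_meta) && is.null(rownames(cell_meta)))
      rownames(cell_meta) <- cell_meta$cell_id
    if (!all(rownames(cell_meta) %in% cell_ids))
      kc_abort("cell_meta contains rows with no matching cell_id", "format_error")
    cell_meta <- cell_meta[cell_ids, , drop = FALSE]
    rownames(cell_meta) <- cell_ids
  }
  for (nm in names(layers)) {
    if (!all(dim(layers[[nm]]) == dim(counts)))
      kc_abort(sprintf("layer '%s' has wrong shape", nm), "format_error")
  }
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta, layers = layers),
            class = "kc_dataset")
}

#' @export
dim.kc_dataset <- function(x) dim(x$counts)

#' @export
#' @method print kc_dataset
print.kc_dataset <- function(x, ...) {
  cat(sprintf("<kc_dataset> %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  if (length(x$layers)) cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (ncol(x$cell_meta)) cat("  cell_meta:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

# Subset cells by index/logical/id, keeping layers and metadata aligned.
subset_cells <- function(ds, idx) {
  if (is.character(idx)) idx <- match(idx, ds$cell_ids)
  layers <- lapply(ds$layers, function(l) l[idx, , drop = FALSE])
  kc_dataset(ds$counts[idx, , drop = FALSE], gene_ids = ds$gene_ids,
             cell_ids = ds$cell_ids[idx],
             cell_meta = ds$cell_meta[idx, , drop = FALSE], layers = layers)
}

# Subset/reorder genes by id.
subset_genes <- function(ds, genes) {
  idx <- match(genes, ds$gene_ids)
  if (anyNA(idx)) kc_abort("unknown gene ids in subset", "format_error")
  layers <- lapply(ds$layers, function(l) l[, idx, drop = FALSE])
  kc_dataset(ds$counts[, idx, drop = FALSE], gene_ids = ds$gene_ids[idx],
             cell_ids = ds$cell_ids, cell_meta = ds$cell_meta, layers = layers)
}

#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`
#' in `dir_path`, with the matrix in the 10x genes-x-cells orientation. The
#' result is transposed to the package's canonical cells-x-genes orientation.
#' Gene identifiers are taken from the first column of the features file; a
#' second column (symbols), when present, is kept in the `gene_symbols`
#' attribute.
#'
#' @param dir_path Directory containing the triplet.
#' @return A [kc_dataset()].
#' @export
read_mtx_triplet <- function(dir_path) {
  pick <- function(cands) {
    for (f in cands) {
      p <- file.path(dir_path, f)
      if (file.exists(p)) return(p)
    }
    kc_abort(sprintf("missing file (looked for %s) in %s",
                     paste(cands, collapse = "/"), dir_path), "io_error")
  }
  mtx <- pick(c("matrix.mtx", "matrix.mtx.gz"))
  feat <- pick(c("features.tsv", "genes.tsv", "features.tsv.gz", "genes.tsv.gz"))
  bc <- pick(c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- Matrix::readMM(mtx)  # genes x cells
  features <- utils::read.table(feat, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE, quote = "")
  barcodes <- utils::read.table(bc, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE, quote = "")[[1]]
  if (nrow(features) != nrow(m))
    kc_abort(sprintf("features rows (%d) != matrix rows (%d)", nrow(features), nrow(m)),
             "format_error")
  if (length(barcodes) != ncol(m))
    kc_abort(sprintf("barcodes rows (%d) != matrix cols (%d)", length(barcodes), ncol(m)),
             "format_error")
  ds <- kc_dataset(Matrix::t(m), gene_ids = features[[1]], cell_ids = barcodes)
  if (ncol(features) >= 2)
    attr(ds, "gene_symbols") <- stats::setNames(trimws(features[[2]]), ds$gene_ids)
  ds
}

#' Write a dataset as a 10x-style MatrixMarket triplet
#'
#' Inverse of [read_mtx_triplet()]: writes `matrix.mtx` (genes x cells),
#' `features.tsv` and `barcodes.tsv` into `dir_path`. When the dataset has
#' per-cell metadata it is written alongside as `cell_meta.tsv`.
#'
#' @param ds A [kc_dataset()].
#' @param dir_path Output directory (created if needed).
#' @export
write_mtx_triplet <- function(ds, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(ds$counts), file.path(dir_path, "matrix.mtx"))
  utils::write.table(data.frame(id = ds$gene_ids),
                     file.path(dir_path, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(ds$cell_ids, file.path(dir_path, "barcodes.tsv"))
  if (ncol(ds$cell_meta)) {
    meta <- cbind(cell_id = ds$cell_ids, ds$cell_meta)
    utils::write.table(meta, file.path(dir_path, "cell_meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir_path)
}

annotation_cols <- function(meta) {
  fixed <- c("tier1", "tier2", "tier3", "final_label")
  probs <- grep("^p_", colnames(meta), value = TRUE)
  c(fixed, probs)
}

#' Write the per-cell annotation table
#'
#' One row per cell: cell id, the three tier labels, the final identity and
#' every recorded probability column (named `p_<node>_<class>`, in tree
#' preorder). Unassigned cells have empty tier-2/3 fields.
#'
#' @param ds A classified [kc_dataset()] (see [classify()]).
#' @param path Output TSV path.
#' @export
write_annotation_table <- function(ds, path) {
  meta <- ds$cell_meta
  need <- c("tier1", "tier2", "tier3", "final_label")
  if (!all(need %in% colnames(meta)))
    kc_abort("dataset has no classification columns; run classify() first",
             "state_error")
  out <- cbind(cell_id = ds$cell_ids, meta[, annotation_cols(meta), drop = FALSE])
  for (j in seq_along(out)) if (is.numeric(out[[j]]))
    out[[j]] <- formatC(out[[j]], format = "g", digits = 10)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an annotation table written by [write_annotation_table()]
#' @param path TSV path.
#' @return data.frame with one row per cell.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) kc_abort(paste("no such file:", path), "io_error")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = NA, na.strings = "NA")
  for (col in c("tier1", "tier2", "tier3", "final_label"))
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  df
}
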