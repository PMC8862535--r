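# Cross-sample comparison layer: composition tables, dot-plot statistics,
# identity means and the exportable gene-summary database.

# Resolve the label each cell carries at a given tier. Cells terminating
# above the tier keep their deepest label (so NPC, Endo and unassigned appear
# alongside tier-2 segments, as in stacked composition charts); NPC-like
# replaces NPC wherever it was called.
label_at_tier <- function(ann, tier = c("tier1", "tier2", "tier3", "final")) {
  tier <- match.arg(tier)
  if (tier == "final") return(ann$final_label)
  lab <- ann$tier1
  depth <- match(tier, c("tier1", "tier2", "tier3"))
  if (depth >= 2) lab <- ifelse(ann$tier2 != "", ann$tier2, lab)
  if (depth >= 3) lab <- ifelse(ann$tier3 != "", ann$tier3, lab)
  ifelse(ann$final_label == "NPC-like" & lab == "NPC", "NPC-like", lab)
}

as_annotation_list <- function(x) {
  grab <- function(d) {
    if (inherits(d, "kc_dataset")) d$cell_meta else as.data.frame(d)
  }
  if (inherits(x, c("kc_dataset", "data.frame"))) x <- list(sample1 = x)
  if (is.null(names(x))) names(x) <- paste0("sample", seq_along(x))
  lapply(x, grab)
}

#' Per-sample identity composition
#'
#' Counts and percentages of cells per identity at a chosen tier, per
#' sample. Percentages sum to 100 within each sample.
#'
#' @param x A classified dataset/annotation, or a named list of them (one
#'   per sample).
#' @param tier `"tier1"`, `"tier2"`, `"tier3"` or `"final"`. At tiers 2-3,
#'   identities terminating higher keep their deepest label.
#' @return data.frame: sample, identity, n_cells, pct_of_sample.
#' @export
composition <- function(x, tier = "tier1") {
  anns <- as_annotation_list(x)
  out <- lapply(names(anns), function(s) {
    lab <- label_at_tier(anns[[s]], tier)
    tab <- table(lab)
    data.frame(sample = s, identity = names(tab),
               n_cells = as.integer(tab),
               pct_of_sample = 100 * as.integer(tab) / length(lab),
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Dot-plot summary statistics
#'
#' For every (sample, identity, gene) group: the percentage of cells with a
#' raw count above zero and the mean log-normalized expression over all
#' cells of the group (zeros included). Genes absent from a sample are
#' emitted with zero values and `missing_gene = TRUE`. A stored reference
#' profile (a previously exported table) can be passed to be emitted
#' alongside, tagged as sample `"reference"`.
#'
#' @param x A classified [kc_dataset()] or named list of them.
#' @param genes Gene identifiers to summarize.
#' @param identities Optional subset of identities to keep.
#' @param tier Tier at which cells are grouped (default `"final"`).
#' @param reference_profile Optional data.frame in the same format.
#' @return A gene-summary data.frame: sample, tier, identity, gene,
#'   pct_expressing, mean_lognorm, n_cells, missing_gene.
#' @export
dotplot_stats <- function(x, genes, identities = NULL, tier = "final",
                          reference_profile = NULL) {
  if (inherits(x, "kc_dataset")) x <- list(sample1 = x)
  if (is.null(names(x))) names(x) <- paste0("sample", seq_along(x))
  rows <- list()
  for (s in names(x)) {
    ds <- normalize_if_needed(x[[s]])
    ann <- ds$cell_meta
    lab <- label_at_tier(ann, tier)
    idents <- identities %||% sort(unique(lab))
    for (ident in idents) {
      i <- which(lab == ident)
      if (!length(i)) next
      for (g in genes) {
        gi <- match(g, ds$gene_ids)
        if (is.na(gi)) {
          rows[[length(rows) + 1]] <- data.frame(
            sample = s, tier = tier, identity = ident, gene = g,
            pct_expressing = 0, mean_lognorm = 0, n_cells = length(i),
            missing_gene = TRUE)
        } else {
          cnt <- ds$counts[i, gi]
          rows[[length(rows) + 1]] <- data.frame(
            sample = s, tier = tier, identity = ident, gene = g,
            pct_expressing = 100 * mean(cnt > 0),
            mean_lognorm = mean(ds$layers$lognorm[i, gi]),
            n_cells = length(i), missing_gene = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(reference_profile)) {
    ref <- reference_profile
    ref$sample <- "reference"
    if (is.null(ref$missing_gene)) ref$missing_gene <- FALSE
    keep <- ref$gene %in% genes
    if (!is.null(identities)) keep <- keep & ref$identity %in% identities
    if (is.null(ref$tier)) ref$tier <- tier
    out <- rbind(out, ref[keep, colnames(out), drop = FALSE])
  }
  out
}

#' Mean identity contribution across samples
#'
#' Summarizes a composition across samples: per identity, the mean
#' percentage, standard deviation and standard error of the mean
#' (SD / sqrt(n_samples)). With a single sample SD and SEM are `NA`.
#' Identities absent from a sample contribute 0% for that sample.
#'
#' @param x As in [composition()].
#' @param tier Tier of the composition.
#' @return data.frame: identity, mean_pct, sd_pct, sem_pct, n_samples.
#' @export
ident_means <- function(x, tier = "tier1") {
  comp <- composition(x, tier)
  samples <- unique(comp$sample)
  idents <- unique(comp$identity)
  full <- expand.grid(sample = samples, identity = idents,
                      stringsAsFactors = FALSE)
  full <- merge(full, comp[, c("sample", "identity", "pct_of_sample")],
                all.x = TRUE)
  full$pct_of_sample[is.na(full$pct_of_sample)] <- 0
  out <- do.call(rbind, lapply(split(full, full$identity), function(d) {
    n <- nrow(d)
    data.frame(identity = d$identity[1], mean_pct = mean(d$pct_of_sample),
               sd_pct = if (n > 1) stats::sd(d$pct_of_sample) else NA_real_,
               sem_pct = if (n > 1) stats::sd(d$pct_of_sample) / sqrt(n) else NA_real_,
               n_samples = n)
  }))
  rownames(out) <- NULL
  out[order(out$identity), ]
}

#' Export the gene-expression summary database
#'
#' Builds the [dotplot_stats()] table at every classification tier for every
#' sample and writes it as a single TSV with the fixed header
#' `sample, tier, identity, gene, pct_expressing, mean_lognorm, n_cells`.
#' The file can be re-imported with [import_database()] and fed back into
#' [dotplot_stats()] as a reference profile.
#'
#' @param x Named list of classified [kc_dataset()] objects.
#' @param genes Genes to summarize (default: all genes of the first sample).
#' @param path Output TSV path.
#' @param tiers Tiers to include.
#' @return The combined data.frame, invisibly.
#' @export
export_database <- function(x, genes = NULL, path,
                            tiers = c("tier1", "tier2", "tier3")) {
  if (inherits(x, "kc_dataset")) x <- list(sample1 = x)
  genes <- genes %||% x[[1]]$gene_ids
  db <- do.call(rbind, lapply(tiers, function(tier)
    dotplot_stats(x, genes = genes, tier = tier)))
  db <- db[, c("sample", "tier", "identity", "gene", "pct_expressing",
               "mean_lognorm", "n_cells")]
  fmt <- db
  fmt$pct_expressing <- formatC(db$pct_expressing, format = "g", digits = 10)
  fmt$mean_lognorm <- formatC(db$mean_lognorm, format = "g", digits = 10)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(db)
}

#' Re-import a summary database written by [export_database()]
#' @param path TSV path.
#' @export
import_database <- function(path) {
  if (!file.exists(path)) kc_abort(paste("no such file:", path), "io_error")
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "")
}
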