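test_that("apply_threshold assigns the argmax above an inclusive boundary", {
  probs <- rbind(c(Nephron = 0.95, Stroma = 0.03, NPC = 0.01),
                 c(Nephron = 0.69, Stroma = 0.10, NPC = 0.05),
                 c(Nephron = 0.70, Stroma = 0.10, NPC = 0.05))
  expect_equal(apply_threshold(probs, 0.7),
               c("Nephron", "unassigned", "Nephron"))  # 0.70 == 0.7 assigns
  expect_false(any(apply_threshold(probs, 0) == "unassigned"))
  expect_true(all(apply_threshold(probs, 1.01) == "unassigned"))
  # ties go to the first column
  tie <- matrix(c(0.8, 0.8, 0.1), 1, dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(apply_threshold(tie, 0.5), "A")
})

test_that("classified cells respect the tree hierarchy", {
  ann <- small_ann()
  tree <- small_fit()$tree
  # tier-k label is a child of the tier-(k-1) label
  has2 <- ann$tier2 != ""
  expect_true(all(ann$tier2[has2] %in% unlist(tree$children[ann$tier1[has2]])))
  has3 <- ann$tier3 != ""
  ok3 <- vapply(which(has3), function(i)
    ann$tier3[i] %in% tree$children[[ann$tier2[i]]], logical(1))
  expect_true(all(ok3))
  # unassigned occurs only at tier 1, with empty deeper labels
  una <- ann$tier1 == "unassigned"
  expect_true(all(ann$tier2[una] == "" & ann$tier3[una] == ""))
  expect_true(all(ann$final_label[una] == "unassigned"))
  # no thresholding below tier 1: every routed lineage cell has a tier-2 label
  routed <- ann$tier1 %in% c("Stroma", "Nephron", "UrEp")
  expect_true(all(ann$tier2[routed] != ""))
  # final label is the deepest assigned identity
  deepest <- ifelse(ann$tier3 != "", ann$tier3,
                    ifelse(ann$tier2 != "", ann$tier2, ann$tier1))
  refined <- ann$final_label == "NPC-like"
  expect_equal(ann$final_label[!refined], deepest[!refined])
})

test_that("simulated tier-3 identities are recovered along their full path", {
  ann <- small_ann()
  truth <- small_split()$test$cell_meta
  pods <- truth$label == "Pod"
  expect_gte(mean(ann$tier1[pods] == "Nephron"), 0.95)
  expect_gte(mean(ann$tier2[pods] == "RC"), 0.9)
  expect_gte(mean(ann$tier3[pods] == "Pod"), 0.9)
})

test_that("unassigned fraction is monotone in the threshold", {
  ann <- small_ann()
  p1 <- as.matrix(ann[grep("^p_kidney_", colnames(ann))])
  colnames(p1) <- sub("^p_kidney_", "", colnames(p1))
  sweep_tab <- threshold_sweep(p1, grid = seq(0, 1.01, by = 0.1))
  expect_true(all(diff(sweep_tab$unassigned_frac) >= 0))
  expect_equal(sweep_tab$unassigned_frac[1], 0)
  expect_equal(sweep_tab$unassigned_frac[nrow(sweep_tab)], 1)
})

test_that("classify never alters the counts layer and merges annotations", {
  ds <- kidclass:::subset_cells(small_split()$test, 1:40)
  before <- as.matrix(ds$counts)
  out <- classify(ds, small_fit(), refine_npc = FALSE)
  expect_equal(as.matrix(out$counts), before, ignore_attr = TRUE)
  expect_true(all(c("tier1", "tier2", "tier3", "final_label") %in%
                    colnames(out$cell_meta)))
})

test_that("probability columns are bounded and recorded only where evaluated", {
  ann <- small_ann()
  pcols <- grep("^p_", colnames(ann), value = TRUE)
  for (col in pcols) {
    v <- ann[[col]][!is.na(ann[[col]])]
    expect_true(all(v >= 0 & v <= 1))
  }
  # tier-1 probabilities exist for every cell
  expect_false(anyNA(ann$p_kidney_Nephron))
  # deeper probabilities only for routed cells
  dn <- !is.na(ann$p_DN_DT)
  expect_true(all(ann$tier2[dn] == "DN"))
})

# ---- NPC refinement --------------------------------------------------------

# Build an NPC-labelled dataset with two far-separated clusters and a
# controlled PAX2-positive fraction per cluster.
refine_fixture <- function(frac1, frac2, n1 = 40, n2 = 40) {
  n <- n1 + n2
  n_genes <- 30
  # constant profiles within each cluster: the re-embedding then yields the
  # two designed clusters exactly, so per-cluster PAX2 fractions are exact
  counts <- matrix(2L, n, n_genes)
  counts[(n1 + 1):n, 1:10] <- counts[(n1 + 1):n, 1:10] + 60L
  pax <- integer(n)
  pax[seq_len(round(frac1 * n1))] <- 3L
  pax[n1 + seq_len(round(frac2 * n2))] <- 3L
  counts <- cbind(counts, PAX2 = pax)
  ids <- sprintf("npc%03d", 1:n)
  ds <- kc_dataset(counts, gene_ids = c(paste0("g", 1:n_genes), "PAX2"),
                   cell_ids = ids)
  ann <- data.frame(tier1 = rep("NPC", n), tier2 = "", tier3 = "",
                    final_label = "NPC", row.names = ids,
                    stringsAsFactors = FALSE)
  list(ds = ds, ann = ann, cluster = rep(1:2, c(n1, n2)))
}

test_that("clusters below 30% PAX2-positive become NPC-like; the 30% boundary stays NPC", {
  # pin the partition so the gate is tested in isolation from the clustering
  fx <- refine_fixture(frac1 = 0, frac2 = 0.30)
  testthat::local_mocked_bindings(
    louvain_clusters = function(scores, ...) fx$cluster,
    .package = "kidclass")
  out <- refine_npc(fx$ann, fx$ds, seed = 1)
  expect_true(all(out$final_label[fx$cluster == 1] == "NPC-like"))  # 0% expressing
  expect_true(all(out$final_label[fx$cluster == 2] == "NPC"))      # exactly 30%: strict
  expect_true(all(out$tier1 == "NPC"))  # tier-1 metadata is kept for audit
  # one notch below the boundary flips the call
  fx29 <- refine_fixture(frac1 = 0.9, frac2 = 0.275)  # 11/40 expressing
  testthat::local_mocked_bindings(
    louvain_clusters = function(scores, ...) fx29$cluster,
    .package = "kidclass")
  out29 <- refine_npc(fx29$ann, fx29$ds, seed = 1)
  expect_true(all(out29$final_label[fx29$cluster == 2] == "NPC-like"))
  expect_true(all(out29$final_label[fx29$cluster == 1] == "NPC"))
})

test_that("refinement is idempotent and only converts NPC to NPC-like", {
  fx <- refine_fixture(frac1 = 0, frac2 = 0.9)
  once <- refine_npc(fx$ann, fx$ds, seed = 1)
  twice <- refine_npc(once, fx$ds, seed = 1)
  expect_identical(once$final_label, twice$final_label)
  expect_true(all(once$final_label %in% c("NPC", "NPC-like")))
  # cells already NPC-like are never flipped back
  expect_true(all(once$final_label[fx$cluster == 1] == "NPC-like"))
})

test_that("refinement degenerate cases are safe", {
  # no NPC cells: annotation unchanged
  ds <- toy_dataset()
  ann <- data.frame(tier1 = c("Endo", "Stroma", "Endo", "Stroma"),
                    tier2 = "", tier3 = "",
                    final_label = c("Endo", "Stroma", "Endo", "Stroma"),
                    row.names = ds$cell_ids, stringsAsFactors = FALSE)
  expect_identical(refine_npc(ann, ds), ann)
  # PAX2 gene absent: warning and no-op
  fx <- refine_fixture(0, 0)
  ds2 <- kidclass:::subset_genes(fx$ds, paste0("g", 1:30))
  expect_warning(out <- refine_npc(fx$ann, ds2), "not present")
  expect_identical(out, fx$ann)
  # fewer than 3 NPC cells: treated as one cluster
  tiny <- refine_fixture(0, 0, n1 = 1, n2 = 1)
  out <- refine_npc(tiny$ann, tiny$ds, seed = 1)
  expect_true(all(out$final_label == "NPC-like"))
})

test_that("other labels are never touched by refinement", {
  fx <- refine_fixture(0, 0)
  fx$ann$tier1[1:10] <- "Stroma"
  fx$ann$final_label[1:10] <- "CS"
  out <- refine_npc(fx$ann, fx$ds, seed = 1)
  expect_equal(out$final_label[1:10], fx$ann$final_label[1:10])
})
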