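mk_ann <- function(tier1, tier2 = "", tier3 = "", final = NULL) {
  n <- length(tier1)
  data.frame(tier1 = tier1, tier2 = rep_len(tier2, n),
             tier3 = rep_len(tier3, n),
             final_label = final %||% ifelse(rep_len(tier3, n) != "", tier3,
                                      ifelse(rep_len(tier2, n) != "", tier2, tier1)),
             stringsAsFactors = FALSE)
}

test_that("composition percentages are exact and sum to 100", {
  ann <- mk_ann(c("A", "A", "A", "B"))
  comp <- composition(list(s = ann), tier = "tier1")
  expect_equal(comp$pct_of_sample[comp$identity == "A"], 75)
  expect_equal(comp$pct_of_sample[comp$identity == "B"], 25)
  only_una <- composition(list(s = mk_ann(rep("unassigned", 5))), "tier1")
  expect_equal(only_una$identity, "unassigned")
  expect_equal(only_una$pct_of_sample, 100)
  # per sample per tier the percentages always total 100
  ann2 <- small_ann()
  for (tier in c("tier1", "tier2", "tier3", "final")) {
    comp <- composition(list(a = ann2, b = ann2[1:100, ]), tier)
    sums <- tapply(comp$pct_of_sample, comp$sample, sum)
    expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-6)
  }
})

test_that("pooling two disjoint samples weights percentages by cell count", {
  a <- mk_ann(rep(c("A", "B"), c(3, 1)))   # 75/25 over 4 cells
  b <- mk_ann(rep(c("A", "B"), c(1, 3)))   # 25/75 over 4 cells
  pooled <- composition(list(p = rbind(a, b)), "tier1")
  expect_equal(pooled$pct_of_sample, c(50, 50))
})

test_that("classified composition tracks the simulated mixing proportions", {
  ann <- small_ann()
  truth <- truth_tiers(small_fit()$tree, small_split()$test$cell_meta$label)
  comp <- composition(list(sim = ann), "tier1")
  truth_tab <- 100 * table(truth$tier1) / nrow(truth)
  for (ident in names(truth_tab)) {
    got <- comp$pct_of_sample[comp$identity == ident]
    if (!length(got)) got <- 0
    expect_lt(abs(got - truth_tab[[ident]]), 5)  # percentage points
  }
})

test_that("dot-plot statistics match their closed forms and a per-cell oracle", {
  counts <- cbind(gX = c(0, 0, 3, 1), gOther = 1)  # second gene keeps totals positive
  ds <- kc_dataset(counts, gene_ids = c("gX", "gOther"), cell_ids = paste0("c", 1:4))
  ds$cell_meta$tier1 <- "A"; ds$cell_meta$tier2 <- ""
  ds$cell_meta$tier3 <- ""; ds$cell_meta$final_label <- "A"
  tab <- dotplot_stats(list(s = ds), genes = "gX")
  expect_equal(tab$pct_expressing, 50)  # 2 of 4 cells
  ln <- normalize_log1p(ds)$layers$lognorm
  expect_equal(tab$mean_lognorm, mean(ln[, "gX"]))  # zeros included
  # absent gene: emitted with zeros and a flag
  tab2 <- dotplot_stats(list(s = ds), genes = c("gX", "gMissing"))
  miss <- tab2[tab2$gene == "gMissing", ]
  expect_true(miss$missing_gene)
  expect_equal(miss$pct_expressing, 0)

  # 20-cell random fixture vs an independent per-cell loop
  set.seed(77)
  n <- 20
  cm <- cbind(matrix(rpois(n * 3, 1.5), n), 2L)  # constant gene keeps totals > 0
  ds2 <- kc_dataset(cm, gene_ids = c("g1", "g2", "g3", "gBase"),
                    cell_ids = sprintf("k%02d", 1:n))
  colnames(cm) <- ds2$gene_ids
  grp <- rep(c("X", "Y"), each = 10)
  ds2$cell_meta$tier1 <- grp; ds2$cell_meta$tier2 <- ""
  ds2$cell_meta$tier3 <- ""; ds2$cell_meta$final_label <- grp
  ds2 <- normalize_log1p(ds2)
  tab3 <- dotplot_stats(list(s = ds2), genes = c("g1", "g2", "g3"))
  for (r in seq_len(nrow(tab3))) {
    cells <- which(grp == tab3$identity[r])
    pos <- 0; tot <- 0
    for (i in cells) {
      pos <- pos + (cm[i, tab3$gene[r]] > 0)
      tot <- tot + ds2$layers$lognorm[i, tab3$gene[r]]
    }
    expect_equal(tab3$pct_expressing[r], unname(100 * pos / length(cells)))
    expect_equal(tab3$mean_lognorm[r], unname(tot / length(cells)))
  }
  # cell order does not matter
  ds2r <- kidclass:::subset_cells(ds2, rev(seq_len(n)))
  tab3r <- dotplot_stats(list(s = ds2r), genes = c("g1", "g2", "g3"))
  expect_equal(tab3r, tab3)
})

test_that("ident_means reproduces the closed-form mean/SD/SEM", {
  two <- list(s1 = mk_ann(rep(c("X", "Y"), c(4, 6))),   # X at 40%
              s2 = mk_ann(rep(c("X", "Y"), c(6, 4))))   # X at 60%
  im <- ident_means(two, "tier1")
  x <- im[im$identity == "X", ]
  expect_equal(x$mean_pct, 50)
  expect_equal(x$sd_pct, sd(c(40, 60)))
  expect_equal(x$sd_pct, 14.142, tolerance = 1e-3)
  expect_equal(x$sem_pct, x$sd_pct / sqrt(2))
  # single sample: dispersion undefined
  one <- ident_means(list(s1 = mk_ann(c("X", "Y"))), "tier1")
  expect_true(all(is.na(one$sd_pct)))
  # identical samples: zero SD
  same <- ident_means(list(a = mk_ann(c("X", "Y")), b = mk_ann(c("X", "Y"))),
                      "tier1")
  expect_equal(same$sd_pct, c(0, 0))
})

test_that("the summary database round trips and is consistent with dotplot_stats", {
  ds <- kidclass:::subset_cells(small_split()$test, 1:60)
  ds <- classify(ds, small_fit(), refine_npc = FALSE)
  genes <- ds$gene_ids[1:4]
  path <- withr::local_tempfile(fileext = ".tsv")
  db <- export_database(list(orgA = ds), genes = genes, path = path)
  back <- import_database(path)
  expect_equal(nrow(back), nrow(db))
  expect_equal(back$pct_expressing, db$pct_expressing, tolerance = 1e-9)
  expect_equal(back$mean_lognorm, db$mean_lognorm, tolerance = 1e-9)
  # per-tier row counts: identities present x genes
  for (tier in c("tier1", "tier2", "tier3")) {
    idents <- unique(kidclass:::label_at_tier(ds$cell_meta, tier))
    expect_equal(sum(db$tier == tier), length(idents) * length(genes))
  }
  # rows agree with a direct dotplot_stats call
  direct <- dotplot_stats(list(orgA = ds), genes = genes, tier = "tier1")
  sub <- db[db$tier == "tier1", ]
  key <- paste(sub$identity, sub$gene)
  dkey <- paste(direct$identity, direct$gene)
  expect_equal(sub$pct_expressing, direct$pct_expressing[match(key, dkey)])
  # a reference profile is emitted alongside, tagged "reference"
  withref <- dotplot_stats(list(orgA = ds), genes = genes, tier = "tier1",
                           reference_profile = back[back$tier == "tier1", ])
  expect_true("reference" %in% withref$sample)
})
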