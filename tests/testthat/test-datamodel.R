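test_that("MTX triplet round trip preserves counts and orientation", {
  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  write_mtx_triplet(ds, dir)
  back <- read_mtx_triplet(dir)
  expect_equal(dim(back$counts), dim(ds$counts))  # transposed back to cells x genes
  expect_equal(as.matrix(back$counts), as.matrix(ds$counts),
               ignore_attr = TRUE)
  expect_equal(back$gene_ids, ds$gene_ids)
  expect_equal(back$cell_ids, ds$cell_ids)
  # a second round trip is exact too
  dir2 <- withr::local_tempdir()
  write_mtx_triplet(back, dir2)
  again <- read_mtx_triplet(dir2)
  expect_equal(as.matrix(again$counts), as.matrix(back$counts),
               ignore_attr = TRUE)
})

test_that("reader rejects malformed triplets", {
  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  write_mtx_triplet(ds, dir)
  # duplicated feature id
  feats <- readLines(file.path(dir, "features.tsv"))
  writeLines(c(feats[-1], feats[2]), file.path(dir, "features.tsv"))
  expect_error(read_mtx_triplet(dir), class = "format_error")
  # dimension mismatch
  writeLines(feats[1:3], file.path(dir, "features.tsv"))
  expect_error(read_mtx_triplet(dir), class = "format_error")
  writeLines(feats, file.path(dir, "features.tsv"))
  # missing file
  file.remove(file.path(dir, "barcodes.tsv"))
  expect_error(read_mtx_triplet(dir), class = "io_error")
})

test_that("empty declared matrix reads as all-zero dataset", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "5 4 0"), file.path(dir, "matrix.mtx"))
  writeLines(paste0("g", 1:5), file.path(dir, "features.tsv"))
  writeLines(paste0("c", 1:4), file.path(dir, "barcodes.tsv"))
  ds <- read_mtx_triplet(dir)
  expect_equal(dim(ds$counts), c(4L, 5L))
  expect_equal(sum(ds$counts), 0)
})

test_that("negative or fractional counts are rejected", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 2", "1 1 -3", "2 2 1"), file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  expect_error(read_mtx_triplet(dir), class = "format_error")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "1 1 2.5"), file.path(dir, "matrix.mtx"))
  expect_error(read_mtx_triplet(dir), class = "format_error")
})

test_that("dataset constructor enforces identifier invariants", {
  m <- matrix(0:3, 2)
  expect_error(kc_dataset(m, gene_ids = c("g", "g"), cell_ids = c("a", "b")),
               class = "format_error")
  expect_error(kc_dataset(m, gene_ids = c("g1", "g2"), cell_ids = c("a", "a")),
               class = "format_error")
  expect_error(kc_dataset(m, gene_ids = "g1", cell_ids = c("a", "b")),
               class = "format_error")
  bad_meta <- data.frame(x = 1, row.names = "zz")
  expect_error(kc_dataset(m, gene_ids = c("g1", "g2"), cell_ids = c("a", "b"),
                          cell_meta = bad_meta),
               class = "format_error")
})

test_that("annotation table round trips and encodes unassigned cells", {
  n <- 3
  ds <- kc_dataset(matrix(1L, n, 2), gene_ids = c("g1", "g2"),
                   cell_ids = paste0("c", 1:n))
  ds$cell_meta$tier1 <- c("Nephron", "unassigned", "NPC")
  ds$cell_meta$tier2 <- c("RC", "", "")
  ds$cell_meta$tier3 <- c("Pod", "", "")
  ds$cell_meta$final_label <- c("Pod", "unassigned", "NPC-like")
  ds$cell_meta$p_kidney_Nephron <- c(0.95, 0.31, 0.12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(ds, path)
  back <- read_annotation_table(path)
  expect_equal(nrow(back), n)
  expect_equal(back$cell_id, ds$cell_ids)
  expect_equal(back$tier1, ds$cell_meta$tier1)
  expect_equal(back$tier2, ds$cell_meta$tier2)   # empty fields preserved
  expect_equal(back$final_label, ds$cell_meta$final_label)
  expect_equal(back$p_kidney_Nephron, ds$cell_meta$p_kidney_Nephron,
               tolerance = 1e-9)
  # unassigned row carries no deeper labels
  una <- back[back$tier1 == "unassigned", ]
  expect_identical(una$tier2, "")
  expect_identical(una$tier3, "")
  expect_identical(una$final_label, "unassigned")
})

test_that("annotation export requires classification columns", {
  expect_error(write_annotation_table(toy_dataset(), tempfile()),
               class = "state_error")
})

test_that("model bundles round trip exactly and verify integrity", {
  fit <- small_fit()
  q <- kidclass:::subset_cells(small_split()$test, 1:50)
  p_orig <- predict(fit, q, refine_npc = FALSE)
  dir <- file.path(withr::local_tempdir(), "bundle")
  save_model(fit, dir)
  back <- load_model(dir)
  p_back <- predict(back, q, refine_npc = FALSE)
  expect_identical(p_orig, p_back)

  # tampered tree digest
  mf <- file.path(dir, "manifest.json")
  m <- jsonlite::read_json(mf)
  m$tree_digest <- paste(rev(strsplit(m$tree_digest, "")[[1]]), collapse = "")
  jsonlite::write_json(m, mf, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(load_model(dir), class = "integrity_error")

  # corrupted node artifact
  save_model(fit, dir2 <- file.path(withr::local_tempdir(), "b2"))
  f <- list.files(file.path(dir2, "nodes"), full.names = TRUE)[1]
  writeBin(as.raw(1:100), f)
  expect_error(load_model(dir2), class = "integrity_error")

  # empty directory
  expect_error(load_model(withr::local_tempdir()), class = "io_error")

  # version mismatch
  save_model(fit, dir3 <- file.path(withr::local_tempdir(), "b3"))
  m <- jsonlite::read_json(file.path(dir3, "manifest.json"))
  m$format_version <- "99"
  jsonlite::write_json(m, file.path(dir3, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(load_model(dir3), class = "compatibility_error")
})
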