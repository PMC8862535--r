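# Shared fixtures, built once per test run and cached. Everything is
# generated in code; no data files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A small full-tree simulation + trained hierarchy, reused across tests.
small_sim <- function() cached("small_sim",
  simulate_kidney(sim_config(n_cells_per_leaf = 40, n_genes = 800, seed = 42)))

small_split <- function() cached("small_split",
  split_train_test(small_sim(), 0.5, seed = 42))

small_fit <- function() cached("small_fit",
  kidclass(small_split()$train, seed = 42,
           params = node_params(cv_folds = 0, seed = 42)))

small_ann <- function() cached("small_ann",
  predict(small_fit(), small_split()$test, seed = 42))

# A 2-lineage toy tree for cheap simulator-level tests.
mini_tree <- function() identity_tree(list(
  name = "root",
  children = list(
    list(name = "A", children = list(list(name = "a1"), list(name = "a2"))),
    list(name = "B", children = list(list(name = "b1"), list(name = "b2")))
  )))

# Tiny handmade dataset: 4 cells x 5 genes with known counts.
toy_dataset <- function() {
  counts <- matrix(c(2, 0, 2, 0, 1,
                     0, 3, 0, 1, 0,
                     5, 0, 0, 0, 0,
                     1, 1, 1, 1, 1), nrow = 4, byrow = TRUE)
  kc_dataset(counts, gene_ids = paste0("g", 1:5), cell_ids = paste0("c", 1:4))
}

# Two Gaussian blobs embedded as a lognorm layer (counts are placeholders),
# for classifier-level tests where the feature geometry must be exact.
blob_dataset <- function(n_per = 30, d = 2, shift = 4, sd = 1, seed = 99,
                         extra_genes = 0) {
  set.seed(seed)
  n <- 2 * n_per
  x <- rbind(matrix(rnorm(n_per * d, 0, sd), n_per),
             matrix(rnorm(n_per * d, shift, sd), n_per))
  if (extra_genes > 0)
    x <- cbind(x, matrix(rnorm(n * extra_genes, 2, sd), n))
  x <- x - min(x)  # lognorm layers are non-negative
  ids <- sprintf("blob%03d", seq_len(n))
  ds <- kc_dataset(matrix(1L, n, ncol(x)),
                   gene_ids = paste0("g", seq_len(ncol(x))),
                   cell_ids = ids,
                   cell_meta = data.frame(label = rep(c("L", "R"), each = n_per),
                                          row.names = ids))
  ds$layers$lognorm <- x
  dimnames(ds$layers$lognorm) <- dimnames(ds$counts)
  ds
}

blob_params <- function(seed = 1, cv_folds = 3)
  node_params(n_pcs = 2, n_hvg = 50, min_cells = 5, cv_folds = cv_folds,
              seed = seed)

# Truth helper: lift simulator labels to their tier-1 ancestors.
truth_tiers <- function(tree, labels) {
  m <- t(vapply(unique(labels), function(l) lift_label(tree, l), character(3)))
  data.frame(tier1 = m[labels, 1], tier2 = m[labels, 2], tier3 = m[labels, 3],
             stringsAsFactors = FALSE)
}

cli_path <- function() system.file("cli", "kidclass.R", package = "kidclass")

run_cli <- function(...) {
  args <- c(cli_path(), ...)
  res <- suppressWarnings(system2(file.path(R.home("bin"), "Rscript"), args,
                                  stdout = TRUE, stderr = TRUE))
  list(status = attr(res, "status") %||% 0L, output = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
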