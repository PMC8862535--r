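# Model bundle: a directory holding a JSON manifest (format version, engine
# parameters, the identity tree and its digest) plus one serialized artifact
# per node model. load_model() verifies the format version, the tree digest
# and a checksum per artifact, so silent corruption surfaces as an error
# instead of wrong predictions.

BUNDLE_FORMAT <- "1.0"

tree_digest <- function(tree) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(tree$spec, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Save a trained hierarchy model to a directory
#'
#' @param model A `kidclass` model.
#' @param dir Output directory (created; must be empty or absent).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "kidclass"))
  dir.create(file.path(dir, "nodes"), recursive = TRUE, showWarnings = FALSE)
  checksums <- character(0)
  for (nm in names(model$nodes)) {
    f <- file.path(dir, "nodes", paste0(nm, ".rds"))
    saveRDS(model$nodes[[nm]], f, version = 2)
    checksums[nm] <- unname(tools::md5sum(f))
  }
  manifest <- list(
    format_version = BUNDLE_FORMAT,
    package = "kidclass",
    tree = model$tree$spec,
    tree_digest = tree_digest(model$tree),
    params = model$params[c("model", "n_pcs", "n_hvg", "cost", "min_cells",
                            "cv_folds", "seed")],
    label_col = model$label_col,
    batch_col = model$batch_col,
    nodes = names(model$nodes),
    checksums = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Load a hierarchy model saved by [save_model()]
#'
#' @param dir Bundle directory.
#' @return A `kidclass` model whose predictions are identical to the saved
#'   model's.
#' @export
load_model <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    kc_abort(sprintf("no manifest.json in '%s'", dir), "io_error")
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$format_version, BUNDLE_FORMAT))
    kc_abort(sprintf("bundle format '%s' not supported (expected '%s')",
                     manifest$format_version %||% "?", BUNDLE_FORMAT),
             "compatibility_error")
  tree <- identity_tree(manifest$tree)
  if (!identical(tree_digest(tree), manifest$tree_digest))
    kc_abort("manifest tree digest does not match the embedded tree",
             "integrity_error")
  nodes <- list()
  for (nm in unlist(manifest$nodes)) {
    f <- file.path(dir, "nodes", paste0(nm, ".rds"))
    if (!file.exists(f))
      kc_abort(sprintf("missing node artifact '%s'", nm), "integrity_error")
    if (!identical(unname(tools::md5sum(f)), manifest$checksums[[nm]]))
      kc_abort(sprintf("checksum mismatch for node artifact '%s'", nm),
               "integrity_error")
    nodes[[nm]] <- readRDS(f)
  }
  params <- manifest$params
  structure(list(tree = tree, nodes = nodes,
                 params = lapply(params, function(x) if (is.list(x)) unlist(x) else x),
                 label_col = manifest$label_col,
                 batch_col = manifest$batch_col,
                 version = manifest$format_version),
            class = "kidclass")
}
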