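#' Identity trees
#'
#' The classification hierarchy is data, not code: a rooted tree whose first
#' tier holds the broad lineages and whose deeper tiers refine them. Each
#' internal node owns one multi-class classifier trained on its children.
#' The developing-kidney tree shipped with the package ([kidney_tree()]) has
#' five first-tier lineages (Stroma, NPC, Nephron, UrEp, Endo), second-tier
#' segments under Stroma, Nephron and UrEp, and third-tier subtypes under the
#' distal nephron (DN), proximal nephron (PN) and renal corpuscle (RC).
#' Classifying other tissues only requires a different tree document.
#'
#' @param x A nested list with fields `name` and optional `children`, or a
#'   path to a JSON file with that structure.
#' @return An object of class `identity_tree`.
#' @export
identity_tree <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) kc_abort(paste("no such tree file:", x), "io_error")
    x <- jsonlite::read_json(x)
  }
  parent <- character(0)
  children <- list()
  order_seen <- character(0)
  dup <- character(0)
  walk <- function(node, par) {
    nm <- trimws(node$name)
    if (nm %in% order_seen) dup <<- c(dup, nm)
    order_seen <<- c(order_seen, nm)
    parent[nm] <<- par
    kids <- node$children
    kid_names <- if (is.null(kids)) character(0) else
      vapply(kids, function(k) trimws(k$name), character(1))
    attr(kid_names, "declared") <- !is.null(kids)
    children[[nm]] <<- kid_names
    if (!is.null(kids)) for (k in kids) walk(k, nm)
  }
  walk(x, NA_character_)
  root <- order_seen[1]
  tr <- structure(list(root = root, parent = parent, children = children,
                       preorder = order_seen, spec = x,
                       duplicates = unique(dup)),
                  class = "identity_tree")
  tr
}

#' The developing human kidney identity tree
#' @return An `identity_tree` with 19 terminal identities across three tiers.
#' @export
kidney_tree <- function() {
  identity_tree(system.file("extdata", "kidney_identity_tree.json",
                            package = "kidclass", mustWork = TRUE))
}

#' @export
#' @method print identity_tree
print.identity_tree <- function(x, ...) {
  rec <- function(nm, depth) {
    cat(strrep("  ", depth), nm, "\n", sep = "")
    for (k in x$children[[nm]]) rec(k, depth + 1)
  }
  rec(x$root, 0)
  invisible(x)
}

#' Validate an identity tree
#'
#' Checks the structural invariants the classifier relies on: unique labels,
#' a single parent per node, and no internal node declared with an empty or
#' single-child list (such a node could not own a multi-class model).
#'
#' @param tree An `identity_tree`.
#' @return Character vector of violations; `character(0)` when the tree is
#'   well formed.
#' @export
validate_tree <- function(tree) {
  v <- character(0)
  if (length(tree$duplicates))
    v <- c(v, sprintf("label '%s' appears under more than one parent",
                      tree$duplicates))
  for (nm in tree$preorder) {
    kids <- tree$children[[nm]]
    if (isTRUE(attr(kids, "declared")) && length(kids) == 0)
      v <- c(v, sprintf("node '%s' declares a children list but has no children", nm))
    if (length(kids) == 1)
      v <- c(v, sprintf("internal node '%s' has a single child; a node model needs >= 2 classes", nm))
  }
  v
}

# Internal nodes that own a classifier (>= 2 children), in preorder.
model_nodes <- function(tree) {
  nodes <- tree$preorder[vapply(tree$preorder,
                                function(n) length(tree$children[[n]]) >= 2,
                                logical(1))]
  nodes
}

# Terminal identities = nodes with no children (root excluded).
#' Terminal identities of a tree
#' @param tree An `identity_tree`.
#' @export
tree_leaves <- function(tree) {
  setdiff(tree$preorder[vapply(tree$preorder,
                               function(n) length(tree$children[[n]]) == 0,
                               logical(1))], tree$root)
}

# Path from root (exclusive) to label, i.e. the tier-1..tier-k ancestry.
label_path <- function(tree, label) {
  if (!label %in% tree$preorder) return(NULL)
  path <- character(0)
  cur <- label
  while (!is.na(tree$parent[[cur]])) {
    path <- c(cur, path)
    cur <- tree$parent[[cur]]
  }
  path
}

#' Lift a terminal label to its tier-wise ancestry
#'
#' @param tree An `identity_tree`.
#' @param label A node label.
#' @return Named character vector with entries `tier1`, `tier2`, `tier3`
#'   (empty string where the label terminates above that tier).
#' @export
lift_label <- function(tree, label) {
  path <- label_path(tree, label)
  if (is.null(path))
    kc_abort(sprintf("label '%s' is not in the identity tree", label), "label_error")
  out <- c(tier1 = "", tier2 = "", tier3 = "")
  out[seq_len(min(3, length(path)))] <- path[seq_len(min(3, length(path)))]
  out
}

# tier map for a vector of labels -> data.frame(tier1,tier2,tier3)
tier_map <- function(tree, labels) {
  u <- unique(labels)
  m <- t(vapply(u, function(l) lift_label(tree, l), character(3)))
  data.frame(tier1 = m[labels, 1], tier2 = m[labels, 2], tier3 = m[labels, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pool labeled reference datasets
#'
#' Concatenates cells across datasets, restricts genes to the common
#' intersection (in the first dataset's order), records the source of each
#' cell in a `source` metadata column (usable as a batch key), and checks
#' that every label resolves in the identity tree.
#'
#' @param datasets List of [kc_dataset()] objects carrying a label column.
#' @param tree An `identity_tree`.
#' @param label_col Name of the label column in each dataset's `cell_meta`.
#' @return A single [kc_dataset()].
#' @export
assemble_reference <- function(datasets, tree, label_col = "label") {
  stopifnot(length(datasets) >= 1)
  genes <- Reduce(intersect, lapply(datasets, function(d) d$gene_ids))
  if (length(genes) == 0)
    kc_abort("datasets share no genes", "gene_overlap_error")
  nms <- names(datasets) %||% paste0("ref", seq_along(datasets))
  if (is.null(names(datasets))) names(datasets) <- nms
  parts <- lapply(seq_along(datasets), function(i) {
    d <- subset_genes(datasets[[i]], genes)
    if (!label_col %in% colnames(d$cell_meta))
      kc_abort(sprintf("dataset %d lacks label column '%s'", i, label_col),
               "label_error")
    bad <- setdiff(unique(d$cell_meta[[label_col]]), tree$preorder)
    if (length(bad))
      kc_abort(sprintf("unknown label(s) not in tree: %s",
                       paste(bad, collapse = ", ")), "label_error")
    d$cell_meta$source <- nms[i]
    d
  })
  counts <- do.call(rbind, lapply(parts, function(d) d$counts))
  meta_cols <- Reduce(union, lapply(parts, function(d) colnames(d$cell_meta)))
  meta <- do.call(rbind, lapply(parts, function(d) {
    m <- d$cell_meta
    for (mc in setdiff(meta_cols, colnames(m))) m[[mc]] <- NA
    m[, meta_cols, drop = FALSE]
  }))
  cell_ids <- unlist(lapply(parts, function(d) d$cell_ids), use.names = FALSE)
  if (anyDuplicated(cell_ids))
    cell_ids <- paste(rep(nms, vapply(parts, function(d) nrow(d$counts), 1L)),
                      cell_ids, sep = "_")
  rownames(meta) <- cell_ids
  kc_dataset(counts, gene_ids = genes, cell_ids = cell_ids, cell_meta = meta)
}
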