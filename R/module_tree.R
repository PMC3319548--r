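#' Hierarchical gene modules
#'
#' A hierarchical gene module is a rooted tree whose leaves are genes and
#' whose internal nodes represent progressively broader functional groupings.
#' Gene IDs are unique among the leaves of one tree; in a fuzzy forest the
#' same gene may appear as a leaf of several trees.
#'
#' @name module_tree
#' @keywords internal
NULL

#' Construct a module tree
#'
#' @param children named list mapping each internal node ID to the character
#'   vector of its child node IDs; nodes absent from the list are leaves.
#' @param genes named character vector mapping leaf node IDs to gene IDs.
#'   Leaf IDs equal to the gene ID are the common case; pass names only when
#'   they differ.
#' @param root root node ID. Defaults to the unique node that is nobody's
#'   child.
#' @return an object of class `"module_tree"`.
#' @export
module_tree <- function(children, genes, root = NULL) {
  if (is.null(names(genes))) names(genes) <- genes
  kids <- unlist(children, use.names = FALSE)
  nodes <- unique(c(names(children), kids, names(genes)))
  if (is.null(root)) {
    root <- setdiff(nodes, kids)
    if (length(root) != 1L) stop("tree must have exactly one root")
  }
  leaves <- setdiff(nodes, names(children))
  if (!setequal(leaves, names(genes))) {
    stop("leaf node IDs must match names(genes)")
  }
  # duplicate gene values are tolerated (fuzzy merges); node IDs must be unique
  if (anyDuplicated(kids)) stop("a node may have only one parent")
  if (anyDuplicated(names(genes))) stop("leaf node IDs must be unique")
  structure(list(children = children, genes = genes, root = root,
                 nodes = nodes),
            class = "module_tree")
}

#' A single-gene (leaf) module tree
#' @param gene gene ID.
#' @return a `"module_tree"` with one node.
#' @export
leaf_tree <- function(gene) {
  module_tree(children = setNames(list(), character(0)),
              genes = setNames(gene, gene), root = gene)
}

#' Join trees under a new root
#' @param trees list of `"module_tree"` objects with disjoint node IDs.
#' @param root_id ID for the new root node.
#' @return a `"module_tree"`.
#' @export
join_trees <- function(trees, root_id) {
  children <- c(setNames(list(vapply(trees, function(t) t$root, character(1))),
                         root_id),
                do.call(c, lapply(trees, `[[`, "children")))
  genes <- do.call(c, lapply(trees, `[[`, "genes"))
  module_tree(children, genes, root = root_id)
}

#' @export
print.module_tree <- function(x, ...) {
  cat("Hierarchical gene module:", length(x$genes), "genes,",
      length(x$children), "internal nodes\n")
  cat(" ", to_newick(x), "\n")
  invisible(x)
}

internal_nodes <- function(tree) names(tree$children)

leaf_nodes <- function(tree) names(tree$genes)

is_leaf <- function(tree, node) node %in% names(tree$genes)

# Children-before-parents node order.
postorder_nodes <- function(tree) {
  out <- character(0)
  walk <- function(v) {
    for (c0 in tree$children[[v]]) walk(c0)
    out[[length(out) + 1L]] <<- v
  }
  walk(tree$root)
  unlist(out)
}

node_heights <- function(tree) {
  h <- setNames(integer(length(tree$nodes)), tree$nodes)
  for (v in postorder_nodes(tree)) {
    kids <- tree$children[[v]]
    h[[v]] <- if (length(kids)) max(h[kids]) + 1L else 0L
  }
  h
}

# Leaf genes below each node.
subtree_genes <- function(tree, node = tree$root) {
  if (is_leaf(tree, node)) return(unname(tree$genes[node]))
  unlist(lapply(tree$children[[node]], subtree_genes, tree = tree),
         use.names = FALSE)
}

# Extract the subtree rooted at `node` as a free-standing module_tree.
extract_subtree <- function(tree, node) {
  if (is_leaf(tree, node)) return(leaf_tree(unname(tree$genes[node])))
  keep_int <- character(0)
  keep_leaf <- character(0)
  walk <- function(v) {
    if (is_leaf(tree, v)) { keep_leaf <<- c(keep_leaf, v); return(invisible(NULL)) }
    keep_int <<- c(keep_int, v)
    for (c0 in tree$children[[v]]) walk(c0)
  }
  walk(node)
  module_tree(tree$children[keep_int], tree$genes[keep_leaf], root = node)
}

#' Serialize a module tree to a Newick string
#'
#' Leaf labels are gene IDs; internal labels, when `labels` is supplied, are
#' written after the closing parenthesis (used to carry node annotations,
#' pipe-joined).
#'
#' @param tree a `"module_tree"`.
#' @param labels optional named character vector of internal-node labels.
#' @return a Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, labels = NULL) {
  fmt <- function(v) {
    if (is_leaf(tree, v)) return(newick_quote(unname(tree$genes[v])))
    lab <- if (!is.null(labels) && v %in% names(labels)) newick_quote(labels[[v]]) else ""
    paste0("(", paste(vapply(tree$children[[v]], fmt, character(1)),
                      collapse = ","), ")", lab)
  }
  paste0(fmt(tree$root), ";")
}

newick_quote <- function(x) {
  if (grepl("[ \t(),:;\\[\\]']", x)) paste0("'", gsub("'", "''", x), "'") else x
}
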