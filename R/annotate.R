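#' Hierarchical functional annotation of a gene module
#'
#' Installs the leaf annotations and then annotates every internal node
#' bottom-up: the annotation `F(v)` of an internal node is the largest
#' unrelated subset of the intersection of its children's ancestor term
#' sets — the *most specific common functional terms* among the children.
#' `F(v)` is never empty because the root term belongs to every ancestor set.
#'
#' @param tree a [module_tree].
#' @param annotations named list mapping gene IDs to character vectors of
#'   term IDs. Sets violating unrelatedness are reduced to their most
#'   specific members with a warning.
#' @param tax a [taxonomy].
#' @param unannotated policy for leaves whose gene has no annotation:
#'   `"error"` (default) or `"root"` (annotate with the root term, the
#'   convention for hypothetical/unannotated genes).
#' @return an object of class `"annotated_module"`: the tree plus the
#'   node-to-term-set annotation function `F`.
#' @export
annotate_module <- function(tree, annotations, tax,
                            unannotated = c("error", "root")) {
  unannotated <- match.arg(unannotated)
  F <- vector("list", length(tree$nodes)); names(F) <- tree$nodes

  reduced <- character(0)
  for (leaf in leaf_nodes(tree)) {
    g <- tree$genes[[leaf]]
    terms <- annotations[[g]]
    if (is.null(terms) || length(terms) == 0L) {
      if (unannotated == "error") stop("gene has no annotation: ", g)
      terms <- tax$root
    }
    red <- reduce_to_specific(terms, tax)
    if (length(red) < length(unique(terms))) reduced <- c(reduced, g)
    F[[leaf]] <- red
  }
  if (length(reduced)) {
    warning("annotations reduced to their most specific terms for gene(s): ",
            paste(unique(reduced), collapse = ", "))
  }

  for (v in postorder_nodes(tree)) {
    if (is_leaf(tree, v)) next
    kids <- tree$children[[v]]
    if (length(kids) == 1L) {          # degenerate node after a hierarchy cut
      F[[v]] <- F[[kids]]
      next
    }
    common <- Reduce(intersect, lapply(F[kids], ancestor_term_set, tax = tax))
    F[[v]] <- max_unrelated_subset(common, tax)
  }

  structure(list(tree = tree, F = F), class = "annotated_module")
}

#' @export
print.annotated_module <- function(x, ...) {
  cat("Annotated hierarchical gene module:", length(x$tree$genes), "genes\n")
  for (v in rev(postorder_nodes(x$tree))) {
    tag <- if (is_leaf(x$tree, v)) paste0(x$tree$genes[[v]], " (leaf)") else v
    cat(sprintf("  %-14s F = {%s}\n", tag, paste(x$F[[v]], collapse = ", ")))
  }
  invisible(x)
}
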