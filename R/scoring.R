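#' Scoring configuration for the hierarchical modularity score
#'
#' Collects the tunable parameters of HMS scoring.
#'
#' @param theta positive penalization parameter. Larger values forgive
#'   parent--child annotation drift: with the default reciprocal variant the
#'   penalty for terms one taxonomy edge apart is 50% at `theta = 1` and
#'   shrinks towards 0 as `theta` grows.
#' @param penalty_variant functional form of the penalization factor:
#'   `"reciprocal"` (`P = 1 - D/(D + theta)`, the default), `"exponential"`
#'   (`exp(-D/theta)`) or `"linear"` (`max(0, 1 - D/L)`), where `D` is the
#'   largest child set-distance and `L` the taxonomy depth.
#' @param node_aggregation how per-node contributions `P(v) * sigma*(F(v))`
#'   combine into the module score: `"mean"` over internal nodes (default,
#'   size-comparable across modules) or `"sum-normalized"`
#'   (`sum(P*sigma) / sum(sigma)`, the penalty-weighted fraction of
#'   attainable specificity).
#' @param set_distance_aggregation how per-term minimum distances combine
#'   into the parent-to-child set distance `D`: `"max"` (default) or
#'   `"mean"`.
#' @param level_aggregation how a term's occurrence levels combine into its
#'   specificity (relevant for DAG taxonomies): `"mean"`, `"min"` or
#'   `"max"`.
#' @param set_specificity how the specificities of the terms in `F(v)`
#'   combine into the node specificity `sigma*`: `"max"` (default; annotate
#'   by the most specific common term) or `"mean"`.
#' @return an object of class `"scoring_config"`.
#' @export
scoring_config <- function(theta = 10,
                           penalty_variant = c("reciprocal", "exponential", "linear"),
                           node_aggregation = c("mean", "sum-normalized"),
                           set_distance_aggregation = c("max", "mean"),
                           level_aggregation = c("mean", "min", "max"),
                           set_specificity = c("max", "mean")) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    stop("theta must be a single positive number")
  }
  structure(list(theta = theta,
                 penalty_variant = match.arg(penalty_variant),
                 node_aggregation = match.arg(node_aggregation),
                 set_distance_aggregation = match.arg(set_distance_aggregation),
                 level_aggregation = match.arg(level_aggregation),
                 set_specificity = match.arg(set_specificity)),
            class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("HMS scoring configuration\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, x[[f]]))
  invisible(x)
}

# Parent-to-child set distance D: aggregate over parent terms of the minimum
# taxonomy distance to any related child term. Inf when a parent term has no
# related partner (under max aggregation the whole D is then Inf).
set_distance <- function(parent_terms, child_terms, tax, config) {
  per_term <- vapply(parent_terms, function(tp) {
    min(vapply(child_terms, function(tc) term_distance_fast(tp, tc, tax),
               numeric(1)))
  }, numeric(1))
  switch(config$set_distance_aggregation,
         max = max(per_term),
         mean = mean(per_term))
}

#' Dissimilarity between a parent and a child annotation
#'
#' `d = D / (D + theta)` where `D` is the aggregated shortest-path distance
#' between the two unrelated term sets; 0 for identical annotations, 1 when
#' the sets are unrelated (`D = Inf`).
#'
#' @param parent_terms,child_terms unrelated term sets (character vectors).
#' @param tax a [taxonomy].
#' @param config a [scoring_config].
#' @return numeric in `[0, 1]`.
#' @export
dissimilarity <- function(parent_terms, child_terms, tax,
                          config = scoring_config()) {
  D <- set_distance(parent_terms, child_terms, tax, config)
  if (is.infinite(D)) 1 else D / (D + config$theta)
}

#' Penalization factor of an internal node
#'
#' Discounts a node's score by how far (in taxonomy edges) its annotation
#' sits from its children's annotations: `P = 1` when every child annotation
#' equals the parent's, decreasing towards 0 as the worst child drifts away.
#'
#' @param node_terms the node's annotation (unrelated term set).
#' @param children_terms list of the children's annotations.
#' @inheritParams dissimilarity
#' @return numeric in `[0, 1]`.
#' @export
penalization <- function(node_terms, children_terms, tax,
                         config = scoring_config()) {
  if (length(children_terms) == 0L) stop("node has no children")
  D <- vapply(children_terms, set_distance, numeric(1),
              parent_terms = node_terms, tax = tax, config = config)
  D_max <- max(D)
  penal_from_distance(D_max, tax, config)
}

penal_from_distance <- function(D_max, tax, config) {
  switch(config$penalty_variant,
         reciprocal = if (is.infinite(D_max)) 0 else
           1 - D_max / (D_max + config$theta),
         exponential = exp(-D_max / config$theta),
         linear = max(0, 1 - D_max / tax$depth))
}

node_sigma <- function(terms, tax, config) {
  s <- tax$sigma[[config$level_aggregation]][terms]
  switch(config$set_specificity, max = max(s), mean = mean(s))
}

#' Hierarchical modularity score (HMS)
#'
#' The functional-coherence score of an annotated hierarchical gene module:
#' per internal node, the term specificity of its annotation weighted by its
#' penalization factor, aggregated over internal nodes. A perfectly coherent
#' module whose genes share a maximally specific term scores 1; a module
#' whose nodes share nothing but the root scores 0.
#'
#' @param module an [annotate_module] result, or a list of them (a forest,
#'   whose internal nodes are pooled; a forest with no internal node
#'   scores 0).
#' @inheritParams dissimilarity
#' @param details if `TRUE`, also return the per-node penalizations and
#'   specificities.
#' @return numeric in `[0, 1]`, or a list with components `hms` and `nodes`
#'   (a data.frame) when `details = TRUE`.
#' @export
hms <- function(module, tax, config = scoring_config(), details = FALSE) {
  mods <- if (inherits(module, "annotated_module")) list(module) else module
  stopifnot(all(vapply(mods, inherits, logical(1), "annotated_module")))
  if (length(mods) == 1L && length(mods[[1L]]$tree$genes) < 2L &&
      length(internal_nodes(mods[[1L]]$tree)) == 0L) {
    stop("HMS is undefined for a single-leaf module")
  }
  tree_id <- integer(0); node_id <- character(0)
  Pv <- numeric(0); sv <- numeric(0)
  for (m in seq_along(mods)) {
    am <- mods[[m]]
    for (v in internal_nodes(am$tree)) {
      kids <- am$tree$children[[v]]
      P <- if (length(kids) == 1L) 1 else   # degenerate pass-through node
        penalization(am$F[[v]], am$F[kids], tax, config)
      tree_id <- c(tree_id, m); node_id <- c(node_id, v)
      Pv <- c(Pv, P); sv <- c(sv, node_sigma(am$F[[v]], tax, config))
    }
  }
  score <- if (length(Pv) == 0L) 0 else
    switch(config$node_aggregation,
           mean = mean(Pv * sv),
           `sum-normalized` = if (sum(sv) == 0) 0 else sum(Pv * sv) / sum(sv))
  if (details) {
    list(hms = score,
         nodes = data.frame(tree = tree_id, node = node_id, P = Pv,
                            sigma = sv, stringsAsFactors = FALSE))
  } else {
    score
  }
}

#' HMS of a gene pair
#'
#' Convenience wrapper scoring the two-leaf module (two genes under one
#' root): the specificity of the pair's most specific common annotation,
#' discounted by how far each gene's annotation sits from it.
#'
#' @param gene_a,gene_b distinct gene IDs.
#' @param annotations named list mapping gene IDs to term-ID vectors.
#' @inheritParams dissimilarity
#' @return numeric in `[0, 1]`.
#' @export
pair_score <- function(gene_a, gene_b, annotations, tax,
                       config = scoring_config()) {
  if (identical(gene_a, gene_b)) stop("pair_score needs two distinct genes")
  tree <- join_trees(list(leaf_tree(gene_a), leaf_tree(gene_b)), "pair_root")
  am <- annotate_module(tree, annotations, tax)
  hms(am, tax, config)
}
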