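#' Similarity between two annotated clusters
#'
#' The similarity TAFI uses as its linkage: the hierarchical modularity score
#' of the hypothetical module obtained by adding a new root whose children
#' are the two clusters' roots. Because HMS is a semi-metric (no triangle
#' inequality), it serves directly as the linkage; no separate linkage rule
#' (average, complete, Ward, ...) is involved.
#'
#' @param a,b [annotate_module] results (annotated cluster trees).
#' @param tax a [taxonomy].
#' @param config a [scoring_config].
#' @return numeric in `[0, 1]`.
#' @export
cluster_similarity <- function(a, b, tax, config = scoring_config()) {
  if (is.null(a$sums)) a$sums <- hms_sums(a, tax, config)
  if (is.null(b$sums)) b$sums <- hms_sums(b, tax, config)
  merged <- merge_annotated(a, b, tax, config, root_id = ".virtual_root")
  merged$sim
}

# Merge two annotated clusters under a new root; returns the annotated
# module, the new root's P and sigma, and the merged tree's HMS, computed
# incrementally from the constituents' running sums.
merge_annotated <- function(a, b, tax, config, root_id) {
  common <- intersect(ancestor_term_set(a$F[[a$tree$root]], tax),
                      ancestor_term_set(b$F[[b$tree$root]], tax))
  F_r <- max_unrelated_subset(common, tax)
  P_r <- penalization(F_r, list(a$F[[a$tree$root]], b$F[[b$tree$root]]),
                      tax, config)
  s_r <- node_sigma(F_r, tax, config)

  ta <- a$tree; tb <- b$tree
  Fb <- b$F
  clash <- intersect(ta$nodes, tb$nodes)
  if (length(clash)) {
    taken <- c(ta$nodes, tb$nodes)
    map <- setNames(tb$nodes, tb$nodes)
    for (v in clash) {
      cand <- paste0(v, "*")
      while (cand %in% taken) cand <- paste0(cand, "*")
      map[[v]] <- cand
      taken <- c(taken, cand)
    }
    tb <- rename_nodes(tb, map)
    names(Fb) <- unname(map[names(Fb)])
  }
  tree <- join_trees(list(ta, tb), root_id)
  F <- c(a$F, Fb)
  F[[root_id]] <- F_r

  sums <- list(PS = a$sums$PS + b$sums$PS + P_r * s_r,
               S = a$sums$S + b$sums$S + s_r,
               n = a$sums$n + b$sums$n + 1L)
  sim <- switch(config$node_aggregation,
                mean = sums$PS / sums$n,
                `sum-normalized` = if (sums$S == 0) 0 else sums$PS / sums$S)
  list(tree = tree, F = F, sums = sums, sim = sim, P_root = P_r)
}

# Rename node IDs per `map` (fuzzy merges can bring two copies of a gene's
# subtree into one tree; node IDs must stay unique within the tree).
rename_nodes <- function(tree, map) {
  new_id <- function(v) unname(map[v])
  children <- setNames(lapply(tree$children, new_id),
                       new_id(names(tree$children)))
  genes <- setNames(unname(tree$genes), new_id(names(tree$genes)))
  module_tree(children, genes, root = new_id(tree$root))
}

as_cluster <- function(am, tax, config) {
  det <- hms_sums(am, tax, config)
  list(tree = am$tree, F = am$F, sums = det,
       leaves = sort(unname(am$tree$genes)))
}

hms_sums <- function(am, tax, config) {
  PS <- 0; S <- 0; n <- 0L
  for (v in internal_nodes(am$tree)) {
    kids <- am$tree$children[[v]]
    P <- if (length(kids) == 1L) 1 else penalization(am$F[[v]], am$F[kids], tax, config)
    s <- node_sigma(am$F[[v]], tax, config)
    PS <- PS + P * s; S <- S + s; n <- n + 1L
  }
  list(PS = PS, S = S, n = n)
}

#' TAFI: taxonomy-driven agglomerative fuzzy reconstruction
#'
#' Reconstructs a hierarchical gene module from a flat "bag of genes", given
#' each gene's functional annotation in a hierarchical taxonomy. Like
#' agglomerative hierarchical clustering, TAFI starts from singleton
#' clusters and merges bottom-up, with the hypothetical-merge HMS as the
#' similarity; unlike classic AHC it merges, at each iteration, *every*
#' cluster pair whose similarity reaches `alpha * S_max` (with `S_max` the
#' iteration's best similarity). A cluster joining several merges appears as
#' a subtree in each of them, so multi-functional genes can end up in
#' several subtrees of the result — the fuzziness. A merge whose leaf
#' multiset has already been formed is pruned. Merging stops when `S_max`
#' falls below `beta` or a single cluster remains; if stopping fires early
#' the result is a forest.
#'
#' @param genes character vector of gene IDs (the bag of genes).
#' @param annotations named list mapping gene IDs to term-ID vectors.
#' @param tax a [taxonomy].
#' @param alpha merging factor in `(0, 1]`; `alpha = 1` reduces TAFI to
#'   classic best-pair AHC (no fuzziness) when similarities are tie-free.
#' @param beta stopping criterion in `[0, 1]`: merging stops once the best
#'   inter-cluster similarity drops below it.
#' @param config a [scoring_config].
#' @param unannotated policy for genes without annotation, see
#'   [annotate_module].
#' @param force_single_root if `TRUE`, any remaining clusters are joined
#'   under a virtual root so the result is a single tree.
#' @return an object of class `"tafi"` with components `forest` (list of
#'   [annotate_module] results), `history` (per-iteration `S_max` and merge
#'   counts), and the parameters used.
#' @export
tafi <- function(genes, annotations, tax, alpha = 0.9, beta = 0.1,
                 config = scoring_config(),
                 unannotated = c("error", "root"),
                 force_single_root = FALSE) {
  if (length(genes) < 1L) stop("empty gene set")
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (!(beta >= 0 && beta <= 1)) stop("beta must be in [0, 1]")
  unannotated <- match.arg(unannotated)
  genes <- unique(genes)

  clusters <- list()
  for (g in sort(genes)) {
    am <- annotate_module(leaf_tree(g), annotations, tax,
                          unannotated = unannotated)
    clusters[[g]] <- as_cluster(am, tax, config)
  }
  registry <- new.env(parent = emptyenv())
  for (cl in clusters) assign(leaf_key(cl$tree), TRUE, envir = registry)

  sim_cache <- new.env(parent = emptyenv())
  next_node <- 1L
  history <- list()
  iter <- 0L

  repeat {
    if (length(clusters) <= 1L) break
    ids <- names(clusters)
    pairs <- utils::combn(ids, 2L)
    # only executable merges compete for S_max: gene-disjoint pairs (a gene
    # occurs once per tree) whose union has not been formed before
    executable <- vapply(seq_len(ncol(pairs)), function(j) {
      la <- clusters[[pairs[1L, j]]]$leaves
      lb <- clusters[[pairs[2L, j]]]$leaves
      !any(la %in% lb) &&
        is.null(registry[[paste(sort(c(la, lb)), collapse = "\r")]])
    }, logical(1))
    pairs <- pairs[, executable, drop = FALSE]
    if (ncol(pairs) == 0L) break
    sims <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      key <- paste0(pairs[1L, j], "\r", pairs[2L, j])
      hit <- sim_cache[[key]]
      if (is.null(hit)) {
        hit <- cluster_similarity(clusters[[pairs[1L, j]]],
                                  clusters[[pairs[2L, j]]], tax, config)
        assign(key, hit, envir = sim_cache)
      }
      sims[j] <- hit
    }
    S_max <- max(sims)
    iter <- iter + 1L
    if (S_max < beta) {
      history[[iter]] <- data.frame(iteration = iter, S_max = S_max,
                                    n_merges = 0L, n_active = length(clusters))
      break
    }

    admitted <- which(sims >= alpha * S_max - 1e-12)
    mkey <- vapply(admitted, function(j) {
      paste(sort(c(clusters[[pairs[1L, j]]]$leaves,
                   clusters[[pairs[2L, j]]]$leaves)), collapse = "\r")
    }, character(1))
    ord <- order(-sims[admitted], mkey)
    admitted <- admitted[ord]
    mkey <- mkey[ord]
    if (alpha == 1) {            # classic non-fuzzy AHC: single best merge
      admitted <- admitted[1L]
      mkey <- mkey[1L]
    }

    used <- character(0)
    born <- list()
    for (idx in seq_along(admitted)) {
      j <- admitted[idx]
      if (!is.null(registry[[mkey[idx]]])) next
      ia <- pairs[1L, j]; ib <- pairs[2L, j]
      root_id <- sprintf(".N%d", next_node); next_node <- next_node + 1L
      m <- merge_annotated(clusters[[ia]], clusters[[ib]], tax, config, root_id)
      assign(mkey[idx], TRUE, envir = registry)
      born[[root_id]] <- list(tree = m$tree, F = m$F, sums = m$sums,
                              leaves = sort(unname(m$tree$genes)))
      used <- union(used, c(ia, ib))
    }
    history[[iter]] <- data.frame(iteration = iter, S_max = S_max,
                                  n_merges = length(born),
                                  n_active = length(clusters))
    if (length(born) == 0L) break   # every admitted merge pruned
    clusters <- c(clusters[setdiff(ids, used)], born)
  }

  if (force_single_root && length(clusters) > 1L) {
    merged <- Reduce(function(a, b) {
      root_id <- sprintf(".N%d", next_node); next_node <<- next_node + 1L
      m <- merge_annotated(a, b, tax, config, root_id)
      list(tree = m$tree, F = m$F, sums = m$sums)
    }, clusters)
    clusters <- setNames(list(merged), merged$tree$root)
  }

  forest <- lapply(unname(clusters), function(cl) {
    structure(list(tree = cl$tree, F = cl$F), class = "annotated_module")
  })
  structure(list(forest = forest,
                 history = if (length(history)) do.call(rbind, history)
                           else data.frame(iteration = integer(0), S_max = numeric(0),
                                           n_merges = integer(0), n_active = integer(0)),
                 alpha = alpha, beta = beta, config = config,
                 genes = sort(genes), call = match.call()),
            class = "tafi")
}

leaf_key <- function(tree) paste(sort(subtree_genes(tree)), collapse = "\r")

#' @export
print.tafi <- function(x, ...) {
  cat("TAFI hierarchical module reconstruction\n")
  cat(sprintf("  %d genes, alpha = %g, beta = %g, theta = %g\n",
              length(x$genes), x$alpha, x$beta, x$config$theta))
  cat(sprintf("  forest of %d tree(s); %d merge iteration(s)\n",
              length(x$forest), nrow(x$history)))
  for (i in seq_along(x$forest)) {
    cat(sprintf("  tree %d (%d leaves): %s\n", i,
                length(x$forest[[i]]$tree$genes), to_newick(x$forest[[i]]$tree)))
  }
  invisible(x)
}

#' @export
summary.tafi <- function(object, tax = NULL, ...) {
  cat("TAFI reconstruction summary\n")
  cat(sprintf("  genes: %d   trees: %d\n", length(object$genes),
              length(object$forest)))
  dup <- table(unlist(lapply(object$forest, function(am) unique(unname(am$tree$genes)))))
  fuzzy <- names(dup)[dup > 1L]
  cat(sprintf("  fuzzy (multi-tree) genes: %s\n",
              if (length(fuzzy)) paste(fuzzy, collapse = ", ") else "none"))
  if (nrow(object$history)) {
    cat("  S_max trace:", paste(sprintf("%.3f", object$history$S_max),
                                collapse = " "), "\n")
  }
  if (!is.null(tax)) {
    cat(sprintf("  forest HMS: %.4f\n", hms(object$forest, tax, object$config)))
  }
  invisible(object)
}

#' @export
plot.tafi <- function(x, ...) {
  big <- x$forest[lengths(lapply(x$forest, function(am) am$tree$genes)) >= 2L]
  if (length(big) == 0L) stop("nothing to plot: all clusters are singletons")
  op <- graphics::par(mfrow = c(1, length(big)))
  on.exit(graphics::par(op))
  for (am in big) {
    ph <- ape::read.tree(text = to_newick(am$tree))
    plot(ph, ...)
  }
  invisible(x)
}

#' Cut a reconstructed hierarchy into k gene sets
#'
#' Removes the highest merges (greatest-height internal nodes first, ties
#' broken by smaller subtree, then by leaf set) until exactly `k` connected
#' subtrees remain, and returns their leaf gene sets. A fuzzy gene may
#' appear in several of the returned sets.
#'
#' @param x a `"tafi"` object, or a list of [module_tree]/annotated modules.
#' @param k number of gene sets to produce; between 1 and the total leaf
#'   count.
#' @return list of `k` character vectors of gene IDs.
#' @export
cut_hierarchy <- function(x, k) {
  trees <- if (inherits(x, "tafi")) {
    lapply(x$forest, `[[`, "tree")
  } else {
    lapply(x, function(t) if (inherits(t, "annotated_module")) t$tree else t)
  }
  n_leaves <- sum(vapply(trees, function(t) length(t$genes), integer(1)))
  if (k < 1L || k > n_leaves) stop("k must be between 1 and the leaf count")

  if (k < length(trees)) stop("forest already has more than k trees")
  while (length(trees) < k) {
    h <- vapply(trees, function(t) max(node_heights(t)), integer(1))
    sz <- vapply(trees, function(t) length(t$genes), integer(1))
    keys <- vapply(trees, leaf_key, character(1))
    splittable <- which(h > 0L)
    pick <- splittable[order(-h[splittable], sz[splittable], keys[splittable])][1L]
    t0 <- trees[[pick]]
    parts <- lapply(t0$children[[t0$root]], extract_subtree, tree = t0)
    trees <- c(trees[-pick], parts)
    if (length(trees) > k) stop("multi-way root: cannot cut to exactly k subtrees")
  }
  lapply(trees, function(t) sort(unique(unname(t$genes))))
}
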