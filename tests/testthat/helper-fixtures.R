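# Shared fixtures and independent oracles, built in code.

# root <- t1 <- t2 <- ... <- tL (a single chain of depth L)
chain_taxonomy <- function(L) {
  ids <- c("r", paste0("t", seq_len(L)))
  taxonomy(data.frame(child = ids[-1], parent = ids[-(L + 1)],
                      stringsAsFactors = FALSE))
}

# root -> a, d ; a -> b, c ; d -> e, f   (two sibling subtrees, depth 2)
toy_taxonomy <- function() {
  taxonomy(data.frame(child = c("a", "d", "b", "c", "e", "f"),
                      parent = c("root", "root", "a", "a", "d", "d"),
                      stringsAsFactors = FALSE))
}

# caterpillar module tree over the given genes
caterpillar_tree <- function(genes) {
  Reduce(function(acc, g) join_trees(list(acc, leaf_tree(g)),
                                     paste0(".n_", g)),
         genes[-1], leaf_tree(genes[1]))
}

# random unrelated annotations: k terms per gene drawn from the taxonomy
random_annotations <- function(genes, tax, k = 3) {
  pool <- setdiff(tax$terms, tax$root)
  ann <- lapply(genes, function(g) {
    reduce_to_specific(sample(pool, min(k, length(pool))), tax)
  })
  names(ann) <- genes
  ann
}

# exhaustive power-set search for a maximum unrelated subset (size only)
oracle_max_unrelated_size <- function(terms, tax) {
  n <- length(terms)
  rel <- matrix(FALSE, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      rel[i, j] <- rel[j, i] <- is_related(terms[i], terms[j], tax)
    }
  }
  best <- 0L
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    sub <- rel[idx, idx, drop = FALSE]
    if (!any(sub)) best <- length(idx)
  }
  best
}

# all root-to-term simple-path lengths by explicit recursive enumeration
oracle_levels <- function(term, tax) {
  paths_up <- function(t) {
    if (t == tax$root) return(0L)
    sort(unique(unlist(lapply(tax$parents[[t]], function(p) paths_up(p) + 1L))))
  }
  paths_up(term)
}

# classic best-pair agglomerative clustering with the hypothetical-merge HMS
# as similarity; ties broken like tafi() documents (lexicographic smallest
# merged leaf set) so tie-free and tied fixtures are both comparable
ahc_oracle <- function(genes, ann, tax, config = scoring_config()) {
  cl <- lapply(sort(genes), function(g) annotate_module(leaf_tree(g), ann, tax))
  names(cl) <- sort(genes)
  n <- 0L
  while (length(cl) > 1L) {
    ids <- names(cl)
    best <- NULL
    for (i in 1:(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      s <- cluster_similarity(cl[[ids[i]]], cl[[ids[j]]], tax, config)
      key <- paste(sort(c(leaf_gene_ids(cl[[ids[i]]]$tree),
                          leaf_gene_ids(cl[[ids[j]]]$tree))), collapse = ",")
      if (is.null(best) || s > best$s + 1e-12 ||
          (abs(s - best$s) <= 1e-12 && key < best$key)) {
        best <- list(s = s, a = ids[i], b = ids[j], key = key)
      }
    }
    n <- n + 1L
    rid <- paste0(".o", n)
    tr <- join_trees(list(cl[[best$a]]$tree, cl[[best$b]]$tree), rid)
    cl[[best$a]] <- NULL; cl[[best$b]] <- NULL
    cl[[rid]] <- annotate_module(tr, ann, tax)
  }
  cl[[1L]]$tree
}

leaf_gene_ids <- function(tree) sort(unname(tree$genes))

# canonical clade representation of a tree (for topology comparison)
clade_keys <- function(tree) {
  walk <- function(v) {
    if (v %in% names(tree$genes)) return(list(genes = unname(tree$genes[v]),
                                              keys = character(0)))
    parts <- lapply(tree$children[[v]], walk)
    genes <- sort(unlist(lapply(parts, `[[`, "genes")))
    keys <- c(unlist(lapply(parts, `[[`, "keys")),
              paste(genes, collapse = ","))
    list(genes = genes, keys = keys)
  }
  sort(walk(tree$root)$keys)
}
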