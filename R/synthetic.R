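#' Specification for the synthetic-data generators
#'
#' Bundles the knobs of the seeded generators that emulate the statistical
#' structure of a functional taxonomy (GO-like rooted tree or DAG) and of
#' curated modular gene sets (pathway/complex-like bags of genes planted in
#' disjoint taxonomy subtrees, optionally with multi-functional genes shared
#' between modules and with annotation noise).
#'
#' @param seed integer RNG seed; generated output is deterministic given it.
#' @param depth taxonomy depth `L >= 2` (every generated taxonomy reaches
#'   exactly this depth).
#' @param branching integer range `c(min, max)` of children per expanded
#'   term, both `>= 1`.
#' @param max_width cap on how many terms per level are expanded further
#'   (keeps deep taxonomies from exploding).
#' @param dag_extra_parent_prob probability that a term at level 2 or deeper
#'   receives one extra parent from a shallower level, turning the tree into
#'   a DAG; never creates cycles and never deepens the taxonomy.
#' @param n_modules number of planted modules `m`.
#' @param genes_per_module genes per planted module.
#' @param terms_per_gene integer range of annotation terms drawn per gene.
#' @param multi_function_prob probability a gene is multi-functional: it is
#'   additionally annotated from a second module's subtree and becomes a
#'   member of both reference sets.
#' @param annotation_noise probability that each drawn term is replaced by a
#'   uniformly random taxonomy term.
#' @return an object of class `"generator_spec"`.
#' @export
generator_spec <- function(seed = 1L, depth = 5L, branching = c(3L, 4L),
                           max_width = 50L,
                           dag_extra_parent_prob = 0,
                           n_modules = 3L, genes_per_module = 8L,
                           terms_per_gene = c(1L, 3L),
                           multi_function_prob = 0,
                           annotation_noise = 0) {
  stopifnot(depth >= 2L, length(branching) == 2L, branching[1L] >= 1L,
            branching[2L] >= branching[1L],
            dag_extra_parent_prob >= 0, dag_extra_parent_prob <= 1,
            multi_function_prob >= 0, multi_function_prob <= 1,
            annotation_noise >= 0, annotation_noise <= 1,
            n_modules >= 1L, genes_per_module >= 1L,
            terms_per_gene[1L] >= 1L)
  structure(as.list(environment()), class = "generator_spec")
}

# sample() treats a length-1 vector as 1:n; this keeps degenerate ranges safe
sample_range <- function(range) {
  if (range[1L] == range[2L]) range[1L] else sample(seq(range[1L], range[2L]), 1L)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random rooted taxonomy
#'
#' Builds a tree level by level (children counts drawn from the branching
#' range, the frontier capped at `max_width`, one lineage forced down to
#' depth `L`) and then, with probability `dag_extra_parent_prob` per
#' eligible term, adds an extra parent from a strictly shallower level —
#' producing a DAG with multi-level terms while keeping the depth at `L`.
#'
#' @param spec a [generator_spec].
#' @return a [taxonomy].
#' @export
generate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    counter <- 0L
    new_term <- function() {
      counter <<- counter + 1L
      sprintf("T%05d", counter)
    }
    root <- "T00000"
    tree_level <- c(T00000 = 0L)
    child <- character(0); parent <- character(0)
    frontier <- root
    for (l in seq_len(spec$depth)) {
      if (length(frontier) > spec$max_width) {
        expand <- sort(sample(frontier, spec$max_width))
      } else expand <- frontier
      nxt <- character(0)
      for (p in expand) {
        nk <- sample_range(spec$branching)
        for (i in seq_len(nk)) {
          v <- new_term()
          child <- c(child, v); parent <- c(parent, p)
          tree_level[[v]] <- l
          nxt <- c(nxt, v)
        }
      }
      if (length(nxt) == 0L) stop("infeasible branching: frontier died out")
      frontier <- nxt
    }
    # extra parents: candidate parents sit at strictly shallower tree levels,
    # so no cycle can form and no root-to-term path can exceed L
    if (spec$dag_extra_parent_prob > 0) {
      for (v in names(tree_level)[tree_level >= 2L]) {
        if (stats::runif(1L) < spec$dag_extra_parent_prob) {
          cand <- setdiff(names(tree_level)[tree_level < tree_level[[v]]],
                          c(v, parent[child == v]))
          if (length(cand)) {
            p2 <- if (length(cand) == 1L) cand else sample(cand, 1L)
            child <- c(child, v); parent <- c(parent, p2)
          }
        }
      }
    }
    taxonomy(data.frame(child = child, parent = parent,
                        stringsAsFactors = FALSE))
  })
}

#' Plant modular gene sets in a taxonomy
#'
#' Picks `m` disjoint subtrees of depth at least 2, generates
#' `genes_per_module` genes per module annotated with unrelated term sets
#' drawn from their module's subtree, optionally makes genes
#' multi-functional (annotated from, and member of, a second module), and
#' finally applies annotation noise.
#'
#' @param spec a [generator_spec].
#' @param tax a [taxonomy], typically from [generate_taxonomy].
#' @return list with `annotations` (named list gene -> term set), `modules`
#'   (list of `m` reference gene sets), `anchors` (the subtree root terms)
#'   and `seed`.
#' @export
generate_planted_modules <- function(spec, tax) {
  stopifnot(inherits(spec, "generator_spec"), inherits(tax, "taxonomy"))
  with_seed(spec$seed + 1L, {
    anchors <- disjoint_anchor_terms(tax, spec$n_modules)
    # each module carries a shared core of maximally deep terms of its
    # subtree — the way the members of one complex or pathway are annotated
    # with the same specific terms; heterogeneity within a module is
    # introduced by annotation_noise, not by the clean planting
    cores <- lapply(anchors, function(a) {
      d <- setdiff(descendant_terms(tax, a), a)
      deepest <- max(vapply(tax$levels[d], max, integer(1)))
      pool <- d[vapply(tax$levels[d], max, integer(1)) == deepest]
      k <- min(sample_range(spec$terms_per_gene), length(pool))
      core <- if (length(pool) == 1L) pool else sort(sample(pool, k))
      reduce_to_specific(core, tax)
    })
    m <- spec$n_modules
    annotations <- list()
    modules <- rep(list(character(0)), m)
    names(modules) <- paste0("module", seq_len(m))
    all_terms <- setdiff(tax$terms, tax$root)
    for (i in seq_len(m)) {
      for (j in seq_len(spec$genes_per_module)) {
        g <- sprintf("g%02d_%02d", i, j)
        terms <- cores[[i]]
        modules[[i]] <- c(modules[[i]], g)
        if (spec$multi_function_prob > 0 &&
            stats::runif(1L) < spec$multi_function_prob && m > 1L) {
          other <- if (i == m) 1L else i + 1L
          terms <- c(terms, cores[[other]])
          modules[[other]] <- c(modules[[other]], g)
        }
        if (spec$annotation_noise > 0) {
          flip <- stats::runif(length(terms)) < spec$annotation_noise
          if (any(flip)) {
            terms[flip] <- sample(all_terms, sum(flip), replace = TRUE)
          }
        }
        annotations[[g]] <- reduce_to_specific(unique(terms), tax)
      }
    }
    list(annotations = annotations, modules = modules,
         anchors = anchors, cores = cores, seed = spec$seed)
  })
}

descendant_terms <- function(tax, term) {
  out <- term
  frontier <- term
  while (length(frontier)) {
    frontier <- setdiff(unique(unlist(tax$children[frontier], use.names = FALSE)), out)
    out <- c(out, frontier)
  }
  sort(out)
}

# m terms, as shallow and populous as possible, whose descendant sets are
# pairwise disjoint and reach at least 2 levels further down.
disjoint_anchor_terms <- function(tax, m) {
  cands <- setdiff(tax$terms, tax$root)
  lev <- vapply(tax$levels[cands], min, integer(1))
  desc <- lapply(cands, descendant_terms, tax = tax)
  reach <- vapply(seq_along(cands), function(i) {
    max(vapply(tax$levels[desc[[i]]], max, integer(1)))
  }, integer(1))
  deep <- reach >= lev + 2L
  # prefer subtrees reaching the full taxonomy depth: their deepest terms
  # are maximally specific, which keeps planted modules comparable
  ord <- order(reach < tax$depth, lev, -lengths(desc), cands)
  chosen <- integer(0)
  used <- character(0)
  for (i in ord) {
    if (!deep[i]) next
    if (any(desc[[i]] %in% used)) next
    chosen <- c(chosen, i)
    used <- c(used, desc[[i]])
    if (length(chosen) == m) break
  }
  if (length(chosen) < m) {
    stop("taxonomy does not contain ", m, " disjoint subtrees of depth >= 2")
  }
  cands[sort(chosen)]
}
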