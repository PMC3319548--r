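#' Hierarchical taxonomies of functional terms
#'
#' A taxonomy is a rooted directed tree or DAG whose nodes are functional
#' terms (e.g. Gene Ontology terms); edges point from a parent (more general)
#' term to a child (more specific) term. Exactly one node, the root, has no
#' parent. In a DAG a term can be reached from the root along paths of
#' different lengths, so it occurs at a *set* of levels; the taxonomy depth
#' `L` is the largest level of any term.
#'
#' @name taxonomy
#' @keywords internal
NULL

#' Build a taxonomy from a child--parent edge table
#'
#' @param edges two-column data.frame (or matrix) with child term IDs in the
#'   first column and parent term IDs in the second. Term IDs are opaque
#'   case-sensitive strings.
#' @param virtual_root if `TRUE` and several terms lack a parent, a synthetic
#'   root (`"VIRTUAL:ROOT"`) is added above them instead of failing.
#'
#' @return an object of class `"taxonomy"` with components `terms`, `root`,
#'   `parents`, `children`, `levels` (per-term sorted integer vector of
#'   occurrence levels), `depth` (the maximum level `L`) and a memoized
#'   ancestor-closure table.
#' @export
taxonomy <- function(edges, virtual_root = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("'edges' needs child and parent columns")
  child <- as.character(edges[[1L]])
  parent <- as.character(edges[[2L]])
  keep <- !(is.na(child) | is.na(parent) | child == "" | parent == "")
  child <- child[keep]; parent <- parent[keep]
  if (any(child == parent)) {
    stop("cycle detected: self edge ", child[child == parent][1L])
  }
  dup <- duplicated(paste0(child, "\r", parent))
  child <- child[!dup]; parent <- parent[!dup]
  terms <- sort(unique(c(child, parent)))
  roots <- setdiff(terms, child)
  if (length(roots) == 0L) stop("cycle detected: no term without a parent")
  if (length(roots) > 1L) {
    if (!virtual_root) {
      stop("multiple parentless terms (", paste(roots, collapse = ", "),
           "); set virtual_root = TRUE to join them under a synthetic root")
    }
    vr <- "VIRTUAL:ROOT"
    child <- c(child, roots)
    parent <- c(parent, rep(vr, length(roots)))
    terms <- sort(c(terms, vr))
    roots <- vr
  }
  parents <- split(parent, factor(child, levels = terms))
  children <- split(child, factor(parent, levels = terms))
  parents <- lapply(parents, sort)
  children <- lapply(children, sort)

  # Kahn topological order; leftovers expose a cycle.
  indeg <- lengths(parents)
  queue <- names(indeg)[indeg == 0L]
  topo <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    topo <- c(topo, v)
    for (c0 in children[[v]]) {
      indeg[[c0]] <- indeg[[c0]] - 1L
      if (indeg[[c0]] == 0L) queue <- c(queue, c0)
    }
  }
  if (length(topo) < length(terms)) {
    bad <- setdiff(terms, topo)[1L]
    stop("cycle detected involving edge ", bad, " -> ",
         intersect(parents[[bad]], setdiff(terms, topo))[1L])
  }

  # All root-to-term path lengths: levels(v) = union over parents of levels+1.
  levels <- vector("list", length(terms)); names(levels) <- terms
  levels[[roots]] <- 0L
  for (v in topo) {
    if (v == roots) next
    lv <- unlist(lapply(parents[[v]], function(p) levels[[p]] + 1L))
    levels[[v]] <- sort(unique(lv))
  }
  depth <- max(unlist(levels))
  if (depth < 1L) stop("taxonomy must contain at least one non-root term")

  anc <- vector("list", length(terms)); names(anc) <- terms
  for (v in topo) {
    anc[[v]] <- sort(unique(c(v, unlist(anc[parents[[v]]], use.names = FALSE))))
  }

  sigma <- lapply(c(mean = mean, min = min, max = max), function(f) {
    vapply(levels, function(lv) f(lv / depth), numeric(1))
  })

  structure(
    list(terms = terms, root = roots, parents = parents, children = children,
         levels = levels, depth = depth, ancestors = anc, sigma = sigma,
         .dist_cache = new.env(parent = emptyenv())),
    class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("Hierarchical taxonomy of functional terms\n")
  cat("  terms:", length(x$terms), "  root:", x$root,
      "  depth L:", x$depth, "\n")
  multi <- sum(lengths(x$levels) > 1L)
  cat("  structure:", if (multi) "DAG" else "tree",
      if (multi) sprintf("(%d multi-level terms)", multi) else "", "\n")
  invisible(x)
}

stopifnot_term <- function(term, tax) {
  miss <- setdiff(term, tax$terms)
  if (length(miss)) stop("unknown term(s): ", paste(miss, collapse = ", "))
}

#' Level specificity score
#'
#' The specificity attached to a taxonomy level: `zeta(l) = l / L`, zero at
#' the root and one at the deepest level. Vectorized over `level`.
#'
#' @param level integer level(s), `0 <= level <= L`.
#' @param L taxonomy depth, `L >= 1`.
#' @return numeric in `[0, 1]`.
#' @export
level_specificity <- function(level, L) {
  if (L < 1L) stop("L must be >= 1")
  if (any(level < 0L) || any(level > L)) stop("level must lie in [0, L]")
  level / L
}

#' Functional term specificity score
#'
#' Aggregates the level specificity over the levels at which a term occurs
#' (several levels are possible in a DAG). The root always scores 0; a term
#' occurring only at the deepest level scores 1.
#'
#' @param term term ID(s).
#' @param tax a [taxonomy].
#' @param aggregate how to combine level specificities when a term occurs at
#'   several levels.
#' @return numeric vector in `[0, 1]`, one value per term.
#' @export
term_specificity <- function(term, tax, aggregate = c("mean", "min", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot_term(term, tax)
  tax$sigma[[aggregate]][term]
}

#' Are two terms related (ancestor/descendant)?
#'
#' Two terms are related when a directed path joins them in either direction;
#' a term is related to itself by convention.
#'
#' @inheritParams term_specificity
#' @param a,b term IDs.
#' @return logical.
#' @export
is_related <- function(a, b, tax) {
  stopifnot_term(c(a, b), tax)
  a == b || a %in% tax$ancestors[[b]] || b %in% tax$ancestors[[a]]
}

#' Ancestor closure of a term set
#'
#' Every term lying on any simple path from a member of `terms` to the root,
#' plus the members themselves; always contains the root.
#'
#' @inheritParams term_specificity
#' @param terms character vector of term IDs.
#' @return sorted character vector of term IDs.
#' @export
ancestor_term_set <- function(terms, tax) {
  stopifnot_term(terms, tax)
  sort(unique(unlist(tax$ancestors[terms], use.names = FALSE)))
}

#' Shortest-path distance between two related terms
#'
#' Length of the shortest simple directed path between the pair, in whichever
#' direction the ancestor relation holds; `Inf` for unrelated terms and 0 for
#' equal ones. Results are memoized per taxonomy.
#'
#' @inheritParams is_related
#' @return non-negative integer, or `Inf`.
#' @export
term_distance <- function(a, b, tax) {
  stopifnot_term(c(a, b), tax)
  term_distance_fast(a, b, tax)
}

term_distance_fast <- function(a, b, tax) {
  if (a == b) return(0L)
  key <- if (a < b) paste0(a, "\r", b) else paste0(b, "\r", a)
  hit <- tax$.dist_cache[[key]]
  if (!is.null(hit)) return(hit)
  d <- if (a %in% tax$ancestors[[b]]) {
    bfs_down(a, b, tax)
  } else if (b %in% tax$ancestors[[a]]) {
    bfs_down(b, a, tax)
  } else {
    Inf
  }
  assign(key, d, envir = tax$.dist_cache)
  d
}

# BFS along parent->child edges from an ancestor to a descendant.
bfs_down <- function(from, to, tax) {
  frontier <- from
  d <- 0L
  seen <- character(0)
  while (length(frontier)) {
    if (to %in% frontier) return(d)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(tax$children[frontier], use.names = FALSE)), seen)
    d <- d + 1L
  }
  Inf  # unreachable under a broken closure; defensive
}

#' Keep only the most specific terms of a set
#'
#' Drops every term that is a strict ancestor of another member, yielding an
#' unrelated (pairwise non-ancestral) set — the canonical form of a gene
#' annotation. Real annotation files routinely list a term together with its
#' ancestors; this removes that redundancy.
#'
#' @inheritParams ancestor_term_set
#' @return sorted character vector forming an unrelated set.
#' @export
reduce_to_specific <- function(terms, tax) {
  terms <- unique(terms)
  stopifnot_term(terms, tax)
  if (length(terms) <= 1L) return(terms)
  # a term is kept unless it is a strict ancestor of another member
  strict_anc <- unique(unlist(lapply(terms, function(s)
    setdiff(tax$ancestors[[s]], s)), use.names = FALSE))
  sort(setdiff(terms, strict_anc))
}

#' Is a term set unrelated (an antichain)?
#'
#' @inheritParams ancestor_term_set
#' @return logical.
#' @export
is_unrelated_set <- function(terms, tax) {
  terms <- unique(terms)
  if (length(terms) <= 1L) return(TRUE)
  for (i in seq_len(length(terms) - 1L)) {
    for (j in (i + 1L):length(terms)) {
      if (is_related(terms[i], terms[j], tax)) return(FALSE)
    }
  }
  TRUE
}

#' Maximum-cardinality unrelated subset
#'
#' Exact maximum antichain of a candidate term set under the taxonomy's
#' ancestor order, found by branch and bound. Ties in cardinality are broken
#' deterministically: larger summed term specificity first, then the
#' lexicographically smallest sorted ID vector, so annotation is reproducible.
#'
#' @inheritParams ancestor_term_set
#' @return sorted character vector; an unrelated set of maximum size.
#' @export
max_unrelated_subset <- function(terms, tax) {
  terms <- unique(terms)
  if (length(terms) == 0L) stop("empty candidate set")
  stopifnot_term(terms, tax)
  n <- length(terms)
  if (n == 1L) return(terms)
  sig <- unname(tax$sigma$mean[terms])
  ord <- order(-sig, terms)
  terms <- terms[ord]; sig <- sig[ord]
  anc <- tax$ancestors
  rel <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    ai <- anc[[terms[i]]]
    for (j in (i + 1L):n) {
      rel[i, j] <- rel[j, i] <-
        terms[j] %in% ai || terms[i] %in% anc[[terms[j]]]
    }
  }
  if (!any(rel)) return(sort(terms))
  best <- list(size = 0L, sig = -Inf, ids = character(0))
  suffix_sig <- rev(cumsum(rev(sig)))

  recurse <- function(i, chosen, chosen_sig) {
    if (i > n) {
      size <- length(chosen)
      ids <- sort(terms[chosen])
      if (size > best$size ||
          (size == best$size && chosen_sig > best$sig + 1e-12) ||
          (size == best$size && abs(chosen_sig - best$sig) <= 1e-12 &&
           paste(ids, collapse = "\r") < paste(best$ids, collapse = "\r"))) {
        best <<- list(size = size, sig = chosen_sig, ids = ids)
      }
      return(invisible(NULL))
    }
    remaining <- n - i + 1L
    if (length(chosen) + remaining < best$size) return(invisible(NULL))
    if (length(chosen) + remaining == best$size &&
        chosen_sig + suffix_sig[i] < best$sig - 1e-12) return(invisible(NULL))
    if (!any(rel[i, chosen])) recurse(i + 1L, c(chosen, i), chosen_sig + sig[i])
    recurse(i + 1L, chosen, chosen_sig)
  }
  recurse(1L, integer(0), 0)
  best$ids
}
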