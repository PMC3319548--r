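#' Contingency table between reference modules and predicted subtrees
#'
#' Cell (i, j) counts the genes shared by reference set i and predicted set
#' j. Columns are reordered so that the matched diagonal is maximal: by
#' exhaustive search over column permutations for `k <= 8` (exact
#' maximum-weight assignment at the sizes this analysis is run at), greedily
#' beyond — or always greedily with `method = "greedy"`. A gene belonging to
#' several predicted sets (fuzzy membership) is counted in each of them.
#' In the ideal case the table is diagonal: every reference module maps
#' one-to-one onto a predicted subtree.
#'
#' @param reference,predicted lists of `k` character vectors of gene IDs.
#' @param method column-to-row assignment strategy.
#' @return an object of class `"contingency_table"`: the k-by-k integer
#'   matrix with rows = reference sets, columns = matched predicted sets.
#' @export
build_contingency <- function(reference, predicted,
                              method = c("optimal", "greedy")) {
  method <- match.arg(method)
  k <- length(reference)
  if (length(predicted) != k) stop("reference and predicted must have equal length")
  if (k < 1L) stop("need at least one set")
  counts <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      counts[i, j] <- length(intersect(unique(reference[[i]]),
                                       unique(predicted[[j]])))
    }
  }
  perm <- if (method == "optimal" && k <= 8L) {
    best_permutation(counts)
  } else {
    greedy_permutation(counts)
  }
  out <- counts[, perm, drop = FALSE]
  rn <- if (!is.null(names(reference))) names(reference) else paste0("ref", seq_len(k))
  cn <- if (!is.null(names(predicted))) names(predicted) else paste0("pred", seq_len(k))
  dimnames(out) <- list(reference = rn, predicted = cn[perm])
  structure(out, class = c("contingency_table", class(out)))
}

best_permutation <- function(counts) {
  k <- nrow(counts)
  perms <- all_permutations(k)
  diag_sum <- vapply(seq_len(nrow(perms)), function(r) {
    sum(counts[cbind(seq_len(k), perms[r, ])])
  }, numeric(1))
  perms[which.max(diag_sum), ]
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(first) {
    rest <- sub
    rest[rest >= first] <- rest[rest >= first] + 1L
    cbind(first, rest, deparse.level = 0L)
  }))
}

greedy_permutation <- function(counts) {
  k <- nrow(counts)
  perm <- integer(k)
  free_cols <- seq_len(k)
  ord <- order(-apply(counts, 1L, max))
  for (i in ord) {
    j <- free_cols[which.max(counts[i, free_cols])]
    perm[i] <- j
    free_cols <- setdiff(free_cols, j)
  }
  perm
}

as_count_matrix <- function(table) {
  m <- unclass(table)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("need a square count matrix")
  if (any(m < 0)) stop("counts must be non-negative")
  if (sum(m) == 0) stop("all-zero contingency table")
  m
}

#' Heidke skill score
#'
#' Chance-corrected agreement `(PC - E) / (1 - E)` with proportion correct
#' `PC` (diagonal mass) and expected agreement `E` from both marginals.
#' 1 for a perfect diagonal, 0 when agreement equals marginal chance.
#'
#' @param table a [build_contingency] result or square count matrix.
#' @return numeric, at most 1.
#' @export
heidke_score <- function(table) {
  m <- as_count_matrix(table)
  n <- sum(m)
  pc <- sum(diag(m)) / n
  e <- sum(rowSums(m) * colSums(m)) / n^2
  if (e == 1) return(0)  # single-cell table: no skill measurable
  (pc - e) / (1 - e)
}

#' Peirce skill score
#'
#' Like the Heidke score, but normalized by the reference (row) marginals
#' only: `(PC - E) / (1 - E')` with `E' = sum(p_i^2)` over reference
#' fractions. 1 for a perfect diagonal, 0 for uniform agreement.
#'
#' @inheritParams heidke_score
#' @return numeric, at most 1.
#' @export
peirce_score <- function(table) {
  m <- as_count_matrix(table)
  n <- sum(m)
  pc <- sum(diag(m)) / n
  e <- sum(rowSums(m) * colSums(m)) / n^2
  e_ref <- sum((rowSums(m) / n)^2)
  if (e_ref == 1) return(0)
  (pc - e) / (1 - e_ref)
}

#' Gerrity skill score
#'
#' The equitable skill score built from the Gerrity weight matrix, which is
#' derived from the reference (row) marginals: correct cells earn positive
#' weights (rarer categories earn more), off-diagonal cells are debited by
#' their category separation. 1 for a perfect diagonal; random or constant
#' predictions score 0 in expectation.
#'
#' @inheritParams heidke_score
#' @return numeric, at most 1.
#' @export
gerrity_score <- function(table) {
  m <- as_count_matrix(table)
  k <- nrow(m)
  if (k < 2L) stop("Gerrity score needs at least 2 categories")
  n <- sum(m)
  p <- rowSums(m) / n
  if (any(p == 0)) stop("empty reference row")
  cum <- cumsum(p)[seq_len(k - 1L)]
  a <- (1 - cum) / cum           # odds of falling above each category split
  b <- 1 / (k - 1)
  s <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) {
      lead <- if (i > 1L) sum(1 / a[seq_len(i - 1L)]) else 0
      tail <- if (j <= k - 1L) sum(a[j:(k - 1L)]) else 0
      s[i, j] <- s[j, i] <- b * (lead - (j - i) + tail)
    }
  }
  sum(m / n * s)
}
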