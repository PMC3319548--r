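#' Read a taxonomy from an OBO file or an edge-list TSV
#'
#' OBO 1.2/1.4 flat files: only `[Term]` stanzas are used; `is_a:` edges are
#' retained (`relationship: part_of` optionally, via `include_part_of`),
#' obsolete terms are dropped, and `alt_id`s are recorded so annotation
#' readers can map them to the primary ID. Edge lists are two-column TSV,
#' child then parent, with an optional `child<TAB>parent` header.
#'
#' @param path file path.
#' @param format `"auto"` detects OBO by the `format-version:`/stanza
#'   syntax.
#' @param namespace optional OBO namespace filter (e.g.
#'   `"biological_process"`).
#' @param include_part_of also keep `part_of` relationship edges.
#' @param virtual_root see [taxonomy].
#' @return a [taxonomy]; OBO inputs carry an `alt_ids` attribute (named
#'   character vector alt -> primary).
#' @export
read_taxonomy <- function(path, format = c("auto", "obo", "edgelist"),
                          namespace = NULL, include_part_of = FALSE,
                          virtual_root = FALSE) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (any(grepl("^\\[Term\\]|^format-version:", lines))) "obo" else "edgelist"
  }
  if (format == "obo") {
    parse_obo(lines, namespace, include_part_of, virtual_root)
  } else {
    body <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (length(parts) && identical(tolower(parts[[1L]][1:2]), c("child", "parent"))) {
      parts <- parts[-1L]
    }
    if (length(parts) == 0L) stop("empty edge list")
    edges <- data.frame(child = vapply(parts, `[`, character(1), 1L),
                        parent = vapply(parts, `[`, character(1), 2L),
                        stringsAsFactors = FALSE)
    taxonomy(edges, virtual_root = virtual_root)
  }
}

parse_obo <- function(lines, namespace, include_part_of, virtual_root) {
  starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]", lines)
  if (length(term_starts) == 0L) stop("no [Term] stanzas found")
  bounds <- c(starts, length(lines) + 1L)
  id <- character(0); ns <- character(0)
  child <- character(0); parent <- character(0)
  alt_from <- character(0); alt_to <- character(0)
  obsolete <- character(0)
  field <- function(stanza, key) {
    hits <- stanza[startsWith(stanza, paste0(key, ":"))]
    trimws(sub("!.*$", "", substring(hits, nchar(key) + 2L)))
  }
  for (s in term_starts) {
    end <- min(bounds[bounds > s]) - 1L
    stanza <- lines[(s + 1L):end]
    tid <- field(stanza, "id")[1L]
    if (is.na(tid) || !nzchar(tid)) next
    if (any(field(stanza, "is_obsolete") == "true")) {
      obsolete <- c(obsolete, tid)
      next
    }
    id <- c(id, tid)
    tns <- field(stanza, "namespace")[1L]
    ns <- c(ns, if (length(tns) && !is.na(tns)) tns else NA_character_)
    for (p in field(stanza, "is_a")) {
      child <- c(child, tid); parent <- c(parent, p)
    }
    if (include_part_of) {
      rels <- field(stanza, "relationship")
      po <- rels[startsWith(rels, "part_of")]
      for (p in trimws(sub("^part_of", "", po))) {
        child <- c(child, tid); parent <- c(parent, p)
      }
    }
    for (a in field(stanza, "alt_id")) {
      alt_from <- c(alt_from, a); alt_to <- c(alt_to, tid)
    }
  }
  names(ns) <- id
  if (!is.null(namespace)) {
    keep <- id[!is.na(ns) & ns == namespace]
    sel <- child %in% keep & parent %in% keep
    child <- child[sel]; parent <- parent[sel]
  }
  keep_edge <- !(child %in% obsolete) & !(parent %in% obsolete)
  child <- child[keep_edge]; parent <- parent[keep_edge]
  if (length(child) == 0L) stop("no usable is_a edges after filtering")
  tax <- taxonomy(data.frame(child = child, parent = parent,
                             stringsAsFactors = FALSE),
                  virtual_root = virtual_root)
  attr(tax, "alt_ids") <- setNames(alt_to, alt_from)[alt_to %in% tax$terms]
  tax
}

#' Write a taxonomy as a minimal OBO file
#'
#' @param tax a [taxonomy].
#' @param path output path.
#' @param header extra header lines (e.g. a seed record).
#' @export
write_taxonomy_obo <- function(tax, path, header = character(0)) {
  out <- c("format-version: 1.2", header, "")
  for (t in tax$terms) {
    out <- c(out, "[Term]", paste0("id: ", t), paste0("name: ", t),
             paste0("is_a: ", tax$parents[[t]]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read gene annotations from a GAF 2.x or two-column TSV file
#'
#' GAF: comment lines start with `!`; column 2 (DB object ID; column 3, the
#' symbol, with `use_symbol = TRUE`) supplies the gene and column 5 the term
#' ID; rows whose qualifier contains `NOT` are skipped. TSV: two columns,
#' gene then term. Duplicate (gene, term) rows collapse; term IDs absent
#' from the taxonomy are mapped through its `alt_ids` when possible,
#' otherwise skipped with a warning (`strict = TRUE` errors instead). Each
#' gene's term set is reduced to its most specific (unrelated) form.
#'
#' @param path file path.
#' @param tax a [taxonomy].
#' @param format `"auto"` treats files whose data lines have >= 15 columns
#'   or a `!gaf-version` header as GAF.
#' @param use_symbol take the gene symbol column instead of the object ID
#'   (GAF only).
#' @param strict error (rather than warn) on unknown term IDs.
#' @return named list mapping gene IDs to unrelated term sets.
#' @export
read_annotations <- function(path, tax, format = c("auto", "gaf", "tsv"),
                             use_symbol = FALSE, strict = FALSE) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(lines, "!") | startsWith(lines, "#")
  body <- lines[nzchar(lines) & !is_comment]
  if (length(body) == 0L) {
    warning("no annotation rows in ", path)
    return(setNames(list(), character(0)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (format == "auto") {
    format <- if (any(grepl("^!gaf-version", lines)) ||
                  length(parts[[1L]]) >= 15L) "gaf" else "tsv"
  }
  if (format == "gaf") {
    qual <- vapply(parts, `[`, character(1), 4L)
    keep <- !grepl("(^|\\|)NOT(\\||$)", qual)
    gene <- vapply(parts, `[`, character(1), if (use_symbol) 3L else 2L)[keep]
    term <- vapply(parts, `[`, character(1), 5L)[keep]
  } else {
    gene <- vapply(parts, `[`, character(1), 1L)
    term <- vapply(parts, `[`, character(1), 2L)
    if (length(gene) && identical(tolower(c(gene[1L], term[1L])),
                                  c("gene", "term"))) {
      gene <- gene[-1L]; term <- term[-1L]
    }
  }
  alt <- attr(tax, "alt_ids")
  unknown <- !(term %in% tax$terms)
  if (!is.null(alt) && any(unknown)) {
    mapped <- !is.na(alt[term[unknown]])
    term[unknown][mapped] <- alt[term[unknown][mapped]]
    unknown <- !(term %in% tax$terms)
  }
  if (any(unknown)) {
    msg <- paste0(sum(unknown), " annotation row(s) with unknown term IDs (e.g. ",
                  term[unknown][1L], ")")
    if (strict) stop(msg) else warning(msg, "; skipped")
    gene <- gene[!unknown]; term <- term[!unknown]
  }
  if (length(gene) == 0L) return(setNames(list(), character(0)))
  sets <- split(term, gene)
  lapply(sets, function(ts) reduce_to_specific(unique(ts), tax))
}

#' Write annotations as a two-column TSV
#' @param annotations named list gene -> term vector.
#' @param path output path.
#' @param header extra comment lines (prefixed with `#`).
#' @export
write_annotations_tsv <- function(annotations, path, header = character(0)) {
  rows <- unlist(lapply(names(annotations), function(g) {
    paste(g, annotations[[g]], sep = "\t")
  }))
  writeLines(c(if (length(header)) paste0("# ", header), rows), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene IDs, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("no gene sets in ", path)
    return(setNames(list(), character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' Write gene sets as a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read a forest of module trees from a Newick file
#'
#' One tree per line (or several `;`-terminated trees on one line). Leaf
#' labels are gene IDs and must be unique within one tree; internal labels,
#' if present, are kept as node IDs.
#'
#' @param path file path.
#' @return list of [module_tree] objects.
#' @export
read_module_forest <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "")
  chunks <- strsplit(text, ";", fixed = TRUE)[[1L]]
  chunks <- trimws(chunks)
  chunks <- chunks[nzchar(chunks)]
  if (length(chunks) == 0L) stop("no trees in ", path)
  lapply(chunks, function(nwk) {
    if (!grepl("(", nwk, fixed = TRUE)) {      # single-leaf tree: bare label
      return(leaf_tree(gsub("^'|'$", "", nwk)))
    }
    ph <- tryCatch(ape::read.tree(text = paste0(nwk, ";")),
                   error = function(e) stop("malformed Newick near \"",
                                            substr(nwk, 1L, 40L), "\": ",
                                            conditionMessage(e)))
    if (is.null(ph)) stop("malformed Newick near \"", substr(nwk, 1L, 40L), "\"")
    phylo_to_module_tree(ph)
  })
}

phylo_to_module_tree <- function(ph) {
  ntip <- length(ph$tip.label)
  if (anyDuplicated(ph$tip.label)) stop("duplicate leaf labels within one tree")
  nlab <- ph$node.label
  # internal labels become node IDs only when usable as such (unique and
  # distinct from the leaves); annotation dumps often repeat labels
  use_labels <- !is.null(nlab) && !anyNA(nlab) && all(nzchar(nlab)) &&
    !anyDuplicated(nlab) && !any(nlab %in% ph$tip.label)
  node_id <- function(i) {
    if (i <= ntip) return(ph$tip.label[i])
    j <- i - ntip
    if (use_labels) nlab[j] else paste0(".I", j)
  }
  children <- list()
  for (r in seq_len(nrow(ph$edge))) {
    p <- node_id(ph$edge[r, 1L]); c0 <- node_id(ph$edge[r, 2L])
    children[[p]] <- c(children[[p]], c0)
  }
  genes <- setNames(ph$tip.label, ph$tip.label)
  module_tree(children, genes, root = node_id(ntip + 1L))
}

#' Write a forest of (annotated) module trees as Newick
#'
#' For annotated modules the internal labels carry each node's annotation
#' `F(v)`, pipe-joined; a companion TSV with per-node `F(v)` and `P(v)` can
#' be requested.
#'
#' @param forest list of [module_tree] or annotated modules (or a `"tafi"`
#'   object).
#' @param path output path.
#' @param tax,config needed when `node_table` is requested, to compute
#'   `P(v)`.
#' @param node_table optional path for the companion per-node TSV.
#' @export
write_module_forest <- function(forest, path, tax = NULL, config = NULL,
                                node_table = NULL) {
  if (inherits(forest, "tafi")) forest <- forest$forest
  lines <- vapply(forest, function(m) {
    if (inherits(m, "annotated_module")) {
      labs <- vapply(internal_nodes(m$tree), function(v) {
        paste(m$F[[v]], collapse = "|")
      }, character(1))
      to_newick(m$tree, labels = labs)
    } else {
      to_newick(m)
    }
  }, character(1))
  writeLines(lines, path)
  if (!is.null(node_table)) {
    if (is.null(tax)) stop("node_table needs the taxonomy")
    if (is.null(config)) config <- scoring_config()
    rows <- c("tree\tnode\tF\tP")
    for (i in seq_along(forest)) {
      m <- forest[[i]]
      if (!inherits(m, "annotated_module")) next
      for (v in internal_nodes(m$tree)) {
        kids <- m$tree$children[[v]]
        P <- if (length(kids) == 1L) 1 else
          penalization(m$F[[v]], m$F[kids], tax, config)
        rows <- c(rows, paste(i, v, paste(m$F[[v]], collapse = "|"),
                              format(P, digits = 10), sep = "\t"))
      }
    }
    writeLines(rows, node_table)
  }
  invisible(path)
}
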