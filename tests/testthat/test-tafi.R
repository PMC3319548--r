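test_that("a single gene yields a one-leaf forest", {
  tx <- chain_taxonomy(2)
  fit <- tafi("g1", list(g1 = "t2"), tx)
  expect_length(fit$forest, 1)
  expect_equal(leaf_gene_ids(fit$forest[[1]]$tree), "g1")
  expect_error(tafi(character(0), list(), tx), "empty")
})

test_that("cluster similarity is the HMS of the explicitly merged tree", {
  tx <- generate_taxonomy(generator_spec(seed = 5, depth = 5,
                                         branching = c(2L, 3L),
                                         max_width = 16L))
  set.seed(11)
  ann <- random_annotations(c("a", "b", "c"), tx, k = 3)
  A <- annotate_module(join_trees(list(leaf_tree("a"), leaf_tree("b")), "ra"),
                       ann, tx)
  B <- annotate_module(leaf_tree("c"), ann, tx)
  merged <- annotate_module(join_trees(list(A$tree, B$tree), "R"), ann, tx)
  expect_equal(cluster_similarity(A, B, tx), hms(merged, tx))
  # boundary similarities for singleton clusters
  s1 <- cluster_similarity(annotate_module(leaf_tree("x"), list(x = "t2"),
                                           chain_taxonomy(2)),
                           annotate_module(leaf_tree("y"), list(y = "t2"),
                                           chain_taxonomy(2)),
                           chain_taxonomy(2))
  expect_equal(s1, 1)
  tx2 <- toy_taxonomy()
  s0 <- cluster_similarity(annotate_module(leaf_tree("x"), list(x = "b"), tx2),
                           annotate_module(leaf_tree("y"), list(y = "e"), tx2),
                           tx2)
  expect_equal(s0, 0)
})

test_that("alpha = 1 reduces TAFI to classic best-pair agglomeration", {
  set.seed(3)
  for (sd in 1:4) {
    tx <- generate_taxonomy(generator_spec(seed = 100 + sd, depth = 5))
    genes <- sprintf("x%02d", 1:7)
    ann <- random_annotations(genes, tx, k = 3)
    fit <- tafi(genes, ann, tx, alpha = 1, beta = 0)
    expect_length(fit$forest, 1)
    tree <- fit$forest[[1]]$tree
    # single binary tree over each gene exactly once
    expect_equal(leaf_gene_ids(tree), sort(genes))
    expect_true(all(lengths(tree$children) == 2L))
    expect_identical(clade_keys(tree), clade_keys(ahc_oracle(genes, ann, tx)))
  }
})

test_that("a multi-functional gene ends up in several subtrees (fuzziness)", {
  spec <- generator_spec(seed = 3, n_modules = 2, genes_per_module = 4)
  tx <- generate_taxonomy(spec)
  pm <- generate_planted_modules(spec, tx)
  ann <- pm$annotations
  shared <- "g01_04"
  ann[[shared]] <- reduce_to_specific(c(pm$cores[[1]], pm$cores[[2]]), tx)
  fit <- tafi(unique(unlist(pm$modules)), ann, tx, alpha = 0.9, beta = 0.1)
  membership <- lapply(fit$forest, function(am) unique(leaf_gene_ids(am$tree)))
  with_shared <- membership[vapply(membership, function(m) shared %in% m,
                                   logical(1))]
  # the shared gene co-occurs with genes of module 1 in some tree and with
  # genes of module 2 in another
  m1 <- setdiff(pm$modules[[1]], shared)
  m2 <- setdiff(pm$modules[[2]], shared)
  expect_true(any(vapply(with_shared, function(m) any(m1 %in% m), logical(1))))
  expect_true(any(vapply(with_shared, function(m) any(m2 %in% m), logical(1))))
})

test_that("no two trees of a TAFI forest share an identical leaf set", {
  spec <- generator_spec(seed = 9, n_modules = 2, genes_per_module = 4)
  tx <- generate_taxonomy(spec)
  pm <- generate_planted_modules(spec, tx)
  fit <- tafi(unique(unlist(pm$modules)), pm$annotations, tx,
              alpha = 0.85, beta = 0.05)
  keys <- vapply(fit$forest, function(am) {
    paste(sort(unname(am$tree$genes)), collapse = ",")
  }, character(1))
  expect_false(anyDuplicated(keys) > 0)
})

test_that("stopping criterion beta leaves a forest; force_single_root joins it", {
  tx <- toy_taxonomy()
  ann <- list(g1 = "b", g2 = "c", g3 = "e", g4 = "f")
  fit <- tafi(names(ann), ann, tx, alpha = 1, beta = 0.35)
  expect_gt(length(fit$forest), 1)   # the two subtrees never meet above beta
  fit2 <- tafi(names(ann), ann, tx, alpha = 1, beta = 0.35,
               force_single_root = TRUE)
  expect_length(fit2$forest, 1)
  expect_equal(leaf_gene_ids(fit2$forest[[1]]$tree), names(ann))
})

test_that("cut_hierarchy honours its boundary cases and splits top merges first", {
  tx <- toy_taxonomy()
  ann <- list(g1 = "b", g2 = "c", g3 = "e", g4 = "f")
  fit <- tafi(names(ann), ann, tx, alpha = 1, beta = 0)
  expect_length(fit$forest, 1)
  expect_equal(cut_hierarchy(fit, 1)[[1]], names(ann))
  expect_equal(sort(vapply(cut_hierarchy(fit, 4), identity, character(1))),
               names(ann))
  cuts <- cut_hierarchy(fit, 2)
  expect_equal(sort(vapply(cuts, paste, character(1), collapse = ",")),
               c("g1,g2", "g3,g4"))
  expect_error(cut_hierarchy(fit, 5), "between 1 and")
})
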