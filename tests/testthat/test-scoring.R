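test_that("dissimilarity reproduces its anchor values", {
  cfg1 <- scoring_config(theta = 1)
  tx <- chain_taxonomy(2)
  # identical annotations: zero dissimilarity
  expect_equal(dissimilarity("t1", "t1", tx, cfg1), 0)
  # immediate neighbours at theta = 1: exactly one half
  expect_equal(dissimilarity("t1", "t2", tx, cfg1), 0.5)
  # unrelated sets: maximal dissimilarity
  tx2 <- toy_taxonomy()
  expect_equal(dissimilarity("b", "e", tx2, cfg1), 1)
  # distance 15 at theta = 100 gives a penalty that rounds to 13%
  tx15 <- chain_taxonomy(16)
  d <- dissimilarity("t1", "t16", tx15, scoring_config(theta = 100))
  expect_equal(round(100 * d), 13)
})

test_that("penalization factor follows the worked example and variants", {
  tx <- chain_taxonomy(2)
  cfg <- scoring_config(theta = 1)
  # children at dissimilarities 0.5 and 0 give P = 0.5
  expect_equal(penalization("t1", list("t2", "t1"), tx, cfg), 0.5)
  expect_equal(penalization("t1", list("t1", "t1"), tx, cfg), 1)
  expect_error(penalization("t1", list(), tx, cfg), "children")
  # exponential and linear variants at distance 1
  expect_equal(penalization("t1", list("t2"), tx,
                            scoring_config(theta = 2,
                                           penalty_variant = "exponential")),
               exp(-0.5))
  expect_equal(penalization("t1", list("t2"), tx,
                            scoring_config(penalty_variant = "linear")),
               1 - 1 / 2)
  # unrelated child annihilates the reciprocal and exponential penalties
  tx2 <- toy_taxonomy()
  expect_equal(penalization("b", list("e"), tx2, cfg), 0)
})

test_that("HMS hits its boundary cases", {
  tx <- chain_taxonomy(3)
  # two genes sharing one maximally deep term: perfect score
  expect_equal(pair_score("x", "y", list(x = "t3", y = "t3"), tx), 1)
  # genes sharing only the root score zero
  tx2 <- toy_taxonomy()
  expect_equal(pair_score("x", "y", list(x = "b", y = "e"), tx2), 0)
  expect_error(pair_score("x", "x", list(x = "b"), tx2), "distinct")
})

test_that("HMS equals a straight-line recomputation on a 3-leaf caterpillar", {
  tx <- generate_taxonomy(generator_spec(seed = 31, depth = 4,
                                         branching = c(2L, 3L),
                                         max_width = 10L))
  set.seed(31)
  genes <- c("ga", "gb", "gc")
  ann <- random_annotations(genes, tx, k = 2)
  cfg <- scoring_config(theta = 5)
  am <- annotate_module(caterpillar_tree(genes), ann, tx)
  got <- hms(am, tx, cfg)
  # independent recomputation: explicit sum over the two internal nodes
  total <- 0
  for (v in names(am$tree$children)) {
    kids <- am$tree$children[[v]]
    ds <- vapply(kids, function(k) {
      per <- vapply(am$F[[v]], function(tp) {
        min(vapply(am$F[[k]], function(tc) term_distance(tp, tc, tx),
                   numeric(1)))
      }, numeric(1))
      D <- max(per)
      if (is.infinite(D)) 1 else D / (D + cfg$theta)
    }, numeric(1))
    P <- 1 - max(ds)
    total <- total + P * max(term_specificity(am$F[[v]], tx))
  }
  expect_equal(got, total / 2)
  # wrapper equivalence for a pair
  expect_equal(pair_score("ga", "gb", ann, tx, cfg),
               hms(annotate_module(join_trees(list(leaf_tree("ga"),
                                                   leaf_tree("gb")), "R"),
                                   ann, tx), tx, cfg))
})

test_that("HMS stays in [0,1] and is monotone non-decreasing in theta", {
  set.seed(77)
  thetas <- c(0.5, 1, 2, 5, 10, 50, 100)
  for (sd in 1:5) {
    tx <- generate_taxonomy(generator_spec(seed = 700 + sd, depth = 5,
                                           branching = c(2L, 3L),
                                           max_width = 16L,
                                           dag_extra_parent_prob = 0.1))
    genes <- paste0("g", 1:6)
    ann <- random_annotations(genes, tx, k = 3)
    am <- annotate_module(caterpillar_tree(genes), ann, tx)
    scores <- vapply(thetas, function(th) {
      hms(am, tx, scoring_config(theta = th))
    }, numeric(1))
    expect_true(all(scores >= 0 & scores <= 1))
    expect_true(all(diff(scores) >= -1e-12))
  }
})

test_that("the sum-normalized node aggregation also stays within [0,1]", {
  tx <- toy_taxonomy()
  cfg <- scoring_config(node_aggregation = "sum-normalized")
  genes <- c("x", "y", "z")
  ann <- list(x = "b", y = "c", z = "e")
  am <- annotate_module(caterpillar_tree(genes), ann, tx)
  s <- hms(am, tx, cfg)
  expect_gte(s, 0); expect_lte(s, 1)
})
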