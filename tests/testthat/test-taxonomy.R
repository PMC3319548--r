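test_that("chain taxonomy gets correct levels and depth", {
  tx <- chain_taxonomy(2)
  expect_equal(tx$depth, 2L)
  expect_equal(tx$levels[["r"]], 0L)
  expect_equal(tx$levels[["t1"]], 1L)
  expect_equal(tx$levels[["t2"]], 2L)
  expect_equal(tx$root, "r")
})

test_that("a DAG term reachable along paths of different lengths occurs at several levels", {
  # x has parents p1 (level 1) and p2 (level 2)
  tx <- taxonomy(data.frame(child = c("p1", "p2", "x", "x"),
                            parent = c("root", "p1", "p1", "p2")))
  expect_equal(tx$levels[["x"]], c(2L, 3L))
  expect_equal(tx$depth, 3L)
})

test_that("level sets match brute-force path enumeration on random DAGs", {
  for (sd in 1:8) {
    tx <- generate_taxonomy(generator_spec(seed = sd, depth = 4,
                                           branching = c(2L, 3L),
                                           max_width = 12L,
                                           dag_extra_parent_prob = 0.3))
    for (t in sample(tx$terms, 8)) {
      expect_identical(tx$levels[[t]], oracle_levels(t, tx))
    }
  }
})

test_that("cycles and root problems are rejected", {
  expect_error(taxonomy(data.frame(child = c("a", "b"), parent = c("b", "a"))),
               "cycle")
  expect_error(taxonomy(data.frame(child = "a", parent = "a")), "cycle")
  expect_error(taxonomy(data.frame(child = c("a", "b"),
                                   parent = c("r1", "r2"))),
               "virtual_root")
  tx <- taxonomy(data.frame(child = c("a", "b"), parent = c("r1", "r2")),
                 virtual_root = TRUE)
  expect_equal(tx$root, "VIRTUAL:ROOT")
  expect_equal(tx$depth, 2L)
})

test_that("level specificity is l/L with its boundary values", {
  expect_equal(level_specificity(0, 5), 0)
  expect_equal(level_specificity(5, 5), 1)
  expect_equal(level_specificity(3, 4), 0.75)
  expect_error(level_specificity(5, 4), "level")
})

test_that("term specificity averages occurrence levels and pins root/leaf", {
  tx <- chain_taxonomy(3)
  expect_equal(unname(term_specificity("r", tx)), 0)
  expect_equal(unname(term_specificity("t3", tx)), 1)
  # x occurs at levels {2,3} in a depth-4 DAG -> mean(2/4, 3/4)
  tx2 <- taxonomy(data.frame(
    child = c("p1", "p2", "x", "x", "q"),
    parent = c("root", "p1", "p1", "p2", "x")))
  expect_equal(tx2$depth, 4L)
  expect_equal(unname(term_specificity("x", tx2)), 0.625)
  expect_equal(unname(term_specificity("x", tx2, aggregate = "min")), 0.5)
  expect_equal(unname(term_specificity("x", tx2, aggregate = "max")), 0.75)
  expect_error(term_specificity("nope", tx), "unknown")
})

test_that("relatedness is the (transitive, reflexive) ancestor relation", {
  tx <- toy_taxonomy()
  expect_true(is_related("root", "f", tx))
  expect_true(is_related("b", "a", tx))       # either direction
  expect_true(is_related("b", "b", tx))
  expect_false(is_related("b", "c", tx))      # siblings
  expect_false(is_related("b", "e", tx))      # across subtrees
})

test_that("ancestor closure contains every path to the root", {
  tx <- chain_taxonomy(2)
  expect_equal(ancestor_term_set("r", tx), "r")
  expect_equal(ancestor_term_set("t2", tx), c("r", "t1", "t2"))
  # DAG: both parents appear in the closure
  tx2 <- taxonomy(data.frame(child = c("p1", "p2", "x", "x"),
                             parent = c("root", "root", "p1", "p2")))
  expect_equal(ancestor_term_set("x", tx2), c("p1", "p2", "root", "x"))
})

test_that("term distance is shortest-path, symmetric, Inf when unrelated", {
  tx <- toy_taxonomy()
  expect_equal(term_distance("b", "b", tx), 0L)
  expect_equal(term_distance("a", "b", tx), 1L)
  expect_equal(term_distance("b", "a", tx), 1L)
  expect_equal(term_distance("root", "b", tx), 2L)
  expect_identical(term_distance("b", "e", tx), Inf)  # unrelated siblings' kids
  # distance 1 iff direct edge, on a random taxonomy
  tx2 <- generate_taxonomy(generator_spec(seed = 2, depth = 3,
                                          branching = c(2L, 2L),
                                          max_width = 8L))
  for (t in setdiff(tx2$terms, tx2$root)) {
    for (p in tx2$parents[[t]]) {
      expect_equal(term_distance(p, t, tx2), 1L)
    }
  }
})

test_that("reduction keeps only the most specific members", {
  tx <- chain_taxonomy(3)
  expect_equal(reduce_to_specific(c("t3", "t1"), tx), "t3")
  # two parents of one deep term both drop
  tx2 <- taxonomy(data.frame(child = c("p1", "p2", "x"),
                             parent = c("root", "root", "p1")))
  expect_equal(reduce_to_specific(c("p1", "p2", "x"), tx2), c("p2", "x"))
  expect_true(is_unrelated_set(reduce_to_specific(c("p1", "p2", "x"), tx2), tx2))
})

test_that("maximum unrelated subset matches examples and tie-break", {
  tx <- chain_taxonomy(2)
  expect_equal(max_unrelated_subset("r", tx), "r")
  # all of a chain is pairwise related: the deepest term wins the tie-break
  expect_equal(max_unrelated_subset(c("r", "t1", "t2"), tx), "t2")
  tx2 <- toy_taxonomy()
  expect_equal(max_unrelated_subset(c("root", "b", "c"), tx2), c("b", "c"))
  expect_error(max_unrelated_subset(character(0), tx), "empty")
})

test_that("maximum unrelated subset agrees with the power-set oracle on random DAGs", {
  set.seed(424)
  for (sd in 1:30) {
    tx <- generate_taxonomy(generator_spec(seed = 300 + sd, depth = 4,
                                           branching = c(2L, 3L),
                                           max_width = 12L,
                                           dag_extra_parent_prob = 0.25))
    cand <- sample(tx$terms, min(9, length(tx$terms)))
    got <- max_unrelated_subset(cand, tx)
    expect_true(is_unrelated_set(got, tx))
    expect_equal(length(got), oracle_max_unrelated_size(cand, tx))
  }
})
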