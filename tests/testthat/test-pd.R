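tr0 <- read_newick(T0)

test_that("inclusive PD counts every edge with a descendant in the group", {
  expect_equal(pd_inclusive(tr0, c("A", "B")), 6)
  expect_equal(pd_inclusive(tr0, c("A", "B", "C")), 10)
  expect_equal(pd_inclusive(tr0, c("A", "C")), 8)
  expect_error(pd_inclusive(tr0, character(0)), "non-empty")
  expect_error(pd_inclusive(tr0, "Z"), 'unknown leaf label.*"Z"')
})

test_that("exclusive PD counts edges leading only to the group", {
  expect_equal(pd_exclusive(tr0, "A"), 1)
  expect_equal(pd_exclusive(tr0, c("A", "C")), 5)
  expect_equal(pd_exclusive(tr0, c("A", "B", "C")), 10)
  # complement identity on the toy tree
  expect_equal(pd_exclusive(tr0, c("A", "C")), 10 - pd_inclusive(tr0, "B"))
})

test_that("unrooted convention gives the minimal spanning path", {
  expect_equal(pd_inclusive(tr0, c("A", "B"), rooted = FALSE), 3)
  expect_equal(pd_inclusive(tr0, c("A", "C"), rooted = FALSE), 8)
  expect_equal(pd_inclusive(tr0, "A", rooted = FALSE), 0)
})

test_that("pruning retains exactly the edges with a kept descendant", {
  p <- prune_to_group(tr0, c("A", "B"))
  expect_equal(tree_length(p), 6)
  expect_setequal(p$tip.label, c("A", "B"))
  expect_equal(tree_length(prune_to_group(tr0, c("A", "B", "C"))), 10)
  expect_equal(tree_length(prune_to_group(tr0, "A")), 4)
  expect_error(prune_to_group(tr0, character(0)), "non-empty")
  expect_error(prune_to_group(tr0, c("A", "Z")), "unknown leaf")
})

test_that("prune length equals PD_I for all subsets of random trees", {
  for (seed in 1:10) {
    tr <- simulate_tree(8, mean_brlen = 0.3, seed = seed)
    for (grp in all_subsets(tr$tip.label)) {
      expect_equal(tree_length(prune_to_group(tr, grp)),
                   pd_inclusive(tr, grp), tolerance = 1e-9)
    }
  }
})

test_that("pruning is idempotent and never increases total length", {
  for (seed in 1:5) {
    tr <- simulate_tree(10, seed = seed)
    grp <- sample(tr$tip.label, 4)
    once <- prune_to_group(tr, grp)
    twice <- prune_to_group(once, grp)
    expect_equal(tree_length(twice), tree_length(once), tolerance = 1e-12)
    expect_lte(tree_length(once), tree_length(tr))
  }
})

test_that("PD matches brute-force edge classification on random trees", {
  withr::with_seed(42, {
    for (rep in 1:12) {
      n <- sample(3:8, 1)
      tr <- simulate_tree(n, mean_brlen = 0.5, seed = rep)
      for (grp in all_subsets(tr$tip.label)) {
        ora <- oracle_pd(tr, grp)
        expect_equal(pd_inclusive(tr, grp), ora$pd_i, tolerance = 1e-12)
        expect_equal(pd_exclusive(tr, grp), ora$pd_e, tolerance = 1e-12)
      }
    }
  })
})

test_that("PD obeys ordering, complementarity and monotonicity", {
  for (seed in 1:8) {
    tr <- simulate_tree(9, seed = seed)
    total <- tree_length(tr)
    leaves <- tr$tip.label
    g <- sample(leaves, 4)
    h <- union(g, sample(setdiff(leaves, g), 2))
    expect_lte(pd_exclusive(tr, g), pd_inclusive(tr, g))
    expect_lte(pd_inclusive(tr, g), total)
    expect_gte(pd_exclusive(tr, g), 0)
    expect_equal(pd_exclusive(tr, g) + pd_inclusive(tr, setdiff(leaves, g)),
                 total, tolerance = 1e-9)
    expect_lte(pd_inclusive(tr, g), pd_inclusive(tr, h))
    expect_lte(pd_exclusive(tr, g), pd_exclusive(tr, h))
  }
})

test_that("polytomies and zero-length edges are handled", {
  tr <- read_newick("((A:1,B:2,C:3):0,D:4);")
  expect_equal(tree_length(tr), 10)
  expect_equal(pd_inclusive(tr, c("A", "B")), 3)
  expect_equal(pd_exclusive(tr, c("A", "B", "C")), 6)
})
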