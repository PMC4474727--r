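test_that("simulated trees are rooted binary with exponential lengths", {
  tr <- simulate_tree(5, mean_brlen = 0.1, seed = 1)
  expect_equal(ape::Ntip(tr), 5)
  expect_equal(nrow(tr$edge), 8)
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.binary(tr))
  expect_error(simulate_tree(1), ">= 2")
})

test_that("tree simulation is deterministic under a seed", {
  a <- write_newick(simulate_tree(20, seed = 9))
  b <- write_newick(simulate_tree(20, seed = 9))
  expect_identical(a, b)
  expect_false(identical(a, write_newick(simulate_tree(20, seed = 10))))
})

test_that("branch lengths have the requested mean", {
  tr <- simulate_tree(200, mean_brlen = 0.1, seed = 3)
  lens <- tr$edge.length
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 0.1), 3 * se)
})

test_that("random province assignment covers edge cases", {
  tr <- simulate_tree(30, seed = 4)
  all_in <- assign_provinces(tr, "random", provinces = "P1", p = 1, seed = 1)
  expect_setequal(all_in$species, tr$tip.label)
  fixed <- assign_provinces(tr, "random", provinces = "P1", n_members = 7,
                            seed = 1)
  expect_equal(nrow(fixed), 7)
  expect_error(assign_provinces(tr, "random", provinces = "P1", p = 0, seed = 1),
               "no members")
})

test_that("clustered assignment annotates exactly one clade", {
  withr::with_seed(5, {
    found <- FALSE
    for (s in 1:20) {
      tr <- simulate_tree(20, seed = s)
      if (!4 %in% clade_sizes(tr)) next
      found <- TRUE
      mp <- assign_provinces(tr, "clustered", provinces = "Focal",
                             clade_size = 4, seed = s)
      expect_equal(nrow(mp), 4)
      node <- ape::getMRCA(tr, mp$species)
      below <- ape::extract.clade(tr, node)$tip.label
      expect_setequal(mp$species, below)
      break
    }
    expect_true(found)
  })
  tr <- simulate_tree(5, seed = 1)
  expect_error(assign_provinces(tr, "clustered", clade_size = 6),
               "no clade of size 6")
})

test_that("zero intraspecific divergence gives identical conspecifics", {
  db <- simulate_barcodes(4, 3, alignment_length = 100,
                          divergence_intra = 0, seed = 8)
  for (sp in unique(db$species)) {
    expect_length(unique(db$sequence[db$species == sp]), 1)
  }
})

test_that("pairwise divergence follows the Jukes-Cantor expectation", {
  # two conspecific sequences sit 2 * t_intra apart on the star
  t_intra <- 0.05
  expected <- 0.75 * (1 - exp(-4 * (2 * t_intra) / 3))
  dists <- vapply(1:100, function(s) {
    db <- simulate_barcodes(2, 2, alignment_length = 300,
                            divergence_intra = t_intra, seed = 1000 + s)
    sp <- db$species[1]
    seqs <- db$sequence[db$species == sp]
    p_distance(seqs[1], seqs[2])
  }, numeric(1))
  se <- sd(dists) / sqrt(length(dists))
  expect_lt(abs(mean(dists) - expected), 3 * se)
})

test_that("barcode simulation is deterministic and valid", {
  a <- simulate_barcodes(6, c(1, 2, 3, 1, 2, 3), alignment_length = 120, seed = 11)
  b <- simulate_barcodes(6, c(1, 2, 3, 1, 2, 3), alignment_length = 120, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(alignment_length(a), 120)
  expect_equal(nrow(a), 12)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_barcode_fasta(a, f1); write_barcode_fasta(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_barcodes(4, c(1, 2)), "seqs_per_species")
  expect_error(simulate_barcodes(4, 2, divergence_inter = -1), ">= 0")
})
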