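test_that("segregating sites are columns with two unambiguous states", {
  db <- barcode_db(c("s1", "s2"), c("X x", "Y y"), c("ACGT", "AGGT"))
  expect_equal(segregating_sites(db), 2L)
  same <- barcode_db(c("s1", "s2"), c("X x", "Y y"), c("ACGT", "ACGT"))
  expect_length(segregating_sites(same), 0)
  # gaps and ambiguity codes do not create segregation
  amb <- barcode_db(c("s1", "s2", "s3"), c("X x", "Y y", "Z z"),
                    c("A-RT", "ANGT", "A-GT"))
  expect_equal(segregating_sites(amb), integer(0))
})

test_that("segregating sites match a brute-force column scan", {
  withr::with_seed(101, {
    for (rep in 1:10) {
      db <- random_toy_db(n_seqs = 6, n_cols = 12, n_species = 3)
      m <- do.call(rbind, strsplit(db$sequence, ""))
      expected <- which(apply(m, 2, function(col) {
        length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2
      }))
      expect_equal(segregating_sites(db), expected)
    }
  })
})

test_that("species profiles count bases and build majority consensus", {
  db <- barcode_db(c("a", "b"), c("X x", "X x"), c("ACGT", "ACGT"))
  pr <- species_profiles(db)
  expect_equal(unname(pr$consensus), "ACGT")
  # tie at the last column resolves to the alphabetically first base
  db2 <- barcode_db(c("a", "b"), c("Y y", "Y y"), c("AGGT", "AGGA"))
  expect_equal(unname(species_profiles(db2)$consensus), "AGGA")
  # counts at each column sum to the number of unambiguous bases
  db3 <- barcode_db(c("a", "b", "c"), c("Z z", "Z z", "Z z"),
                    c("AC-T", "ACNT", "AGGT"))
  cm <- species_profiles(db3)$counts[["Z z"]]
  expect_equal(unname(colSums(cm)), c(3, 3, 1, 3))
  # an all-gap column becomes a gap in the consensus
  db4 <- barcode_db(c("a", "b"), c("W w", "W w"), c("A-G", "A-G"))
  expect_equal(unname(species_profiles(db4)$consensus), "A-G")
})

test_that("the worked posterior matches hand arithmetic", {
  db <- worked_db()
  pr <- species_profiles(db)
  sites <- segregating_sites(db)
  expect_equal(sites, c(2L, 4L))
  post <- ssa_posterior("ACGT", pr, sites)
  lx <- (2 / 5) * (2 / 5)
  ly <- (1 / 6) * (2 / 6)
  expect_equal(unname(post[["Xus alba"]]), lx / (lx + ly), tolerance = 1e-12)
  expect_equal(sum(post), 1, tolerance = 1e-12)
})

test_that("posteriors match direct enumeration on random toy databases", {
  withr::with_seed(202, {
    done <- 0
    while (done < 8) {
      db <- random_toy_db(n_seqs = 6, n_cols = 6, n_species = 3)
      if (length(unique(db$species)) < 2) next
      done <- done + 1
      pr <- species_profiles(db)
      sites <- segregating_sites(db)
      q <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
      got <- ssa_posterior(q, pr, sites)
      want <- oracle_posterior(q, db, sites)
      expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-9)
      expect_equal(sum(got), 1, tolerance = 1e-9)
    }
  })
})

test_that("an uninformative query yields a uniform posterior with warning", {
  db <- worked_db()
  pr <- species_profiles(db)
  sites <- segregating_sites(db)
  expect_warning(post <- ssa_posterior("A-G-", pr, sites), "uniform")
  expect_equal(unname(post), c(0.5, 0.5))
})

test_that("p-distance ignores gaps and handles disjoint coverage", {
  expect_equal(p_distance("ACGT", "AGGA"), 0.5)
  expect_equal(p_distance("AC-T", "ACGT"), 0)
  expect_warning(d <- p_distance("AC--", "--GT"), "undefined")
  expect_equal(d, 1)
  expect_error(p_distance("ACG", "ACGT"), "length")
})

test_that("the worked minimum-risk assignment calls the right species", {
  res <- assignment_risk("ACGT", worked_db())
  lx <- 0.16; ly <- 2 / 36
  px <- lx / (lx + ly)
  expect_equal(res$risk[res$species == "Xus alba"], 0, tolerance = 1e-12)
  expect_equal(res$risk[res$species == "Yus flava"], 0.5 * px, tolerance = 1e-12)
  expect_equal(attr(res, "call"), "Xus alba")
  expect_false(attr(res, "ambiguous"))
})

test_that("a query equal to a consensus has exactly zero risk there", {
  db <- worked_db()
  res <- assignment_risk("AGGA", db)  # consensus of Yus flava
  expect_equal(res$risk[res$species == "Yus flava"], 0)
  expect_equal(attr(res, "call"), "Yus flava")
})

test_that("twin species with identical sequences tie and are flagged", {
  db <- barcode_db(c("a1", "a2", "b1", "b2", "c1"),
                   c("Aus una", "Aus una", "Bus una", "Bus una", "Cus tria"),
                   c("ACGTAC", "ACGTAC", "ACGTAC", "ACGTAC", "GTACGT"))
  res <- assignment_risk("ACGTAC", db)
  expect_true(attr(res, "ambiguous"))
  expect_setequal(attr(res, "tied_species"), c("Aus una", "Bus una"))
  expect_equal(attr(res, "call"), "Aus una")  # lexicographic tie-break
})

test_that("assignment is invariant to record order", {
  db <- simulate_barcodes(5, 3, alignment_length = 120, seed = 4)
  q <- db$sequence[1]
  db2 <- db[rev(seq_len(nrow(db))), ]
  a <- assignment_risk(q, db)
  b <- assignment_risk(q, db2)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
  expect_identical(attr(a, "call"), attr(b, "call"))
})

test_that("fewer than two candidate species is an error", {
  db <- barcode_db(c("a", "b"), c("X x", "X x"), c("AC", "AC"))
  expect_error(assignment_risk("AC", db), "at least 2 candidate species")
})

test_that("range standardisation follows the printed formula", {
  expect_equal(standardize_risk(c(0, 0.2, 0.6)), c(0, 1 / 3, 1),
               tolerance = 1e-12)
  expect_equal(standardize_risk(c(0.1, 0.3)), c(0, 0.5), tolerance = 1e-12)
  expect_equal(standardize_risk(c(0.4, 0.4)), c(0, 0))
  expect_equal(standardize_risk(c(0.1, 0.3), method = "range"), c(0, 1))
  expect_error(standardize_risk(numeric(0)), "empty")
  # rows whose minimum is 0 stay inside [0, 1]
  withr::with_seed(7, {
    for (i in 1:20) {
      r <- c(0, runif(5))
      s <- standardize_risk(r)
      expect_true(all(s >= 0 & s <= 1))
    }
  })
})
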