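# Shared fixtures and independent oracles for the test suite.

T0 <- "((A:1,B:2):3,C:4);"

# The two-species worked database: X = {ACGT}, Y = {AGGT, AGGA}.
worked_db <- function() {
  barcode_db(c("x1", "y1", "y2"),
             c("Xus alba", "Yus flava", "Yus flava"),
             c("ACGT", "AGGT", "AGGA"))
}

# Per-edge descendant leaf sets, computed independently of the package's
# path-union machinery (phangorn::Descendants walks the edge matrix itself).
edge_leaf_sets <- function(tree) {
  lapply(seq_len(nrow(tree$edge)), function(i) {
    tree$tip.label[phangorn::Descendants(tree, tree$edge[i, 2], "tips")[[1]]]
  })
}

# Brute-force edge-classification PD: an edge counts towards PD_I when its
# descendant leaves intersect the group, towards PD_E when they are all in
# the group. The root (stem) edge, when present, descends to every leaf.
oracle_pd <- function(tree, group) {
  sets <- edge_leaf_sets(tree)
  stem <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  inc <- vapply(sets, function(s) any(s %in% group), logical(1))
  exc <- vapply(sets, function(s) all(s %in% group), logical(1))
  all_in <- all(tree$tip.label %in% group)
  list(pd_i = sum(tree$edge.length[inc]) + stem,
       pd_e = sum(tree$edge.length[exc]) + if (all_in) stem else 0)
}

# Closed-form expected PD_I of a uniform k-subset of `group`: edge e (with
# m_e group members below it) is covered unless all k draws miss them, so
# E[PD] = stem + sum_e len_e (1 - C(N - m_e, k) / C(N, k)).
oracle_expected_pd <- function(tree, group, k) {
  sets <- edge_leaf_sets(tree)
  n <- length(group)
  stem <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  m <- vapply(sets, function(s) sum(s %in% group), numeric(1))
  stem + sum(tree$edge.length * (1 - choose(n - m, k) / choose(n, k)))
}

# Direct enumeration of the segregating-sites posterior: per-site
# (count + 1) / (total + 4) products in plain arithmetic, no log space.
oracle_posterior <- function(query, db, sites) {
  q <- strsplit(toupper(query), "")[[1]]
  species <- sort(unique(db$species))
  lik <- vapply(species, function(sp) {
    seqs <- strsplit(db$sequence[db$species == sp], "")
    out <- 1
    for (j in sites) {
      if (!q[j] %in% c("A", "C", "G", "T")) next
      col <- vapply(seqs, `[[`, character(1), j)
      col <- col[col %in% c("A", "C", "G", "T")]
      out <- out * (sum(col == q[j]) + 1) / (length(col) + 4)
    }
    out
  }, numeric(1))
  lik / sum(lik)
}

# A random barcode_db with arbitrary composition (not via the package's
# simulator), for oracle-equivalence checks on tiny alignments.
random_toy_db <- function(n_seqs, n_cols, n_species) {
  sp <- sprintf("Genus%d sp%d", seq_len(n_species), seq_len(n_species))
  barcode_db(
    sprintf("q%d", seq_len(n_seqs)),
    sample(sp, n_seqs, replace = TRUE),
    vapply(seq_len(n_seqs), function(i) {
      paste(sample(c("A", "C", "G", "T", "-", "N"), n_cols, replace = TRUE,
                   prob = c(rep(0.22, 4), 0.06, 0.06)), collapse = "")
    }, character(1))
  )
}

# All non-empty subsets of a character vector.
all_subsets <- function(x) {
  unlist(lapply(seq_along(x), function(k) {
    asplit(combn(x, k), 2)
  }), recursive = FALSE)
}
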