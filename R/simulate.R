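#' Simulate a random rooted binary tree
#'
#' Coalescent-style topology: starting from the leaves, two surviving
#' lineages chosen uniformly at random are joined until a single root
#' remains. Every edge receives an independent exponential length with the
#' given mean (substitutions/site). The result stands in for an inferred
#' gene tree in tests and simulations.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param mean_brlen Mean edge length (> 0).
#' @param labels Optional character vector of leaf labels (default
#'   `t1..tn`).
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @return A rooted binary `phylo` object with `2 * n_leaves - 2` edges.
#' @export
#' @examples
#' tr <- simulate_tree(5, mean_brlen = 0.1, seed = 1)
#' tree_length(tr)
simulate_tree <- function(n_leaves, mean_brlen = 0.1, labels = NULL,
                          seed = NULL) {
  if (!is.numeric(n_leaves) || n_leaves < 2) abort("`n_leaves` must be >= 2.")
  if (!is.numeric(mean_brlen) || mean_brlen <= 0) {
    abort("`mean_brlen` must be > 0.")
  }
  n <- as.integer(n_leaves)
  labels <- labels %||% paste0("t", seq_len(n))
  stopifnot(length(labels) == n, !anyDuplicated(labels))
  with_seed(seed, {
    alive <- seq_len(n)
    next_node <- 2L * n - 1L  # internal ids descend so the root ends at n + 1
    edge <- matrix(0L, nrow = 2L * n - 2L, ncol = 2L)
    e <- 0L
    while (length(alive) > 1) {
      pair <- sample(length(alive), 2L)
      v <- next_node
      next_node <- next_node - 1L
      edge[e + 1L, ] <- c(v, alive[pair[1]])
      edge[e + 2L, ] <- c(v, alive[pair[2]])
      e <- e + 2L
      alive <- c(alive[-pair], v)
    }
    tr <- structure(
      list(edge = edge, edge.length = rexp(nrow(edge), rate = 1 / mean_brlen),
           Nnode = n - 1L, tip.label = labels),
      class = "phylo"
    )
    ape::reorder.phylo(tr, "cladewise")
  })
}

#' Simulate a species-to-province annotation
#'
#' Two regimes bracket how a province's fauna can be assembled. In
#' `"random"` mode membership is scattered over the tree — each leaf joins
#' each province independently with probability `p` (or exactly `n_members`
#' leaves are drawn when given), emulating assembly by dispersal. In
#' `"clustered"` mode one whole clade of the requested size is assigned to
#' the focal province (optionally with `n_noise` extra leaves elsewhere),
#' emulating in-situ diversification; clustered membership concentrates
#' branch length inside the group and therefore inflates the PD_E/PD_I
#' ratio relative to random membership at the same group size.
#'
#' @param tree A `phylo` object.
#' @param mode `"random"` or `"clustered"`.
#' @param provinces Character vector of province names (`"random"` mode);
#'   the first is the focal province in `"clustered"` mode.
#' @param p Per-leaf membership probability (`"random"` mode).
#' @param n_members Exact number of members per province (`"random"` mode;
#'   overrides `p`).
#' @param clade_size Size of the clade to annotate (`"clustered"` mode).
#' @param n_noise Extra non-clade leaves added to the focal province.
#' @param seed Integer seed.
#' @return A province map tibble (`species`, `province`).
#' @export
assign_provinces <- function(tree, mode = c("random", "clustered"),
                             provinces = "P1", p = 0.5, n_members = NULL,
                             clade_size = NULL, n_noise = 0, seed = NULL) {
  mode <- match.arg(mode)
  tree <- validate_tree(tree)
  leaves <- tree$tip.label
  with_seed(seed, {
    if (mode == "random") {
      rows <- lapply(provinces, function(pr) {
        members <- if (!is.null(n_members)) {
          if (n_members < 1 || n_members > length(leaves)) {
            abort("`n_members` out of range.")
          }
          sample(leaves, n_members)
        } else {
          leaves[runif(length(leaves)) < p]
        }
        if (length(members) == 0) {
          abort(sprintf("province \"%s\" received no members; raise `p` or use `n_members`.", pr))
        }
        tibble(species = members, province = pr)
      })
      bind_rows(rows)
    } else {
      if (is.null(clade_size)) abort("`clade_size` is required in clustered mode.")
      ct <- clade_tip_sets(tree)
      sizes <- lengths(ct)
      hit <- which(sizes == clade_size)
      if (length(hit) == 0) {
        abort(sprintf("no clade of size %d exists in this tree (available sizes: %s).",
                      clade_size,
                      paste(sort(unique(sizes)), collapse = ", ")))
      }
      node <- hit[sample.int(length(hit), 1L)]
      members <- leaves[ct[[node]]]
      if (n_noise > 0) {
        pool <- setdiff(leaves, members)
        members <- c(members, sample(pool, min(n_noise, length(pool))))
      }
      tibble(species = members, province = provinces[1])
    }
  })
}

# Tip-index sets below every node (list indexed by node number).
clade_tip_sets <- function(tree) {
  n_tip <- ape::Ntip(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  sets <- c(as.list(seq_len(n_tip)),
            vector("list", tree$Nnode))
  for (i in seq_len(nrow(post$edge))) {
    par <- post$edge[i, 1]; child <- post$edge[i, 2]
    sets[[par]] <- c(sets[[par]], sets[[child]])
  }
  sets
}

#' Sizes of all clades in a tree
#'
#' Convenience for choosing a feasible `clade_size` in
#' [assign_provinces()]'s clustered mode.
#'
#' @param tree A `phylo` object.
#' @return Sorted integer vector of internal-node clade sizes.
#' @export
clade_sizes <- function(tree) {
  sizes <- lengths(clade_tip_sets(validate_tree(tree)))
  sort(sizes[sizes > 1])
}

#' Simulate an aligned barcode database with known species truth
#'
#' Sequences evolve under Jukes-Cantor (equal rates, no indels): a uniform
#' random root sequence evolves along a simulated species tree whose edges
#' have i.i.d. exponential lengths with mean `divergence_inter`
#' (substitutions/site); each tip sequence is the species consensus, from
#' which the individual sequences diverge independently along star branches
#' of length `divergence_intra`. With `divergence_inter` well above
#' `divergence_intra` this reproduces the barcoding gap that species
#' assignment relies on; singletons are allowed via `seqs_per_species`.
#'
#' @param n_species Number of species (>= 2).
#' @param seqs_per_species Integer scalar or vector (length `n_species`) of
#'   sequences per species; 1 gives a singleton.
#' @param alignment_length Number of alignment columns (default 658, the
#'   standard COI barcode fragment).
#' @param divergence_inter Mean species-tree edge length, substitutions/site.
#' @param divergence_intra Individual-to-consensus branch length,
#'   substitutions/site (0 makes conspecific sequences identical).
#' @param species_names Optional character vector of "Genus species" names.
#' @param seed Integer seed.
#' @return A [barcode_db()] whose `species` column is the simulation truth;
#'   the species tree is attached as attribute `species_tree`.
#' @export
#' @examples
#' db <- simulate_barcodes(5, 2, alignment_length = 100, seed = 1)
#' table(db$species)
simulate_barcodes <- function(n_species = 10, seqs_per_species = 3,
                              alignment_length = 658,
                              divergence_inter = 0.05,
                              divergence_intra = 0.005,
                              species_names = NULL, seed = NULL) {
  if (n_species < 2) abort("`n_species` must be >= 2.")
  if (alignment_length < 1) abort("`alignment_length` must be >= 1.")
  if (divergence_inter < 0 || divergence_intra < 0) {
    abort("divergences must be >= 0.")
  }
  nseq <- if (length(seqs_per_species) == 1L) {
    rep(as.integer(seqs_per_species), n_species)
  } else {
    as.integer(seqs_per_species)
  }
  if (length(nseq) != n_species || any(nseq < 1)) {
    abort("`seqs_per_species` must be a positive scalar or length-`n_species` vector.")
  }
  species_names <- species_names %||%
    sprintf("Genus%02d species%02d", seq_len(n_species), seq_len(n_species))
  stopifnot(length(species_names) == n_species)

  with_seed(seed, {
    tr <- simulate_tree(n_species, mean_brlen = max(divergence_inter, 1e-12),
                        labels = species_names)
    if (divergence_inter == 0) tr$edge.length[] <- 0
    n_tip <- ape::Ntip(tr)
    root <- n_tip + 1L
    node_seq <- vector("list", n_tip + tr$Nnode)
    node_seq[[root]] <- sample.int(4L, alignment_length, replace = TRUE) - 1L
    cw <- ape::reorder.phylo(tr, "cladewise")  # parents precede children
    for (i in seq_len(nrow(cw$edge))) {
      par <- cw$edge[i, 1]; child <- cw$edge[i, 2]
      node_seq[[child]] <- evolve_jc(node_seq[[par]], cw$edge.length[i])
    }
    ids <- character(0); sps <- character(0); seqs <- character(0)
    counter <- 0L
    for (s in seq_len(n_species)) {
      tip <- match(species_names[s], tr$tip.label)
      consensus <- node_seq[[tip]]
      for (j in seq_len(nseq[s])) {
        counter <- counter + 1L
        ids <- c(ids, sprintf("sim%04d", counter))
        sps <- c(sps, species_names[s])
        seqs <- c(seqs, paste(DNA_BASES[evolve_jc(consensus, divergence_intra) + 1L],
                              collapse = ""))
      }
    }
    db <- barcode_db(ids, sps, seqs)
    attr(db, "species_tree") <- tr
    db
  })
}

# One Jukes-Cantor step: seq is an integer vector over 0:3, t a branch
# length in expected substitutions/site. P(observe a change) =
# 3/4 (1 - exp(-4 t / 3)); a changed site moves to one of the other three
# bases uniformly.
evolve_jc <- function(seq, t) {
  if (t <= 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * t / 3))
  hit <- which(runif(length(seq)) < p)
  if (length(hit) > 0) {
    seq[hit] <- (seq[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
  }
  seq
}
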