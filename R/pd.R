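#' Inclusive phylogenetic diversity of a leaf group
#'
#' Inclusive PD (`PD_I`) is the total branch length retained when every leaf
#' outside the group is trimmed from the tree: the group's share of the
#' tree's evolutionary heritage. Under the default rooted convention an edge
#' is counted whenever at least one of its descendant leaves belongs to the
#' group, so `PD_I` of the full leaf set equals [tree_length()]. Setting
#' `rooted = FALSE` gives the unrooted variant (the minimal spanning path
#' connecting the group members, which excludes the stem above their most
#' recent common ancestor and is 0 for a single leaf).
#'
#' @param tree A rooted `phylo` object with non-negative edge lengths.
#' @param group Character vector of leaf labels (a non-empty subset of
#'   `tree$tip.label`).
#' @param rooted Count the stem edges from the root down to the group's MRCA
#'   (default `TRUE`).
#' @return Non-negative numeric scalar, in the units of the branch lengths
#'   (substitutions/site for molecular trees).
#' @seealso [pd_exclusive()], [pd_report()], [rarefy_pd()]
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:2):3,C:4);")
#' pd_inclusive(tr, c("A", "B"))  # edges 1 + 2 + 3 = 6
pd_inclusive <- function(tree, group, rooted = TRUE) {
  tree <- validate_tree(tree)
  idx <- group_index(tree, group)
  paths <- tip_root_paths(tree)
  on_path <- rep(FALSE, nrow(tree$edge))
  for (tip in idx) on_path[paths[[tip]]] <- TRUE
  pd <- sum(tree$edge.length[on_path])
  if (rooted) {
    pd + (tree$root.edge %||% 0)
  } else {
    shared <- Reduce(intersect, paths[idx])
    pd - sum(tree$edge.length[shared])
  }
}

#' Exclusive phylogenetic diversity of a leaf group
#'
#' Exclusive PD (`PD_E`) is the branch length found only on lineages leading
#' exclusively to members of the group: edges all of whose descendant leaves
#' are in the group. It measures evolutionary change accrued in situ within
#' the group (e.g. within one biogeographic province) and satisfies the
#' complementarity identity
#' `PD_E(G) = tree_length - PD_I(complement of G)`.
#'
#' @inheritParams pd_inclusive
#' @return Non-negative numeric scalar, at most `pd_inclusive(tree, group)`.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:2):3,C:4);")
#' pd_exclusive(tr, c("A", "C"))  # pendant edges of A and C = 5
pd_exclusive <- function(tree, group) {
  tree <- validate_tree(tree)
  idx <- group_index(tree, group)
  total <- tree_length(tree)
  complement <- setdiff(tree$tip.label, tree$tip.label[idx])
  if (length(complement) == 0) return(total)
  total - pd_inclusive(tree, complement)
}

#' Prune a tree down to a leaf group
#'
#' Retains exactly the edges of `tree` that have at least one descendant leaf
#' in `keep`. Chains of degree-two nodes created by the pruning are merged
#' with their lengths summed, and the stem from the original root down to the
#' MRCA of the kept leaves is preserved as the pruned tree's root edge, so
#' that `tree_length()` of the result equals `pd_inclusive(tree, keep)`.
#' Pruning is idempotent and never increases total length.
#'
#' @inheritParams pd_inclusive
#' @param keep Character vector of leaf labels to retain.
#' @return A `phylo` object on the `keep` leaves.
#' @export
prune_to_group <- function(tree, keep) {
  tree <- validate_tree(tree)
  idx <- group_index(tree, keep)
  keep <- tree$tip.label[idx]
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1L) {
    len <- pd_inclusive(tree, keep)
    out <- structure(
      list(edge = matrix(c(2L, 1L), 1L, 2L), edge.length = len,
           Nnode = 1L, tip.label = keep),
      class = "phylo", order = "cladewise"
    )
    return(out)
  }
  pruned <- ape::keep.tip(tree, keep)
  # keep.tip discards the stem above the MRCA of `keep`; restore it so the
  # retained-edge accounting is exact.
  mrca <- ape::getMRCA(tree, keep)
  root <- ape::Ntip(tree) + 1L
  stem <- 0
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  node <- mrca
  while (node != root) {
    e <- parent_edge[node]
    stem <- stem + tree$edge.length[e]
    node <- tree$edge[e, 1]
  }
  stem <- stem + (tree$root.edge %||% 0)
  if (stem > 0) pruned$root.edge <- stem
  pruned
}

# Resolve a leaf group to tip indices, validating the group contract.
group_index <- function(tree, group) {
  if (length(group) == 0) abort("leaf group must be non-empty.")
  group <- unique(as.character(group))
  idx <- match(group, tree$tip.label)
  if (anyNA(idx)) {
    abort(sprintf("unknown leaf label%s: %s",
                  if (sum(is.na(idx)) > 1) "s" else "",
                  paste0('"', group[is.na(idx)], '"', collapse = ", ")))
  }
  idx
}
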