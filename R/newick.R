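#' Read a branch-length phylogeny from Newick
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is
#' the substrate of all phylogenetic-diversity computations, so invariants
#' that `ape` does not enforce are checked here: leaf labels must be unique
#' and edge lengths non-negative. Edges without a stated length are treated
#' as length zero. Internal node labels (typically bootstrap values) are kept
#' but play no role in PD arithmetic.
#'
#' @param x Either a path to a Newick file or a Newick string (recognised by
#'   a trailing ";" / leading "(").
#' @return A rooted `phylo` object.
#' @export
#' @examples
#' tr <- read_newick("((A:1.0,B:2.0):3.0,C:4.0);")
#' tree_length(tr)
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  is_text <- grepl("[();]", x)
  txt <- if (is_text) x else paste(readLines(x, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    abort(sprintf(
      "Newick parse error: unbalanced parentheses (%d '(' vs %d ')').",
      n_open, n_close
    ), class = "barcodiv_parse_error")
  }
  tr <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)),
                              class = "barcodiv_parse_error")
  )
  if (is.null(tr)) {
    abort("Newick parse error: input could not be read as a tree.",
          class = "barcodiv_parse_error")
  }
  validate_tree(tr)
}

#' Write a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Enforce the tree invariants assumed by the PD code.
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a `phylo` object.")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate leaf label%s: %s",
                  if (length(dup) > 1) "s" else "",
                  paste0('"', dup, '"', collapse = ", ")),
          class = "barcodiv_parse_error")
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[!is.finite(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0)) {
    abort("negative edge lengths are not allowed.",
          class = "barcodiv_parse_error")
  }
  tree
}

#' Total branch length of a tree
#'
#' Sum of all edge lengths, including the root (stem) edge when one is
#' recorded. This is the `PD` of the complete leaf set.
#'
#' @param tree A `phylo` object.
#' @return Non-negative numeric scalar.
#' @export
tree_length <- function(tree) {
  sum(tree$edge.length %||% 0) + (tree$root.edge %||% 0)
}

# Edge indices on the path from the root down to each tip.
# Returns a list indexed by tip number; element i is the integer vector of
# rows of tree$edge lying on the root -> tip i path.
tip_root_paths <- function(tree) {
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ape::Ntip(tree) + 1L
  lapply(seq_len(ape::Ntip(tree)), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      e <- parent_edge[node]
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    path
  })
}
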