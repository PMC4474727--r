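#' Read a species-to-province annotation table
#'
#' The table assigns each species to one or more marine provinces (or any
#' other biogeographic units). Format: UTF-8 TSV with header
#' `species<TAB>province`, one row per (species, province) pair, so a species
#' occurring in several provinces occupies several rows.
#'
#' @param file Path to the TSV file.
#' @return A tibble with columns `species` and `province`.
#' @export
read_province_table <- function(file) {
  tb <- readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  as_province_map(tb)
}

#' Write a species-to-province table
#'
#' @param map A province map (tibble with `species`, `province`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_province_table <- function(map, file) {
  readr::write_tsv(as_province_map(map), file, progress = FALSE)
  invisible(file)
}

#' Validate a province map
#'
#' @param x A data frame with character columns `species` and `province`.
#' @return A deduplicated tibble with those two columns.
#' @export
as_province_map <- function(x) {
  x <- as_tibble(x)
  if (!all(c("species", "province") %in% names(x))) {
    abort("a province map needs `species` and `province` columns.")
  }
  x <- distinct(x, .data$species, .data$province)
  if (any(is.na(x$species)) || any(is.na(x$province)) ||
      any(!nzchar(x$species)) || any(!nzchar(x$province))) {
    abort("province map contains empty species or province entries.")
  }
  x
}

#' Match tree leaves against a province map
#'
#' Leaf labels and table species names are compared on the normalised
#' "genus species" key (see [species_key()]). Every leaf is reported exactly
#' once per province it matches; leaves matching no table entry come back
#' with `province = NA` so that nothing is silently dropped.
#'
#' @param tree A `phylo` object.
#' @param map A province map (see [as_province_map()]).
#' @return A tibble with columns `leaf`, `species`, `province` (NA for
#'   unannotated leaves).
#' @export
match_provinces <- function(tree, map) {
  tree <- validate_tree(tree)
  map <- as_province_map(map)
  leaves <- tibble(leaf = tree$tip.label, key = species_key(tree$tip.label))
  anno <- tibble(key = species_key(map$species), species = map$species,
                 province = map$province)
  anno <- distinct(anno, .data$key, .data$province, .keep_all = TRUE)
  left_join(leaves, anno, by = "key") |>
    select("leaf", "species", "province")
}

#' Inclusive/exclusive PD report per province
#'
#' For each province, computes the inclusive PD (`pd_i`), the exclusive PD
#' (`pd_e`), their ratio `pd_e / pd_i` (the fraction of the province's
#' heritage attributable to in-situ change) and the number of matched leaves
#' `n`. By default, leaves that match no annotation are trimmed from the tree
#' before any PD computation, so the `PD_E` baseline is the annotated tree;
#' set `keep_unannotated = TRUE` to keep them (they then enlarge the total
#' length against which `PD_E` is measured but never join a group).
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param map A province map (see [as_province_map()]).
#' @param provinces Character vector of provinces to report; default all
#'   provinces present in `map`.
#' @param keep_unannotated Keep unannotated leaves in the tree (default
#'   `FALSE`, i.e. trim them).
#' @param quiet Suppress the log message about unmatched names.
#' @return A tibble of class `pd_report` with columns `province`, `n`,
#'   `pd_i`, `pd_e`, `ratio`.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:2):3,C:4);")
#' mp <- tibble::tibble(species = c("A", "B", "C"),
#'                      province = c("P1", "P1", "P2"))
#' pd_report(tr, mp)
pd_report <- function(tree, map, provinces = NULL,
                      keep_unannotated = FALSE, quiet = FALSE) {
  tree <- validate_tree(tree)
  map <- as_province_map(map)
  matched <- match_provinces(tree, map)
  provinces <- provinces %||% sort(unique(map$province))

  unannotated <- unique(matched$leaf[is.na(matched$province)])
  if (length(unannotated) > 0 && !quiet) {
    message(sprintf("%d of %d leaves unannotated%s: %s",
                    length(unannotated), ape::Ntip(tree),
                    if (keep_unannotated) " (kept)" else " (trimmed)",
                    paste(head(unannotated, 10), collapse = ", ")))
  }
  unmatched_species <- setdiff(species_key(map$species),
                               species_key(tree$tip.label))
  if (length(unmatched_species) > 0 && !quiet) {
    message(sprintf("%d annotated species not found among tree leaves.",
                    length(unmatched_species)))
  }

  if (!keep_unannotated) {
    annotated_leaves <- unique(matched$leaf[!is.na(matched$province)])
    if (length(annotated_leaves) == 0) {
      abort("no tree leaf matches any annotated species.")
    }
    tree <- prune_to_group(tree, annotated_leaves)
    matched <- filter(matched, .data$leaf %in% annotated_leaves)
  }

  rows <- lapply(provinces, function(p) {
    grp <- unique(matched$leaf[!is.na(matched$province) & matched$province == p])
    if (length(grp) == 0) {
      miss <- map$species[map$province == p]
      abort(sprintf(
        "province \"%s\" matches no tree leaf (annotated species: %s).",
        p, paste(head(miss, 10), collapse = ", ")))
    }
    pd_i <- pd_inclusive(tree, grp)
    pd_e <- pd_exclusive(tree, grp)
    tibble(province = p, n = length(grp), pd_i = pd_i, pd_e = pd_e,
           ratio = if (pd_i > 0) pd_e / pd_i else NA_real_)
  })
  out <- bind_rows(rows)
  class(out) <- c("pd_report", class(out))
  out
}
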