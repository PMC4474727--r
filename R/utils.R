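#' Normalise a species or leaf name for matching
#'
#' Tree leaf labels and annotation-table species names rarely agree byte for
#' byte: Newick labels use underscores, tables use spaces, and capitalisation
#' drifts. Matching is therefore done on a normalised key: underscores become
#' spaces, whitespace is collapsed, and the comparison is case-insensitive on
#' the "Genus species" prefix (the first two whitespace-delimited tokens).
#' Suffixes such as voucher numbers are ignored for matching but preserved in
#' the original labels.
#'
#' @param x Character vector of names.
#' @return Character vector of lower-case "genus species" keys. Names with a
#'   single token keep that token alone.
#' @export
#' @examples
#' species_key(c("Tedania_oxeata", "tedania  oxeata NIWA123"))
species_key <- function(x) {
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- stringr::str_squish(x)
  x <- tolower(x)
  vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    paste(head(tok, 2L), collapse = " ")
  }, character(1))
}

#' Genus of a species name
#'
#' The genus is the first whitespace-delimited token of a "Genus species"
#' binomial (underscores treated as spaces).
#'
#' @param x Character vector of species names.
#' @return Character vector of genus names (lower-cased for robust comparison).
#' @export
genus_of <- function(x) {
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- stringr::str_squish(tolower(x))
  vapply(strsplit(x, " ", fixed = TRUE), `[[`, character(1), 1L)
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
# A NULL seed leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- rlang::`%||%`
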