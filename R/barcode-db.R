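#' Construct a barcode database
#'
#' A barcode database is the aligned, species-labelled reference against
#' which query sequences are classified. It is a tibble with columns
#' `seq_id`, `species` and `sequence` (aligned, over `A C G T N -` and IUPAC
#' ambiguity codes), carrying the alignment length as an attribute. All
#' sequences must have the same length and all `seq_id`s must be unique.
#'
#' @param seq_id Character vector of unique sequence identifiers.
#' @param species Character vector of "Genus species" names (underscores are
#'   converted to spaces; the genus is the first token).
#' @param sequence Character vector of aligned sequences.
#' @return A tibble of class `barcode_db`.
#' @export
barcode_db <- function(seq_id, species, sequence) {
  species <- stringr::str_squish(gsub("_", " ", species, fixed = TRUE))
  db <- tibble(seq_id = as.character(seq_id), species = species,
               sequence = toupper(as.character(sequence)))
  validate_barcode_db(db)
}

validate_barcode_db <- function(db) {
  db <- as_tibble(db)
  if (!all(c("seq_id", "species", "sequence") %in% names(db))) {
    abort("a barcode_db needs `seq_id`, `species` and `sequence` columns.")
  }
  if (nrow(db) == 0) abort("barcode_db is empty.")
  dup <- unique(db$seq_id[duplicated(db$seq_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate seq_id%s: %s", if (length(dup) > 1) "s" else "",
                  paste0('"', dup, '"', collapse = ", ")))
  }
  bad <- db$seq_id[is.na(db$species) | !nzchar(db$species)]
  if (length(bad) > 0) {
    abort(sprintf("missing species name for record%s: %s",
                  if (length(bad) > 1) "s" else "",
                  paste0('"', bad, '"', collapse = ", ")))
  }
  len <- unique(nchar(db$sequence))
  if (length(len) != 1) {
    off <- db$seq_id[nchar(db$sequence) != len[1]]
    abort(sprintf("unequal alignment length (records: %s).",
                  paste0('"', off, '"', collapse = ", ")))
  }
  attr(db, "alignment_length") <- len
  class(db) <- unique(c("barcode_db", class(db)))
  db
}

#' Alignment length of a barcode database
#' @param db A `barcode_db`.
#' @return Integer number of alignment columns.
#' @export
alignment_length <- function(db) {
  attr(validate_barcode_db(db), "alignment_length")
}

#' Read an aligned barcode FASTA
#'
#' Headers follow the dialect `>seq_id|Genus_species`; underscores in the
#' species field become spaces. Sequences must form an alignment (equal
#' lengths).
#'
#' @param x Path to a FASTA file, or a FASTA string (starting with `>`).
#' @return A [barcode_db()].
#' @export
read_barcode_fasta <- function(x) {
  stopifnot(is.character(x))
  if (length(x) > 1 || startsWith(x[1], ">")) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(x, path)
  } else {
    path <- x
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort("FASTA contains no records.")
  hdr <- names(seqs)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  missing <- hdr[lengths(parts) < 2]
  if (length(missing) > 0) {
    abort(sprintf("missing species field (expected `>seq_id|Genus_species`) in record%s: %s",
                  if (length(missing) > 1) "s" else "",
                  paste0('"', missing, '"', collapse = ", ")))
  }
  barcode_db(
    seq_id = vapply(parts, `[[`, character(1), 1L),
    species = vapply(parts, function(p) paste(p[-1], collapse = "|"), character(1)),
    sequence = as.character(seqs)
  )
}

#' Write a barcode database as aligned FASTA
#'
#' @param db A `barcode_db`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_barcode_fasta <- function(db, file) {
  db <- validate_barcode_db(db)
  set <- Biostrings::BStringSet(db$sequence)
  names(set) <- paste0(db$seq_id, "|", gsub(" ", "_", db$species, fixed = TRUE))
  Biostrings::writeXStringSet(set, file, width = 80L)
  invisible(file)
}

# Character matrix view (sequences x columns) of a barcode_db.
seq_matrix <- function(db) {
  m <- do.call(rbind, strsplit(db$sequence, "", fixed = TRUE))
  rownames(m) <- db$seq_id
  m
}

DNA_BASES <- c("A", "C", "G", "T")
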