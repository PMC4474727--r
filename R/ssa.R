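#' Segregating sites of a barcode database
#'
#' A segregating site is an alignment column at which at least two distinct
#' unambiguous bases (`A C G T`) occur across the database. Gaps, `N` and
#' IUPAC ambiguity codes do not count towards segregation. Only these
#' columns are informative for the classifier: at every other column all
#' species share one base (or nothing), so the likelihood contribution is
#' common to all candidates.
#'
#' @param db A [barcode_db()].
#' @return Integer vector of 1-based column indices (possibly empty).
#' @export
#' @examples
#' db <- barcode_db(c("s1", "s2"), c("X x", "Y y"), c("ACGT", "AGGT"))
#' segregating_sites(db)  # column 2
segregating_sites <- function(db) {
  db <- validate_barcode_db(db)
  m <- seq_matrix(db)
  present <- vapply(DNA_BASES, function(b) colSums(m == b) > 0,
                    logical(ncol(m)))
  present <- matrix(present, ncol = 4)
  which(rowSums(present) >= 2)
}

#' Per-species base profiles and consensus sequences
#'
#' For each species, tallies the unambiguous bases at every alignment column
#' and derives the majority-rule consensus (ties broken towards the
#' alphabetically first base, `A < C < G < T`; columns with no unambiguous
#' base become a gap).
#'
#' @param db A [barcode_db()].
#' @return An object of class `species_profiles`: a list with elements
#'   `species`, `n_seqs`, `counts` (per species, a 4 x L integer matrix with
#'   rows `A C G T`), `consensus` (named character vector) and
#'   `alignment_length`.
#' @export
species_profiles <- function(db) {
  db <- validate_barcode_db(db)
  len <- attr(db, "alignment_length")
  species <- sort(unique(db$species))
  m <- seq_matrix(db)
  counts <- lapply(species, function(sp) {
    sub <- m[db$species == sp, , drop = FALSE]
    cm <- t(matrix(vapply(DNA_BASES, function(b) colSums(sub == b),
                          numeric(len)), ncol = 4))
    storage.mode(cm) <- "integer"
    rownames(cm) <- DNA_BASES
    cm
  })
  names(counts) <- species
  consensus <- vapply(counts, function(cm) {
    paste(vapply(seq_len(ncol(cm)), function(j) {
      if (sum(cm[, j]) == 0) "-" else DNA_BASES[which.max(cm[, j])]
    }, character(1)), collapse = "")
  }, character(1))
  structure(
    list(species = species,
         n_seqs = setNames(as.integer(table(db$species)[species]), species),
         counts = counts,
         consensus = consensus,
         alignment_length = len),
    class = "species_profiles"
  )
}

#' Posterior species membership of a query sequence
#'
#' Bayesian assignment over the database's segregating sites. Each species is
#' modelled by its per-site base frequencies with a Laplace pseudocount
#' (`alpha`, default 1): at site `j` the probability that species `k` emits
#' the query base `q_j` is `(c_kjq + alpha) / (n_kj + 4 alpha)`, with `c` the
#' count of `q_j` among species `k`'s unambiguous bases at `j` and `n` their
#' total. Sites where the query is a gap or ambiguous are skipped. With a
#' uniform prior over species the posterior is the normalised product of the
#' per-site terms, accumulated in log space.
#'
#' @param query An aligned query sequence (string of the same alignment
#'   length as the profiles).
#' @param profiles A [species_profiles()] object.
#' @param sites Integer vector of segregating-site columns
#'   (see [segregating_sites()]).
#' @param alpha Laplace pseudocount (> 0).
#' @return Named numeric vector of posterior probabilities, summing to 1.
#' @export
ssa_posterior <- function(query, profiles, sites, alpha = 1) {
  stopifnot(inherits(profiles, "species_profiles"), alpha > 0)
  q <- query_chars(query, profiles$alignment_length)
  usable <- sites[q[sites] %in% DNA_BASES]
  k <- length(profiles$species)
  if (length(usable) == 0) {
    warn("query has no unambiguous base at any segregating site; posterior is uniform.")
    return(setNames(rep(1 / k, k), profiles$species))
  }
  ll <- vapply(profiles$counts, function(cm) {
    n_j <- colSums(cm[, usable, drop = FALSE])
    c_j <- cm[cbind(match(q[usable], DNA_BASES), usable)]
    sum(log(c_j + alpha) - log(n_j + 4 * alpha))
  }, numeric(1))
  w <- exp(ll - max(ll))
  w / sum(w)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing positions among the columns where both sequences
#' carry an unambiguous base (`A C G T`). If the two sequences share no such
#' column the distance is undefined and is reported as 1 with a warning.
#'
#' @param a,b Aligned sequences (strings of equal length).
#' @return Numeric in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  a <- query_chars(a); b <- query_chars(b)
  if (length(a) != length(b)) abort("sequences differ in length.")
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  if (!any(ok)) {
    warn("no mutually unambiguous sites; p-distance undefined, reporting 1.")
    return(1)
  }
  mean(a[ok] != b[ok])
}

#' Minimum-risk species assignment of a query barcode
#'
#' Combines the segregating-sites posterior with a distance-based loss: the
#' risk of calling species `i` is the expected loss
#' `R(i) = sum_k P(k | S) L(i, k)` with `L(i, i) = 0`. Under the default
#' loss, `L(i, k)` for `k != i` is the p-distance between the query `S` and
#' the consensus of species `i`, which collapses to
#' `R(i) = d(S, consensus_i) (1 - P(i | S))`. The alternative
#' `"consensus_consensus"` loss uses `L(i, k) = d(consensus_i, consensus_k)`.
#' The call is the risk-minimising species; exact ties are reported and
#' flagged ambiguous, with the alphabetically first species as the call.
#'
#' @param query An aligned query sequence (same alignment length as `db`).
#' @param db A [barcode_db()] of candidate species (at least 2 species).
#' @param query_id Identifier used in reports.
#' @param loss `"query_consensus"` (default) or `"consensus_consensus"`.
#' @param alpha Laplace pseudocount for the posterior.
#' @return A tibble of class `ssa_assignment` with one row per candidate
#'   species (`species`, `posterior`, `p_distance`, `risk`), ordered by
#'   increasing risk. Attributes: `call`, `ambiguous`, `tied_species`,
#'   `query_id`.
#' @export
#' @examples
#' db <- barcode_db(c("x1", "y1", "y2"),
#'                  c("Xus alba", "Yus flava", "Yus flava"),
#'                  c("ACGT", "AGGT", "AGGA"))
#' res <- assignment_risk("ACGT", db)
#' attr(res, "call")
assignment_risk <- function(query, db, query_id = "query",
                            loss = c("query_consensus", "consensus_consensus"),
                            alpha = 1) {
  loss <- match.arg(loss)
  db <- validate_barcode_db(db)
  prof <- species_profiles(db)
  if (length(prof$species) < 2) {
    abort("at least 2 candidate species are required for an assignment.")
  }
  sites <- segregating_sites(db)
  post <- ssa_posterior(query, prof, sites, alpha = alpha)
  d <- vapply(prof$consensus, function(cs) p_distance(query, cs), numeric(1))
  risk <- switch(loss,
    query_consensus = d * (1 - post),
    consensus_consensus = {
      cc <- outer(prof$consensus, prof$consensus,
                  Vectorize(function(a, b) p_distance(a, b)))
      diag(cc) <- 0
      as.numeric(cc %*% post)
    }
  )
  out <- tibble(species = prof$species, posterior = unname(post),
                p_distance = unname(d), risk = unname(risk)) |>
    arrange(.data$risk, .data$species)
  tied <- out$species[out$risk <= min(out$risk) + 1e-12]
  attr(out, "query_id") <- query_id
  attr(out, "call") <- tied[1]
  attr(out, "tied_species") <- tied
  attr(out, "ambiguous") <- length(tied) > 1
  class(out) <- c("ssa_assignment", class(out))
  out
}

#' Range-standardise a row of assignment risks
#'
#' Maps raw risks `R` to `(R - min(R)) / (max(R) + min(R))`, the form used to
#' make risks comparable between classification trials (the conventional
#' range denominator `max(R) - min(R)` is available via `method = "range"`).
#' When the denominator is 0 every value maps to 0. With the default
#' denominator the minimum always maps to 0 but the maximum only reaches 1
#' when the minimum is 0.
#'
#' @param r Numeric vector of raw risks (non-empty).
#' @param method `"printed"` (default, `max + min` denominator) or
#'   `"range"` (`max - min`).
#' @return Numeric vector of standardised risks.
#' @export
#' @examples
#' standardize_risk(c(0, 0.2, 0.6))  # 0, 1/3, 1
standardize_risk <- function(r, method = c("printed", "range")) {
  method <- match.arg(method)
  if (length(r) == 0) abort("cannot standardise an empty risk vector.")
  den <- switch(method,
                printed = max(r) + min(r),
                range = max(r) - min(r))
  if (den == 0) return(rep(0, length(r)))
  (r - min(r)) / den
}

# Split a query into characters, upper-cased; check length when known.
query_chars <- function(query, expected_length = NULL) {
  if (is.character(query) && length(query) == 1L) {
    query <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  } else {
    query <- toupper(as.character(query))
  }
  if (!is.null(expected_length) && length(query) != expected_length) {
    abort(sprintf("query length %d does not match alignment length %d.",
                  length(query), expected_length))
  }
  query
}

#' @export
tidy.ssa_assignment <- function(x, ...) {
  out <- as_tibble(x)
  out$query_id <- attr(x, "query_id")
  select(out, "query_id", "species", "posterior", "p_distance", "risk")
}

#' @export
glance.ssa_assignment <- function(x, ...) {
  tibble(query_id = attr(x, "query_id"),
         call = attr(x, "call"),
         ambiguous = attr(x, "ambiguous"),
         min_risk = min(x$risk),
         max_posterior = max(x$posterior))
}
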