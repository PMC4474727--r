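#' Leave-one-out cross-validation of barcode assignment
#'
#' Every sequence in the database is used once as a query against a database
#' from which it has been removed: profiles and segregating sites are rebuilt
#' without it, the minimum-risk assignment is made, and the call is scored.
#' A call is correct when the minimum-risk species matches the query's true
#' species, or — for singletons, whose species vanishes from the candidate
#' set once the sequence is held out — when the called species belongs to
#' the same genus. After each trial the risk row is range-standardised
#' (see [standardize_risk()]) so that trials are comparable; the standardised
#' rows are averaged per true species into a query-species by
#' candidate-species risk matrix.
#'
#' Two accuracies are reported: the fraction of sequences called correctly,
#' and the fraction of species for which a strict majority of their trials
#' were correct (a singleton's single trial stands for the species).
#'
#' @param db A [barcode_db()] with at least 2 species.
#' @param loss,alpha Passed to [assignment_risk()].
#' @param standardize Standardisation variant, see [standardize_risk()].
#' @return An object of class `ssa_loocv`: a list with `calls` (per-trial
#'   tibble), `n_species`, `seq_accuracy`, `species_accuracy` (over species
#'   with at least one scorable trial), `n_singletons`,
#'   `risk_matrix` (long tibble: `query_species`, `candidate_species`,
#'   `mean_std_risk`, `mean_raw_risk`) and the run parameters.
#' @export
ssa_loocv <- function(db, loss = c("query_consensus", "consensus_consensus"),
                      standardize = c("printed", "range"), alpha = 1) {
  loss <- match.arg(loss)
  standardize <- match.arg(standardize)
  db <- validate_barcode_db(db)
  if (length(unique(db$species)) < 2) {
    abort("leave-one-out validation needs a database with at least 2 species.")
  }
  sp_counts <- table(db$species)

  trials <- vector("list", nrow(db))
  risk_rows <- vector("list", nrow(db))
  for (i in seq_len(nrow(db))) {
    rest <- validate_barcode_db(db[-i, , drop = FALSE])
    true_sp <- db$species[i]
    singleton <- sp_counts[[true_sp]] == 1L
    if (length(unique(rest$species)) < 2) {
      warn(sprintf("trial for \"%s\" skipped: fewer than 2 candidate species remain.",
                   db$seq_id[i]))
      trials[[i]] <- tibble(seq_id = db$seq_id[i], true_species = true_sp,
                            called_species = NA_character_, singleton = singleton,
                            correct = NA, min_risk = NA_real_, ambiguous = NA)
      next
    }
    res <- assignment_risk(db$sequence[i], rest, query_id = db$seq_id[i],
                           loss = loss, alpha = alpha)
    called <- attr(res, "call")
    correct <- if (singleton) {
      genus_of(called) == genus_of(true_sp)
    } else {
      called == true_sp
    }
    trials[[i]] <- tibble(seq_id = db$seq_id[i], true_species = true_sp,
                          called_species = called, singleton = singleton,
                          correct = correct, min_risk = min(res$risk),
                          ambiguous = attr(res, "ambiguous"))
    risk_rows[[i]] <- tibble(seq_id = db$seq_id[i], query_species = true_sp,
                             candidate_species = res$species,
                             raw_risk = res$risk,
                             std_risk = standardize_risk(res$risk, method = standardize))
  }
  calls <- bind_rows(trials)
  risks <- bind_rows(risk_rows)

  per_species <- calls |>
    filter(!is.na(.data$correct)) |>
    group_by(.data$true_species) |>
    summarise(frac_correct = mean(.data$correct), .groups = "drop")

  risk_matrix <- risks |>
    group_by(.data$query_species, .data$candidate_species) |>
    summarise(mean_std_risk = mean(.data$std_risk),
              mean_raw_risk = mean(.data$raw_risk), .groups = "drop") |>
    arrange(.data$query_species, .data$candidate_species)

  structure(
    list(calls = calls,
         n_species = length(unique(db$species)),
         seq_accuracy = mean(calls$correct, na.rm = TRUE),
         species_accuracy = mean(per_species$frac_correct > 0.5),
         per_species = per_species,
         n_singletons = sum(sp_counts == 1L),
         risk_matrix = risk_matrix,
         loss = loss, standardize = standardize, alpha = alpha),
    class = "ssa_loocv"
  )
}

#' @export
print.ssa_loocv <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out barcode validation: %d sequences, %d species (%d singletons)\n",
    nrow(x$calls), x$n_species, x$n_singletons))
  cat(sprintf("  sequence-level accuracy: %.3f\n", x$seq_accuracy))
  cat(sprintf("  species-level accuracy:  %.3f\n", x$species_accuracy))
  invisible(x)
}

#' @export
tidy.ssa_loocv <- function(x, ...) x$calls

#' @export
glance.ssa_loocv <- function(x, ...) {
  tibble(n_seqs = nrow(x$calls),
         n_species = x$n_species,
         n_singletons = x$n_singletons,
         seq_accuracy = x$seq_accuracy,
         species_accuracy = x$species_accuracy)
}

#' Heat map of the standardised assignment-risk matrix
#'
#' Rows are query (true) species, columns candidate species; low risk (dark)
#' along the diagonal indicates reliable assignment.
#'
#' @param object An `ssa_loocv` result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ssa_loocv <- function(object, ...) {
  ggplot2::ggplot(object$risk_matrix,
                  ggplot2::aes(x = .data$candidate_species,
                               y = .data$query_species,
                               fill = .data$mean_std_risk)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "standardised risk") +
    ggplot2::labs(x = "candidate species", y = "query species") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
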