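#' Run the province phylogenetic-diversity pipeline
#'
#' Loads a Newick tree and a species-to-province table, computes the
#' inclusive/exclusive PD report for every requested province and the
#' Monte-Carlo rarefaction curve of each province's inclusive PD, and writes
#' the results to `out_dir`:
#'
#' * `pd_summary.json` — `{province: {pd_i, pd_e, ratio, n}}` plus run
#'   metadata (seed, flags, config hash);
#' * `rarefaction.csv` — columns
#'   `province,k,mean_pd,sd_pd,q05,q95,n_reps,seed`.
#'
#' The run is a pure function of its inputs and parameters: rerunning with
#' the same files and seed reproduces the outputs byte for byte.
#'
#' @param tree_file Path to the Newick tree.
#' @param province_file Path to the TSV annotation (`species<TAB>province`).
#' @param out_dir Output directory (created if needed).
#' @param provinces Provinces to analyse (default: all in the table).
#' @param n_reps Monte-Carlo pseudoreplicates per rarefaction point.
#' @param seed Integer seed.
#' @param keep_unannotated Keep leaves with no annotation (default: trim).
#' @param rooted PD convention passed to [pd_inclusive()].
#' @return Invisibly, a list with the report, the curves and the output
#'   paths.
#' @export
run_pd_pipeline <- function(tree_file, province_file, out_dir,
                            provinces = NULL, n_reps = 1000, seed = 1,
                            keep_unannotated = FALSE, rooted = TRUE) {
  for (f in c(tree_file, province_file)) {
    if (!file.exists(f)) {
      abort(sprintf("input file not found: %s", f), class = "barcodiv_input_error")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- read_newick(tree_file)
  map <- read_province_table(province_file)
  provinces <- provinces %||% sort(unique(map$province))
  config <- list(tree_file = tree_file, province_file = province_file,
                 provinces = provinces, n_reps = n_reps, seed = seed,
                 keep_unannotated = keep_unannotated, rooted = rooted)
  cfg_hash <- rlang::hash(config)

  report <- pd_report(tree, map, provinces = provinces,
                      keep_unannotated = keep_unannotated)

  # rarefy on the same (possibly trimmed) tree the report used
  matched <- match_provinces(tree, map)
  work_tree <- tree
  if (!keep_unannotated) {
    work_tree <- prune_to_group(tree, unique(matched$leaf[!is.na(matched$province)]))
  }
  curves <- bind_rows(lapply(seq_along(provinces), function(i) {
    p <- provinces[i]
    grp <- unique(matched$leaf[!is.na(matched$province) & matched$province == p])
    cv <- rarefy_pd(work_tree, grp, n_reps = n_reps, seed = seed + i - 1L)
    mutate(cv, province = p, .before = 1)
  }))

  json_path <- file.path(out_dir, "pd_summary.json")
  csv_path <- file.path(out_dir, "rarefaction.csv")
  summary <- setNames(
    lapply(seq_len(nrow(report)), function(i) {
      list(pd_i = report$pd_i[i], pd_e = report$pd_e[i],
           ratio = report$ratio[i], n = report$n[i])
    }),
    report$province
  )
  jsonlite::write_json(
    list(provinces = summary,
         meta = list(seed = seed, n_reps = n_reps, config_hash = cfg_hash,
                     keep_unannotated = keep_unannotated, rooted = rooted)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  readr::write_csv(format_floats(curves), csv_path, progress = FALSE)
  message(sprintf("pd pipeline: %d provinces, seed %d, config %s -> %s",
                  length(provinces), seed, cfg_hash, out_dir))
  invisible(list(report = report, curves = curves,
                 files = c(json_path, csv_path), config_hash = cfg_hash))
}

#' Run the barcode leave-one-out classification pipeline
#'
#' Loads an aligned barcode FASTA (`>seq_id|Genus_species` headers), runs
#' [ssa_loocv()] and writes to `out_dir`:
#'
#' * `loocv_calls.csv` — one row per trial (true/called species, singleton
#'   flag, correctness, minimum risk);
#' * `risk_matrix.csv` — query-species by candidate-species mean raw and
#'   standardised risks, rows and columns sorted by species name;
#' * `loocv_summary.json` — `{n_species, n_seqs, seq_accuracy,
#'   species_accuracy, n_singletons}` plus run metadata.
#'
#' @param fasta_file Path to the aligned FASTA database.
#' @param out_dir Output directory (created if needed).
#' @param loss,standardize,alpha Passed to [ssa_loocv()].
#' @param seed Recorded in the outputs (the validation itself is
#'   deterministic).
#' @return Invisibly, a list with the `ssa_loocv` object and output paths.
#' @export
run_barcoding_pipeline <- function(fasta_file, out_dir,
                                   loss = "query_consensus",
                                   standardize = "printed",
                                   alpha = 1, seed = 1) {
  if (!file.exists(fasta_file)) {
    abort(sprintf("input file not found: %s", fasta_file),
          class = "barcodiv_input_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  db <- read_barcode_fasta(fasta_file)
  config <- list(fasta_file = fasta_file, loss = loss,
                 standardize = standardize, alpha = alpha, seed = seed)
  cfg_hash <- rlang::hash(config)
  res <- ssa_loocv(db, loss = loss, standardize = standardize, alpha = alpha)

  calls_path <- file.path(out_dir, "loocv_calls.csv")
  matrix_path <- file.path(out_dir, "risk_matrix.csv")
  json_path <- file.path(out_dir, "loocv_summary.json")
  readr::write_csv(format_floats(res$calls), calls_path, progress = FALSE)
  readr::write_csv(format_floats(res$risk_matrix), matrix_path, progress = FALSE)
  jsonlite::write_json(
    list(n_species = res$n_species, n_seqs = nrow(res$calls),
         seq_accuracy = res$seq_accuracy,
         species_accuracy = res$species_accuracy,
         n_singletons = res$n_singletons,
         meta = list(seed = seed, config_hash = cfg_hash, loss = loss,
                     standardize = standardize, alpha = alpha)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  message(sprintf("barcoding pipeline: %d sequences, %d species, config %s -> %s",
                  nrow(res$calls), res$n_species, cfg_hash, out_dir))
  invisible(list(loocv = res, files = c(calls_path, matrix_path, json_path),
                 config_hash = cfg_hash))
}

# 6 significant digits for tabular float output, leaving other columns alone.
format_floats <- function(df) {
  df[] <- lapply(df, function(x) if (is.double(x)) signif(x, 6) else x)
  df
}
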