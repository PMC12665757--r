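# Candidate characterization: per-candidate predicted activities, similarity
# to the training set, and the physicochemical property panel, plus summary
# statistics over a report.

#' Build a candidate report
#'
#' One row per candidate with predicted per-receptor activity (blank when no
#' predictor is supplied), the highest similarity to any training sequence
#' with the best-match ID, and the full physicochemical profile. Rows are
#' sorted by descending mean predicted activity.
#'
#' @param candidates Character vector of sequences, list of `pep_tokens`, or
#'   tibble with a `sequence` column.
#' @param training_records Activity tibble used as the similarity reference.
#' @param predictor Optional function: list of `pep_tokens` -> n x 3
#'   probability matrix (see [predictor_from_models()]).
#' @param overrides Optional NSAA override tibble.
#' @return A tibble (class `candidate_report`).
#' @export
build_report <- function(candidates, training_records, predictor = NULL,
                         overrides = NULL) {
  token_lists <- if (is.data.frame(candidates)) {
    tokenize_all(candidates$sequence)
  } else if (is.character(candidates)) {
    tokenize_all(candidates)
  } else {
    candidates
  }
  if (length(token_lists) == 0) {
    return(structure(tibble::tibble(), class = c("candidate_report", "tbl_df",
                                                 "tbl", "data.frame")))
  }
  seqs <- vapply(token_lists, pep_detokenize, character(1))
  sims <- purrr::map(token_lists, similarity_to_set,
                     set_tokens = training_records$tokens)
  max_sim <- vapply(sims, max, numeric(1))
  best_id <- training_records$id[vapply(sims, which.max, integer(1))]
  props <- pep_properties(seqs, overrides)
  out <- tibble::tibble(
    sequence = seqs,
    GCGR_activity = NA_real_, GLP1R_activity = NA_real_,
    GIPR_activity = NA_real_,
    highest_similarity = max_sim,
    best_match_id = best_id,
    length = props$length,
    mol_weight = props$mol_weight,
    isoelectric = props$isoelectric,
    instability_index = props$instability_index,
    gravy = props$gravy,
    estimated_logP = props$est_logP,
    estimated_PSA = props$est_psa
  )
  if (!is.null(predictor)) {
    probs <- predictor(token_lists)
    out$GCGR_activity <- probs[, "GCGR"]
    out$GLP1R_activity <- probs[, "GLP1R"]
    out$GIPR_activity <- probs[, "GIPR"]
    out <- dplyr::arrange(
      out,
      dplyr::desc((GCGR_activity + GLP1R_activity + GIPR_activity) / 3)
    )
  }
  structure(out, class = c("candidate_report", class(out)))
}

#' Summarize a candidate report
#'
#' Mean, standard deviation and range of the length, activity and property
#' columns, plus presence counts of contiguous motifs.
#'
#' @param report A [build_report()] tibble (or any tibble with the same
#'   columns).
#' @param motifs Character vector of contiguous motifs to count.
#' @return List with `stats` (tibble: variable, mean, sd, min, max) and
#'   `motif_counts` (tibble: motif, count, n).
#' @export
summarize_report <- function(report, motifs = c("EGTF")) {
  if (nrow(report) == 0) stop("empty report", call. = FALSE)
  if (!"length" %in% names(report)) {
    report$length <- vapply(tokenize_all(report$sequence), length, integer(1))
  }
  num_cols <- intersect(
    c("length", "GCGR_activity", "GLP1R_activity", "GIPR_activity",
      "highest_similarity", "mol_weight", "isoelectric", "instability_index",
      "gravy", "estimated_logP", "estimated_PSA"),
    names(report)
  )
  stats_tbl <- tidyr::pivot_longer(report[num_cols], dplyr::everything(),
                                   names_to = "variable") |>
    dplyr::group_by(variable) |>
    dplyr::summarise(
      mean = mean(value, na.rm = TRUE),
      sd = stats::sd(value, na.rm = TRUE),
      min = suppressWarnings(min(value, na.rm = TRUE)),
      max = suppressWarnings(max(value, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(variable, num_cols))
  counts <- tibble::tibble(
    motif = motifs,
    count = vapply(motifs, function(m) {
      count_motif_occurrences(report$sequence, m)
    }, integer(1), USE.NAMES = FALSE),
    n = nrow(report)
  )
  list(stats = stats_tbl, motif_counts = counts)
}

#' Write a candidate report
#'
#' CSV at display precision alongside a JSON file keeping full precision.
#'
#' @param report A candidate report tibble.
#' @param path CSV path (the JSON lands next to it with extension `.json`).
#' @export
write_report <- function(report, path) {
  disp <- report
  for (col in c("GCGR_activity", "GLP1R_activity", "GIPR_activity")) {
    if (col %in% names(disp)) disp[[col]] <- round(disp[[col]], 5)
  }
  for (col in c("mol_weight")) {
    if (col %in% names(disp)) disp[[col]] <- round(disp[[col]], 2)
  }
  for (col in c("isoelectric")) {
    if (col %in% names(disp)) disp[[col]] <- round(disp[[col]], 5)
  }
  for (col in c("instability_index", "gravy", "estimated_logP")) {
    if (col %in% names(disp)) disp[[col]] <- round(disp[[col]], 4)
  }
  readr::write_csv(disp, path, na = "")
  jsonlite::write_json(report, sub("\\.csv$", ".json", path), digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Load the packaged reference candidate panel
#'
#' A 20-candidate panel of designed triple-agonist peptides with published
#' predicted activities, training-set similarities and physicochemical
#' properties, used as a golden fixture for the property pipeline and for
#' summary statistics.
#'
#' @return A tibble.
#' @export
reference_candidates <- function() {
  path <- system.file("extdata", "reference_candidates.csv",
                      package = "triagonist")
  readr::read_csv(path, col_types = readr::cols(
    sequence = readr::col_character(), .default = readr::col_double()
  ))
}
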