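#' Derive binary activity labels from EC50 values
#'
#' Potencies below the threshold define the high-affinity (positive) class;
#' values at or above it the low-affinity class. The default threshold is
#' 1000 pM with strict `<` for the positive class; both are configurable.
#'
#' @param ec50 Numeric vector of EC50 values in pM (`NA` = not measured).
#' @param threshold Positive class boundary in pM.
#' @param strict If `TRUE` (default) the positive class is `ec50 < threshold`,
#'   otherwise `ec50 <= threshold`.
#' @return Integer vector of 1 (high affinity), 0 (low affinity) or `NA`.
#' @examples
#' label_from_ec50(c(22.6, 1000, NA))
#' @export
label_from_ec50 <- function(ec50, threshold = 1000, strict = TRUE) {
  if (any(ec50 < 0, na.rm = TRUE)) {
    stop("EC50 values must be non-negative", call. = FALSE)
  }
  pos <- if (strict) ec50 < threshold else ec50 <= threshold
  as.integer(ifelse(is.na(ec50), NA, pos))
}

#' Read a peptide activity table
#'
#' Reads a CSV with columns `id`, `sequence`, `EC50_GCGR`, `EC50_GLP1R`,
#' `EC50_GIPR` (blank cells = not measured), validates every sequence through
#' the tokenizer, and derives per-receptor binary labels.
#'
#' @param path CSV file path.
#' @param threshold,strict Passed to [label_from_ec50()].
#' @param quiet Suppress the per-receptor label count message.
#' @return A tibble with columns `id`, `sequence`, `tokens` (list of
#'   `pep_tokens`), `EC50_<receptor>` and `label_<receptor>`.
#' @export
read_activity_table <- function(path, threshold = 1000, strict = TRUE, quiet = FALSE) {
  df <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    sequence = readr::col_character(),
    .default = readr::col_double()
  ))
  required <- c("id", "sequence", paste0("EC50_", RECEPTORS))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("activity table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    dups <- unique(df$id[duplicated(df$id)])
    stop("duplicated peptide IDs: ", paste(dups, collapse = ", "), call. = FALSE)
  }
  validate_records(df, threshold = threshold, strict = strict, quiet = quiet)
}

# Shared validation/labeling for freshly read or generated tables
validate_records <- function(df, threshold = 1000, strict = TRUE, quiet = TRUE) {
  tokens <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    tokens[[i]] <- tryCatch(
      pep_tokenize(df$sequence[i]),
      error = function(e) {
        stop(sprintf("row %d (id %s): %s", i, df$id[i], conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  out <- tibble::as_tibble(df)
  out$tokens <- tokens
  for (r in RECEPTORS) {
    out[[paste0("label_", r)]] <-
      label_from_ec50(out[[paste0("EC50_", r)]], threshold, strict)
  }
  if (!quiet) {
    counts <- vapply(RECEPTORS, function(r) sum(!is.na(out[[paste0("label_", r)]])),
                     integer(1))
    message("labelled records: ",
            paste(sprintf("%s %d/%d", RECEPTORS, counts, nrow(out)), collapse = ", "))
  }
  cols <- c("id", "sequence", "tokens",
            paste0("EC50_", RECEPTORS), paste0("label_", RECEPTORS))
  out[, c(cols, setdiff(names(out), cols))]
}

#' Write a peptide activity table
#'
#' Inverse of [read_activity_table()]: writes the `id`, `sequence` and EC50
#' columns back to CSV (labels are derived, not stored).
#'
#' @param records Activity tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(records, path) {
  out <- records[, c("id", "sequence", paste0("EC50_", RECEPTORS))]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read/write plain sequence lists as FASTA
#'
#' NSAA bracket tokens are kept inline on the sequence line, which is
#' non-standard FASTA but preserves the token grammar; each record stays on a
#' single line for the same reason.
#'
#' @param path File path.
#' @return `read_sequences_fasta`: tibble with `id` and `sequence`.
#' @export
read_sequences_fasta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("^>\\s*", "", lines[headers])
  ends <- c(headers[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(headers), function(i) {
    paste0(lines[(headers[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  tibble::tibble(id = ids, sequence = seqs)
}

#' @rdname read_sequences_fasta
#' @param ids,sequences Record identifiers and sequence strings.
#' @export
write_sequences_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  writeLines(as.vector(rbind(paste0(">", ids), sequences)), path)
  invisible(path)
}
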