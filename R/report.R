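# Report writers and the two end-to-end drivers (score / calibrate) the
# command-line interface wraps.

report_columns <- c(
  "model_number", "hal_chain", "hal_residue_name", "hal_residue_seq",
  "hal_atom", "hal_element", "compound_class", "acceptor_kind", "acc_chain",
  "acc_residue_name", "acc_residue_seq", "acc_atom", "neighbor_atom",
  "acceptor_class", "d", "vdw_overlap", "theta1", "theta2",
  "score_distance", "score_theta1", "score_theta2", "halbs",
  "classification", "unscored_reason"
)

#' Write a scored-bond report
#'
#' Formats: `"tsv"` (one row per bond; distances and overlaps to 2
#' decimals Å, angles to 1 decimal degree, scores to 2 decimals; footer
#' comment lines enumerate unscored categories), `"json"` (nested
#' per-model report at full precision), `"mmcif"` (a namespaced
#' `_halbs_summary` key-value block carrying the per-model bond count and
#' mean HalBS).
#'
#' @param scored A `halbs_scores` tibble (typically the selected bonds).
#' @param path Output path, or `NULL` to return the lines invisibly
#'   (stdout-friendly).
#' @param format `"tsv"`, `"json"` or `"mmcif"`.
#' @param block_name Data block name for the mmCIF format.
#' @return The report lines, invisibly; written to `path` when given.
#' @export
write_bond_report <- function(scored, path = NULL,
                              format = c("tsv", "json", "mmcif"),
                              block_name = "model") {
  format <- match.arg(format)
  summ <- summarize_model(scored)
  lines <- switch(format,
    tsv = report_tsv(scored),
    json = report_json(scored, summ),
    mmcif = report_mmcif(summ, block_name)
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", sprintf(sprintf("%%.%df", digits), x))
}

report_tsv <- function(scored) {
  df <- tidy_report_frame(scored)
  out <- df |>
    mutate(
      across(c("d", "vdw_overlap"), ~fmt_num(.x, 2L)),
      across(c("theta1", "theta2"), ~fmt_num(.x, 1L)),
      across(c("score_distance", "score_theta1", "score_theta2", "halbs"),
             ~fmt_num(.x, 2L))
    )
  body <- readr::format_tsv(out)
  body <- strsplit(body, "\n", fixed = TRUE)[[1]]
  unscored <- unique(df$unscored_reason[!is.na(df$unscored_reason)])
  footer <- if (length(unscored)) paste0("# warning: ", unscored) else character()
  c(body, footer)
}

report_json <- function(scored, summ) {
  df <- tidy_report_frame(scored)
  payload <- list(
    model = list(halogen_bond_count = summ$n_bonds,
                 mean_halbs = summ$mean_halbs),
    bonds = df,
    warnings = unique(df$unscored_reason[!is.na(df$unscored_reason)])
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null",
                   pretty = TRUE)
}

report_mmcif <- function(summ, block_name) {
  c(
    paste0("data_", block_name),
    "#",
    sprintf("_halbs_summary.halogen_bond_count %d", summ$n_bonds),
    sprintf("_halbs_summary.mean_halbs %s",
            if (is.na(summ$mean_halbs)) "?" else sprintf("%.2f", summ$mean_halbs)),
    "#"
  )
}

tidy_report_frame <- function(scored) {
  df <- as_tibble(as.data.frame(scored))
  for (col in setdiff(report_columns, names(df))) df[[col]] <- NA
  df[report_columns]
}

#' Read back a TSV bond report
#'
#' @param path Report path (as written by [write_bond_report()]).
#' @return A tibble of the report rows (footer warnings dropped).
#' @export
read_bond_report <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  na = "NA", progress = FALSE)
}

#' Score a structure end to end
#'
#' Reads a structure, detects halogen-bond candidates, scores them
#' against a reference table, selects the reported bond per halogen and
#' summarises the model. A structure without halogens is a successful
#' run with a zero-bond summary, not an error.
#'
#' @param input Path to an mmCIF/PDB file, or a `halbs_structure`.
#' @param stats Reference statistics (default: the packaged synthetic
#'   table, [reference_stats()]).
#' @param dictionary Optional compound dictionary.
#' @param output Optional report path.
#' @param format Report format for `output` (see [write_bond_report()]).
#' @param all_candidates Report all scored candidates instead of the
#'   per-halogen best bond.
#' @param ... Passed to [detect_halogen_bonds()].
#' @return A list: `candidates` (all scored candidates), `bonds`
#'   (selected best bonds), `summary` (per-model count and mean HalBS).
#' @export
run_score <- function(input, stats = reference_stats(), dictionary = NULL,
                      output = NULL, format = c("tsv", "json", "mmcif"),
                      all_candidates = FALSE, ...) {
  format <- match.arg(format)
  st <- if (inherits(input, "halbs_structure")) input else read_structure(input)
  cand <- detect_halogen_bonds(st, dictionary = dictionary, ...)
  scored <- score_bonds(cand, stats)
  bonds <- select_best_bond(scored)
  summ <- summarize_model(bonds)
  if (!is.null(output)) {
    write_bond_report(if (all_candidates) scored else bonds, output, format)
  }
  list(candidates = scored, bonds = bonds, summary = summ)
}

#' Calibrate a corpus end to end
#'
#' Wraps [calibrate()] with file output: writes the reference-statistics
#' table (loadable by [run_score()]) and, optionally, the per-category
#' observation-count summary.
#'
#' @param corpus,metadata,rscc,thresholds,... As in [calibrate()].
#' @param output Optional reference-statistics TSV path.
#' @param counts_output Optional per-category counts TSV path.
#' @return The `halbs_calibration` object, invisibly.
#' @export
run_calibrate <- function(corpus, metadata = NULL, rscc = NULL,
                          thresholds = quality_thresholds(), output = NULL,
                          counts_output = NULL, ...) {
  cal <- calibrate(corpus, metadata = metadata, rscc = rscc,
                   thresholds = thresholds, ...)
  if (!is.null(output)) {
    if (nrow(cal$stats)) write_reference_stats(cal$stats, output)
    else { warn("run_calibrate(): empty statistics table"); readr::write_tsv(cal$stats, output) }
  }
  if (!is.null(counts_output)) readr::write_tsv(cal$counts, counts_output)
  invisible(cal)
}
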