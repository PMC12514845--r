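#' Read a reference-statistics table
#'
#' Reads the columnar reference file consumed by [score_bonds()]: one row
#' per (halogen, acceptor class, parameter) with boxplot statistics.
#' Cells with a non-positive IQR (`q3 <= q1`) are dropped with a warning —
#' the score is undefined for them — and categories with fewer than
#' `min_n` observations are dropped likewise.
#'
#' @param path Path to a TSV with columns `halogen`, `acceptor_class`,
#'   `parameter` (`distance`/`theta1`/`theta2`), `n`, `mean`, `median`,
#'   `q1`, `q3`, `mad`.
#' @param min_n Minimum observations per category (default 5).
#' @return A validated reference-statistics tibble.
#' @export
read_reference_stats <- function(path, min_n = 5L) {
  stats <- readr::read_tsv(path, show_col_types = FALSE,
                           comment = "#", progress = FALSE)
  req <- c("halogen", "acceptor_class", "parameter", "n", "mean", "median",
           "q1", "q3", "mad")
  miss <- setdiff(req, names(stats))
  if (length(miss)) {
    abort(sprintf("reference statistics file '%s' lacks column(s): %s",
                  path, paste(miss, collapse = ", ")))
  }
  stats$halogen <- toupper(stats$halogen)
  bad_iqr <- stats$q3 <= stats$q1
  if (any(bad_iqr)) {
    warn(sprintf("dropping %d reference cell(s) with non-positive IQR", sum(bad_iqr)))
    stats <- stats[!bad_iqr, ]
  }
  small <- stats$n < min_n
  if (any(small)) {
    warn(sprintf("dropping %d reference cell(s) with fewer than %d observations",
                 sum(small), min_n))
    stats <- stats[!small, ]
  }
  validate_reference_stats(stats)
  as_tibble(stats)
}

validate_reference_stats <- function(stats) {
  if (!all(stats$parameter %in% c("distance", "theta1", "theta2"))) {
    abort("reference statistics: parameter must be distance, theta1 or theta2")
  }
  if (!all(stats$halogen %in% .HALOGENS)) {
    abort("reference statistics: halogen must be one of F, CL, BR, I")
  }
  if (!all(stats$acceptor_class %in% c(.ACCEPTOR_CLASSES, "other"))) {
    abort(sprintf("reference statistics: unknown acceptor class(es): %s",
                  paste(setdiff(unique(stats$acceptor_class), .ACCEPTOR_CLASSES),
                        collapse = ", ")))
  }
  if (any(stats$q3 <= stats$q1)) {
    abort("reference statistics: Q3 must exceed Q1 in every cell")
  }
  if (any(stats$q1 > stats$median | stats$median > stats$q3)) {
    abort("reference statistics: require q1 <= median <= q3")
  }
  invisible(stats)
}

#' Write a reference-statistics table
#'
#' @param stats Reference-statistics tibble (as produced by [calibrate()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reference_stats <- function(stats, path) {
  validate_reference_stats(stats)
  readr::write_tsv(stats, path)
  invisible(path)
}

#' Packaged synthetic reference statistics
#'
#' The demonstration reference table shipped with the package
#' (`extdata/reference_stats_synthetic.tsv`). Its quartiles are
#' \strong{synthetic}: they are constructed from the per-category medians,
#' expected angle ranges and observation counts reported for the PDB-REDO
#' ligand-protein halogen-bond corpus, not from that corpus itself.
#' It exercises every scoring path (including the absent C-I···Trp
#' category) and is suitable for demonstrations and testing; for research
#' use, derive a table from your own corpus with [calibrate()] and pass it
#' to [score_bonds()].
#'
#' @return A reference-statistics tibble.
#' @export
reference_stats <- function() {
  path <- system.file("extdata", "reference_stats_synthetic.tsv",
                      package = "halbs", mustWork = TRUE)
  suppressWarnings(read_reference_stats(path))
}
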