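#' Quality thresholds for calibration
#'
#' Defaults are the published filter: halogen B-factor ≤ 100 Å²,
#' real-space correlation coefficient (RSCC) of both the halogen-bearing
#' and the acceptor-bearing compound ≥ 0.9, resolution ≤ 2.5 Å, and at
#' least 5 observations per category.
#'
#' @param max_b_factor Å² (reject strictly above).
#' @param min_rscc Fraction (reject strictly below).
#' @param max_resolution Å (reject strictly above, i.e. worse).
#' @param min_category_n Minimum observations per reference cell.
#' @return A list of thresholds.
#' @export
quality_thresholds <- function(max_b_factor = 100, min_rscc = 0.9,
                               max_resolution = 2.5, min_category_n = 5L) {
  stopifnot(max_b_factor > 0, min_rscc > 0, max_resolution > 0,
            min_category_n > 0)
  list(max_b_factor = max_b_factor, min_rscc = min_rscc,
       max_resolution = max_resolution,
       min_category_n = as.integer(min_category_n))
}

#' Apply the calibration quality filter to candidates
#'
#' Marks each candidate keep/reject against the B-factor, RSCC and
#' resolution thresholds. Calibration demands verified data: a candidate
#' whose metadata is missing for any criterion is rejected with reason
#' `"unverifiable"`. Thresholds are boundary-inclusive (B = 100,
#' RSCC = 0.9, resolution = 2.5 all keep).
#'
#' @param candidates Candidate tibble (needs `hal_b_factor`).
#' @param meta One-row model metadata tibble with `resolution`.
#' @param rscc Per-compound RSCC tibble with columns `chain_id`,
#'   `residue_seq`, `rscc`, or `NULL` (everything unverifiable).
#' @param thresholds From [quality_thresholds()].
#' @return The candidates with logical `keep` and character
#'   `reject_reason` (`NA` when kept) columns appended.
#' @export
quality_filter <- function(candidates, meta, rscc = NULL,
                           thresholds = quality_thresholds()) {
  lookup_rscc <- function(chain, seq) {
    if (is.null(rscc) || !nrow(rscc)) return(NA_real_)
    hit <- rscc$rscc[rscc$chain_id == chain & rscc$residue_seq == seq]
    if (length(hit)) hit[1] else NA_real_
  }
  res <- if (nrow(meta)) meta$resolution[1] else NA_real_
  out <- candidates |>
    mutate(
      rscc_halogen = purrr::map2_dbl(.data$hal_chain, .data$hal_residue_seq, lookup_rscc),
      rscc_acceptor = purrr::map2_dbl(.data$acc_chain, .data$acc_residue_seq, lookup_rscc),
      reject_reason = dplyr::case_when(
        is.na(.data$hal_b_factor) | is.na(res) |
          is.na(.data$rscc_halogen) | is.na(.data$rscc_acceptor) ~ "unverifiable",
        .data$hal_b_factor > thresholds$max_b_factor ~ "b_factor",
        .data$rscc_halogen < thresholds$min_rscc |
          .data$rscc_acceptor < thresholds$min_rscc ~ "rscc",
        res > thresholds$max_resolution ~ "resolution",
        TRUE ~ NA_character_
      ),
      keep = is.na(.data$reject_reason)
    )
  out
}

#' Restrict candidates to ligand-to-protein interactions
#'
#' Calibration uses only halogen atoms in ligands (compounds typed
#' non-polymer) whose acceptor is a canonical amino acid. Modified
#' residues (e.g. diiodotyrosine) and ligand-to-ligand contacts are
#' excluded here, although scoring still handles them.
#'
#' @param candidates Candidate tibble.
#' @return The filtered tibble.
#' @export
restrict_to_ligand_protein <- function(candidates) {
  dplyr::filter(candidates,
                .data$compound_class == "ligand",
                .data$acc_residue_name %in% .CANONICAL_AA)
}

#' Boxplot statistics of one reference cell
#'
#' Computes n, mean, median, Q1, Q3 and the median absolute deviation
#' (MAD, unscaled: `median(|v - median|)`). Quartiles use linear
#' interpolation between closest ranks by default
#' (`stats::quantile(type = 7)`); the estimator is configurable because
#' Q1/Q3 feed the geometric score directly.
#'
#' @param values Numeric measurements.
#' @param min_n Minimum observations; fewer returns a zero-row tibble
#'   (the cell is omitted, mirroring the absent C-I···Trp category).
#' @param type Quartile estimator, passed to [stats::quantile()].
#' @return A tibble with columns `n`, `mean`, `median`, `q1`, `q3`, `mad`
#'   (one row, or zero rows when `n < min_n`).
#' @examples
#' boxplot_stats(c(1, 2, 3, 4, 5))
#' @export
boxplot_stats <- function(values, min_n = 5L, type = 7L) {
  values <- values[!is.na(values)]
  if (length(values) < min_n) {
    return(tibble(n = integer(), mean = double(), median = double(),
                  q1 = double(), q3 = double(), mad = double()))
  }
  q <- unname(quantile(values, probs = c(0.25, 0.75), type = type))
  med <- median(values)
  tibble(n = length(values), mean = mean(values), median = med,
         q1 = q[1], q3 = q[2], mad = median(abs(values - med)))
}

#' Derive reference statistics from a structure corpus
#'
#' Runs the full calibration pipeline the way the reference corpus was
#' mined: per entry, detect candidates ([detect_halogen_bonds()]),
#' restrict to ligand-to-protein pairs, apply the quality filter, keep
#' one acceptor per halogen (theta1 closest to 180°,
#' [select_mining_acceptor()]); then pool observations per
#' (halogen × acceptor class × parameter) and compute boxplot statistics.
#' Cells with fewer than `thresholds$min_category_n` observations or zero
#' IQR are omitted with a warning.
#'
#' @param corpus A named list of `halbs_structure` objects (or a character
#'   vector of file paths; names become entry identifiers, defaulting to
#'   file base names).
#' @param metadata Model-level metadata tibble: `entry_id`, `resolution`
#'   (optionally `r_factor`, `r_free`, `mean_b`). Entries absent here fall
#'   back to the metadata read from the structure file.
#' @param rscc Per-compound RSCC tibble: `entry_id`, `chain_id`,
#'   `residue_seq`, `rscc`.
#' @param thresholds From [quality_thresholds()].
#' @param quartile_type Quartile estimator (see [boxplot_stats()]).
#' @param dictionary Optional compound dictionary shared by all entries.
#' @param ... Passed to [detect_halogen_bonds()].
#' @return A `halbs_calibration` object: list with `stats` (the reference
#'   table, loadable by [score_bonds()]), `counts` (per halogen ×
#'   acceptor-class observation counts), `attrition` (per-filter rejection
#'   counts) and `observations` (the pooled per-bond table).
#' @export
calibrate <- function(corpus, metadata = NULL, rscc = NULL,
                      thresholds = quality_thresholds(), quartile_type = 7L,
                      dictionary = NULL, ...) {
  if (is.character(corpus)) {
    nm <- names(corpus) %||% tools::file_path_sans_ext(basename(corpus))
    corpus <- setNames(lapply(corpus, read_structure), nm)
  }
  if (is.null(names(corpus)) || any(names(corpus) == "")) {
    names(corpus) <- sprintf("entry%04d", seq_along(corpus))
  }
  if (!length(corpus)) {
    warn("calibrate(): empty corpus; returning empty table")
  }

  per_entry <- purrr::imap(corpus, function(st, id) {
    cand <- detect_halogen_bonds(st, dictionary = dictionary, ...)
    if (!nrow(cand)) return(NULL)
    cand <- restrict_to_ligand_protein(cand)
    if (!nrow(cand)) return(NULL)
    meta <- if (!is.null(metadata) && id %in% metadata$entry_id) {
      dplyr::filter(metadata, .data$entry_id == id)
    } else if (inherits(st, "halbs_structure")) st$metadata else tibble(resolution = NA_real_)
    rs <- if (!is.null(rscc)) dplyr::filter(rscc, .data$entry_id == id) else NULL
    mutate(quality_filter(cand, meta, rs, thresholds), entry_id = id)
  })
  obs <- list_rbind(keep(per_entry, Negate(is.null)))

  attrition <- if (nrow(obs)) {
    obs |>
      group_by(.data$reject_reason) |>
      summarise(n = n(), .groups = "drop") |>
      mutate(reject_reason = dplyr::coalesce(.data$reject_reason, "kept"))
  } else tibble(reject_reason = character(), n = integer())

  kept <- dplyr::filter(obs, .data$keep)
  selected <- select_mining_acceptor(kept)

  long <- selected |>
    select("entry_id", "hal_element", "acceptor_class", "acceptor_kind",
           "d", "theta1", "theta2") |>
    rename(distance = "d") |>
    tidyr::pivot_longer(c("distance", "theta1", "theta2"),
                        names_to = "parameter", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))

  stats <- long |>
    group_by(halogen = .data$hal_element, .data$acceptor_class,
             .data$parameter) |>
    dplyr::reframe(boxplot_stats(.data$value, min_n = thresholds$min_category_n,
                                 type = quartile_type))
  zero_iqr <- stats$q3 <= stats$q1
  if (any(zero_iqr)) {
    warn(sprintf("calibrate(): omitting %d cell(s) with non-positive IQR",
                 sum(zero_iqr)))
    stats <- stats[!zero_iqr, ]
  }

  counts <- selected |>
    group_by(.data$acceptor_class, halogen = .data$hal_element) |>
    summarise(n = n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "halogen", values_from = "n",
                       values_fill = 0L)

  structure(list(stats = as_tibble(stats), counts = counts,
                 attrition = attrition, observations = selected,
                 thresholds = thresholds),
            class = "halbs_calibration")
}

#' @export
print.halbs_calibration <- function(x, ...) {
  cat(sprintf("<halbs_calibration> %d reference cell(s), %d observation(s)\n",
              nrow(x$stats), nrow(x$observations)))
  print(x$counts)
  invisible(x)
}

#' @export
tidy.halbs_calibration <- function(x, ...) x$stats

#' @export
glance.halbs_calibration <- function(x, ...) {
  tibble(n_cells = nrow(x$stats),
         n_observations = nrow(x$observations),
         n_categories = nrow(dplyr::distinct(x$stats, .data$halogen,
                                             .data$acceptor_class)))
}

#' Plot calibrated reference distributions
#'
#' Box ranges (Q1–median–Q3) per halogen and acceptor class, one facet
#' per geometric parameter.
#'
#' @param object A `halbs_calibration` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.halbs_calibration <- function(object, ...) {
  ggplot2::ggplot(object$stats,
                  ggplot2::aes(x = .data$halogen, ymin = .data$q1,
                               y = .data$median, ymax = .data$q3,
                               colour = .data$acceptor_class)) +
    ggplot2::geom_crossbar(position = ggplot2::position_dodge(width = 0.7),
                           width = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "acceptor") +
    ggplot2::theme_minimal()
}
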