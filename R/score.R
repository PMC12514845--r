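#' Geometric outlier score of one parameter (box-and-whisker units)
#'
#' Scores a measured geometric parameter against reference quartiles:
#' \deqn{Score_{geom} = \max\left(\frac{value - Q3}{IQR},\;
#'   \frac{Q1 - value}{IQR},\; 0\right)}
#' with \eqn{IQR = Q3 - Q1}. The score is 0 everywhere inside the
#' interquartile box (edges included) and grows by 1 per IQR outside it, so
#' the boxplot whisker endpoint (1.5 IQR beyond a quartile) scores exactly
#' 1.5.
#'
#' @param value Measured value(s); units follow the quartiles.
#' @param q1,q3 First and third reference quartiles (`q3 > q1` required).
#' @return Dimensionless score(s) ≥ 0.
#' @examples
#' score_geom(15, 10, 20) # inside the box
#' score_geom(35, 10, 20) # 1.5 IQR above Q3: the whisker endpoint
#' score_geom(4, 10, 20)  # 0.6 IQR below Q1
#' @export
score_geom <- function(value, q1, q3) {
  if (any(!is.na(q1) & !is.na(q3) & q3 <= q1)) {
    abort("score_geom(): Q3 must exceed Q1 (zero or negative IQR is a calibration error)")
  }
  iqr <- q3 - q1
  pmax((value - q3) / iqr, (q1 - value) / iqr, 0)
}

#' Classify a HalBS value
#'
#' `0` → `"preferred"` (every parameter inside its reference box),
#' `(0, 1.5]` → `"allowed"` (within the whiskers), `> 1.5` → `"outlier"`
#' (at least one parameter beyond the 1.5 × IQR whisker). Boundaries are
#' exact: a score of exactly 1.5 is still allowed.
#'
#' @param halbs_value Numeric vector of HalBS values (≥ 0; `NA` allowed
#'   and propagated).
#' @return Character vector in `{"preferred", "allowed", "outlier"}`.
#' @examples
#' classify_halbs(c(0, 1.5, 1.63))
#' @export
classify_halbs <- function(halbs_value) {
  if (any(halbs_value < 0, na.rm = TRUE)) {
    abort("classify_halbs(): scores are non-negative by construction")
  }
  dplyr::case_when(
    is.na(halbs_value) ~ NA_character_,
    halbs_value == 0 ~ "preferred",
    halbs_value <= 1.5 ~ "allowed",
    TRUE ~ "outlier"
  )
}

stats_wide <- function(stats) {
  validate_reference_stats(stats)
  stats |>
    select("halogen", "acceptor_class", "parameter", "q1", "q3") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = c("q1", "q3"))
}

#' Score halogen-bond candidates with HalBS
#'
#' Applies the per-parameter geometric score ([score_geom()]) to every
#' candidate — distance and theta1 always, theta2 for atomic acceptors —
#' and combines them as
#' \deqn{HalBS = \max(Score_{distance}, Score_{\theta_1}[, Score_{\theta_2}])}
#' the least favourable geometric feature of the bond. Candidates whose
#' (halogen, acceptor-class) category has no reference statistics (for
#' example C–I···Trp) are reported with their geometry but `halbs = NA`
#' and an explicit `unscored_reason`; they are never silently dropped.
#' Acceptors with several covalent neighbours contribute the theta2 with
#' the lowest theta2 score.
#'
#' @param candidates Candidate tibble from [detect_halogen_bonds()].
#' @param stats Reference statistics tibble
#'   (see [read_reference_stats()]; default [reference_stats()], the
#'   packaged synthetic demonstration table).
#' @return A `halbs_scores` tibble: the candidate columns plus
#'   `score_distance`, `score_theta1`, `score_theta2`, `halbs`,
#'   `classification`, `unscored_reason`.
#' @export
score_bonds <- function(candidates, stats = reference_stats()) {
  sw <- stats_wide(stats)
  ensure <- function(col) if (col %in% names(sw)) sw[[col]] else rep(NA_real_, nrow(sw))
  sw$q1_theta2 <- ensure("q1_theta2"); sw$q3_theta2 <- ensure("q3_theta2")

  scored <- candidates |>
    mutate(halogen = .data$hal_element) |>
    left_join(sw, by = c("halogen", "acceptor_class")) |>
    mutate(
      has_dist = !is.na(.data$q1_distance) & !is.na(.data$q3_distance),
      has_t1 = !is.na(.data$q1_theta1) & !is.na(.data$q3_theta1),
      has_t2 = !is.na(.data$q1_theta2) & !is.na(.data$q3_theta2),
      needs_t2 = .data$acceptor_kind == "atomic" & !is.na(.data$theta2),
      scorable = .data$has_dist & .data$has_t1 & (!.data$needs_t2 | .data$has_t2),
      score_distance = if_else(.data$scorable,
        score_geom(.data$d, .data$q1_distance, .data$q3_distance), NA_real_),
      score_theta1 = if_else(.data$scorable,
        score_geom(.data$theta1, .data$q1_theta1, .data$q3_theta1), NA_real_),
      score_theta2 = if_else(.data$scorable & .data$needs_t2,
        score_geom(.data$theta2, .data$q1_theta2, .data$q3_theta2), NA_real_)
    )

  # collapse multi-neighbour acceptors (e.g. Met SD): keep the neighbour
  # with the lowest theta2 score; ties by listed neighbour order
  scored <- scored |>
    group_by(.data$model_number, .data$hal_chain, .data$hal_residue_name,
             .data$hal_residue_seq, .data$hal_ins_code, .data$hal_atom,
             .data$acceptor_kind, .data$acc_chain, .data$acc_residue_name,
             .data$acc_residue_seq, .data$acc_ins_code, .data$acc_atom) |>
    arrange(.data$score_theta2, .data$neighbor_rank, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()

  scored <- scored |>
    mutate(
      halbs = if_else(.data$scorable,
        pmax(.data$score_distance, .data$score_theta1,
             dplyr::coalesce(.data$score_theta2, 0)),
        NA_real_),
      classification = classify_halbs(.data$halbs),
      unscored_reason = if_else(.data$scorable, NA_character_,
        sprintf("no reference statistics for category %s-%s",
                .data$hal_element, .data$acceptor_class))
    ) |>
    select(-dplyr::starts_with("q1_"), -dplyr::starts_with("q3_"),
           -"has_dist", -"has_t1", -"has_t2", -"needs_t2", -"scorable",
           -"halogen") |>
    arrange(.data$model_number, .data$hal_chain, .data$hal_residue_seq,
            .data$hal_ins_code, .data$hal_atom, .data$acceptor_kind,
            .data$acc_chain, .data$acc_residue_seq, .data$acc_ins_code,
            .data$acc_atom)
  class(scored) <- c("halbs_scores", class(scored))
  scored
}

#' Select the reported bond for each halogen
#'
#' When several halogen bonds are possible for one halogen atom (atomic
#' and π combined), the bond with the lowest HalBS is selected and
#' reported. Exact ties prefer the atomic acceptor over the π acceptor,
#' then the shorter distance, then acceptor chain/residue order. A halogen
#' whose candidates are all unscorable keeps one representative row with
#' `halbs = NA` so the geometry is still reported.
#'
#' @param scored A `halbs_scores` tibble.
#' @return A `halbs_scores` tibble with one row per halogen atom.
#' @export
select_best_bond <- function(scored) {
  if (!nrow(scored)) return(scored)
  out <- scored |>
    group_by(.data$model_number, .data$hal_chain, .data$hal_residue_name,
             .data$hal_residue_seq, .data$hal_ins_code, .data$hal_atom) |>
    arrange(is.na(.data$halbs), .data$halbs,
            .data$acceptor_kind != "atomic", .data$d, .data$acc_chain,
            .data$acc_residue_seq, .data$acc_ins_code, .data$acc_atom,
            .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  class(out) <- unique(c("halbs_scores", class(out)))
  out
}

#' Per-model halogen-bond summary
#'
#' Counts the selected (scored) halogen bonds of a model and averages
#' their HalBS; the mean is reported missing (`NA`) when there are no
#' scored bonds. Unscorable candidates never enter the mean.
#'
#' @param selected_bonds A `halbs_scores` tibble, typically from
#'   [select_best_bond()].
#' @return A one-row tibble: `n_bonds`, `mean_halbs`.
#' @export
summarize_model <- function(selected_bonds) {
  scored <- selected_bonds$halbs[!is.na(selected_bonds$halbs)]
  tibble(
    n_bonds = length(scored),
    mean_halbs = if (length(scored)) mean(scored) else NA_real_
  )
}

#' @export
tidy.halbs_scores <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "halbs_scores")
  as_tibble(out)
}

#' @export
glance.halbs_scores <- function(x, ...) {
  best <- select_best_bond(x)
  summ <- summarize_model(best)
  tibble(
    n_candidates = nrow(x),
    n_halogens = nrow(best),
    n_bonds = summ$n_bonds,
    mean_halbs = summ$mean_halbs,
    n_outliers = sum(best$classification == "outlier", na.rm = TRUE)
  )
}

#' Broom-style tidiers
#'
#' `tidy()` returns the underlying tibble of a result object; `glance()`
#' returns a one-row summary.
#'
#' @param x A result object (`halbs_scores` or `halbs_calibration`).
#' @param ... Unused.
#' @name halbs-tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname halbs-tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot scored halogen bonds
#'
#' One point per bond: HalBS against the bond label, coloured by
#' classification, with the outlier threshold (1.5) drawn.
#'
#' @param object A `halbs_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.halbs_scores <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(!is.na(.data$halbs)) |>
    mutate(label = sprintf("%s %s%d %s ·· %s %s%d",
                           .data$hal_residue_name, .data$hal_chain,
                           .data$hal_residue_seq, .data$hal_atom,
                           .data$acc_residue_name, .data$acc_chain,
                           .data$acc_residue_seq))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$halbs,
                                   y = stats::reorder(.data$label, .data$halbs),
                                   colour = .data$classification)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 1.5, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(preferred = "#1b7837",
                                            allowed = "#fdae61",
                                            outlier = "#d73027")) +
    ggplot2::labs(x = "HalBS", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
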