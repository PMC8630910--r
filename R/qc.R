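#' Transform CT values to expression values
#'
#' Expression is the number of PCR cycles above the threshold cycle:
#' `total_cycles - ct` for detected reactions, so higher numbers mean more
#' transcript. CT values at or above the limit of detection, and missing CTs,
#' are scored non-detected and assigned expression 0.
#'
#' @param ct Long-form CT tibble (see [read_ct_matrix()]).
#' @param total_cycles Number of cycles in the PCR reaction (default 40).
#' @param lod Limit-of-detection CT (default 28).
#' @return The tibble with `ct` replaced by `expression`.
#' @export
ct_to_expression <- function(ct, total_cycles = 40, lod = 28) {
  validate_ct(ct)
  assert_scalar_number(total_cycles, "total_cycles", lower = 1)
  assert_scalar_number(lod, "lod", lower = 0)
  if (lod >= total_cycles) {
    abort("`lod` must be smaller than `total_cycles`", class = "monoqtl_config_error")
  }
  ct |>
    mutate(expression = if_else(!is.na(.data$ct) & .data$ct < lod,
                                total_cycles - .data$ct, 0)) |>
    select(-"ct")
}

#' Flag cells with excessive failure scores
#'
#' The failure score of a cell is its total CT across all assays; missing CTs
#' contribute `total_cycles` by default so that low-yield cells are penalised.
#' Cells scoring more than `k_sd` standard deviations above the mean are
#' flagged for exclusion. Statistics are computed per capture run
#' (individual x cell type) by default, or globally.
#'
#' @param ct Long-form CT tibble.
#' @param k_sd Number of standard deviations above the mean (default 2).
#' @param total_cycles Cycle count used for missing CTs.
#' @param missing_as `"total_cycles"` (default) or `"zero"`: contribution of a
#'   missing CT to the score.
#' @param scope `"run"` (per individual x cell type, default) or `"global"`.
#' @return A tibble with one row per cell: `cell_id`, `individual_id`,
#'   `cell_type`, `failure_score`, `flagged`.
#' @export
failure_score_filter <- function(ct, k_sd = 2, total_cycles = 40,
                                 missing_as = c("total_cycles", "zero"),
                                 scope = c("run", "global")) {
  validate_ct(ct)
  missing_as <- match.arg(missing_as)
  scope <- match.arg(scope)
  fill <- if (missing_as == "total_cycles") total_cycles else 0
  scores <- ct |>
    group_by(.data$cell_id, .data$individual_id, .data$cell_type) |>
    summarise(failure_score = sum(if_else(is.na(.data$ct), fill, .data$ct)),
              .groups = "drop")
  if (nrow(scores) < 3) abort("failure-score filter needs at least 3 cells")
  if (scope == "run") {
    scores <- scores |>
      group_by(.data$individual_id, .data$cell_type) |>
      mutate(cutoff = mean(.data$failure_score) + k_sd * sd(.data$failure_score)) |>
      ungroup()
  } else {
    scores$cutoff <- mean(scores$failure_score) + k_sd * sd(scores$failure_score)
  }
  scores <- scores |>
    mutate(flagged = !is.na(.data$cutoff) & .data$failure_score > .data$cutoff) |>
    select(-"cutoff")
  if (all(scores$flagged)) abort("all cells flagged by the failure-score filter")
  scores
}

#' Keep only singlet cells
#'
#' Drops cells whose capture well was scored a doublet or empty on microscopy.
#'
#' @param ct Long-form CT tibble with a `capture_flag` column.
#' @return The tibble restricted to singlet cells. Warns if none remain.
#' @export
exclude_nonsinglets <- function(ct) {
  validate_ct(ct)
  out <- filter(ct, .data$capture_flag == "singlet")
  if (nrow(out) == 0) warn("no singlet cells remain after capture-flag filtering")
  out
}

#' Proportion of cells with detected expression, per group and gene
#'
#' @param expr Expression tibble from [ct_to_expression()].
#' @param group_by Grouping: `"individual"`, `"individual_celltype"` or
#'   `"cell_type"`.
#' @return A tibble with the grouping columns plus `gene`, `n_cells`,
#'   `on_proportion`.
#' @export
on_proportions <- function(expr,
                           group_by = c("individual", "individual_celltype", "cell_type")) {
  assert_cols(expr, c("individual_id", "cell_type", "gene", "expression"), "expression data")
  group_by <- match.arg(group_by)
  keys <- switch(group_by,
    individual = "individual_id",
    individual_celltype = c("individual_id", "cell_type"),
    cell_type = "cell_type"
  )
  expr |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "gene")))) |>
    summarise(n_cells = dplyr::n(),
              on_proportion = mean(.data$expression > 0),
              .groups = "drop")
}

#' Identify genes saturating the detection channel
#'
#' Genes whose on-proportion, averaged across individuals, strictly exceeds
#' the threshold carry almost no dropout signal and are excluded from the
#' logistic (on/off) analysis only.
#'
#' @param expr Expression tibble.
#' @param threshold Average on-proportion above which a gene is dropped
#'   (default 0.98; the rule is a strict `>`).
#' @return A tibble with `gene`, `mean_on_proportion`, `dropped`.
#' @export
drop_saturated_genes <- function(expr, threshold = 0.98) {
  on_proportions(expr, group_by = "individual") |>
    group_by(.data$gene) |>
    summarise(mean_on_proportion = mean(.data$on_proportion), .groups = "drop") |>
    mutate(dropped = .data$mean_on_proportion > threshold)
}

#' Detect person-level on/off expression patterns
#'
#' Flags genes with a binary per-person expression pattern: some individuals'
#' cells essentially never express the gene while other individuals' cells
#' mostly do (the IRF1-type pattern). An individual is "off" when their
#' on-proportion is at most `low` and "on" when it is at least `high`.
#'
#' @param expr Expression tibble.
#' @param low,high On-proportion cutoffs for the off and on states.
#' @param min_individuals Minimum number of individuals required in each
#'   state for a gene to be flagged.
#' @return A tibble with `gene`, `n_off`, `n_on`, `n_mixed`, `flagged`, and a
#'   list-column `per_individual` of per-person on-proportions and states.
#' @export
detect_on_off_genes <- function(expr, low = 0.0, high = 0.5, min_individuals = 2) {
  props <- on_proportions(expr, group_by = "individual") |>
    mutate(status = dplyr::case_when(
      .data$on_proportion <= low ~ "off",
      .data$on_proportion >= high ~ "on",
      TRUE ~ "mixed"
    ))
  n_ind <- n_distinct(props$individual_id)
  if (n_ind < 2 * min_individuals) {
    abort(sprintf("need at least %d individuals to call on/off patterns", 2 * min_individuals))
  }
  counts <- props |>
    group_by(.data$gene) |>
    summarise(
      n_off = sum(.data$status == "off"),
      n_on = sum(.data$status == "on"),
      n_mixed = sum(.data$status == "mixed"),
      .groups = "drop"
    ) |>
    mutate(flagged = .data$n_off >= min_individuals & .data$n_on >= min_individuals)
  nested <- props |>
    select("gene", "individual_id", "on_proportion", "status") |>
    tidyr::nest(per_individual = c("individual_id", "on_proportion", "status"))
  left_join(counts, nested, by = "gene")
}
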