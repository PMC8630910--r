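#' Cross-cell-type eQTL sharing bookkeeping
#'
#' Classifies each significant (SNP, gene) pair as exclusive to classical
#' (CL) monocytes, exclusive to non-classical (NCL) monocytes, or shared. A
#' pair is shared when it meets the significance cutoff in both subsets *and*
#' the direction of association agrees; a pair significant in both subsets
#' with opposite directions is counted exclusive in each and flagged
#' discordant. Within each cell type, transcripts associated with more than
#' one SNP are also reported (the cross-SNP convergence view).
#'
#' When a pair is retained by several methods in the same cell type, its
#' canonical direction comes from the method with the smallest FDR q (ties:
#' smallest p).
#'
#' @param results An eQTL result tibble (from [run_eqtl_scan()] or read from
#'   disk). If a `retained` column is present only retained rows are used;
#'   otherwise, if `fdr_q` is present, rows with `fdr_q < fdr_q` are used;
#'   otherwise all rows are treated as significant. A missing `direction`
#'   column is treated as all-`+`.
#' @param fdr_q Significance cutoff when filtering on `fdr_q`.
#' @return A `sharing_summary`: list with `overall` (counts), `per_snp`,
#'   `pairs` (per-pair classification with directions), `discordant_pairs`,
#'   `multi_snp_transcripts` and `method_counts`.
#' @export
sharing_analysis <- function(results, fdr_q = 0.1) {
  assert_cols(results, c("rsid", "gene", "cell_type", "method"), "eQTL results")
  sig <- results
  if ("retained" %in% names(sig)) {
    sig <- filter(sig, .data$retained)
  } else if ("fdr_q" %in% names(sig)) {
    sig <- filter(sig, !is.na(.data$fdr_q), .data$fdr_q < fdr_q)
  }
  if (!"direction" %in% names(sig)) sig$direction <- "+"
  if (!"fdr_q" %in% names(sig)) sig$fdr_q <- NA_real_
  if (!"p_value" %in% names(sig)) sig$p_value <- NA_real_

  # canonical record per (rsid, gene, cell_type): best-FDR method
  canonical <- sig |>
    group_by(.data$rsid, .data$gene, .data$cell_type) |>
    arrange(.data$fdr_q, .data$p_value, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()

  pairs <- canonical |>
    select("rsid", "gene", "cell_type", "method", "direction") |>
    tidyr::pivot_wider(names_from = "cell_type",
                       values_from = c("direction", "method"),
                       names_sep = ".")
  # guarantee both direction columns exist even if one cell type has no hits
  for (col in c("direction.CL", "direction.NCL", "method.CL", "method.NCL")) {
    if (!col %in% names(pairs)) pairs[[col]] <- NA_character_
  }
  pairs <- pairs |>
    mutate(
      in_cl = !is.na(.data$direction.CL),
      in_ncl = !is.na(.data$direction.NCL),
      concordant = .data$in_cl & .data$in_ncl &
        .data$direction.CL == .data$direction.NCL &
        .data$direction.CL != "undefined",
      status = dplyr::case_when(
        .data$concordant ~ "shared",
        .data$in_cl & .data$in_ncl ~ "discordant",
        .data$in_cl ~ "CL_exclusive",
        TRUE ~ "NCL_exclusive"
      )
    ) |>
    select("rsid", "gene", "status", "direction.CL", "direction.NCL",
           "method.CL", "method.NCL")

  overall <- tibble(
    n_records = nrow(sig),
    n_pairs = nrow(pairs),
    n_cl_hits = sum(pairs$status %in% c("CL_exclusive", "shared", "discordant")),
    n_ncl_hits = sum(pairs$status %in% c("NCL_exclusive", "shared", "discordant")),
    n_shared = sum(pairs$status == "shared"),
    n_discordant = sum(pairs$status == "discordant"),
    n_cl_exclusive = sum(pairs$status %in% c("CL_exclusive", "discordant")),
    n_ncl_exclusive = sum(pairs$status %in% c("NCL_exclusive", "discordant"))
  )

  per_snp <- pairs |>
    group_by(.data$rsid) |>
    summarise(
      n_shared = sum(.data$status == "shared"),
      n_cl_exclusive = sum(.data$status %in% c("CL_exclusive", "discordant")),
      n_ncl_exclusive = sum(.data$status %in% c("NCL_exclusive", "discordant")),
      .groups = "drop"
    )

  multi_snp <- canonical |>
    distinct(.data$cell_type, .data$gene, .data$rsid) |>
    group_by(.data$cell_type, .data$gene) |>
    summarise(n_snps = dplyr::n(),
              rsids = paste(sort(.data$rsid), collapse = ","),
              .groups = "drop") |>
    filter(.data$n_snps > 1)

  method_counts <- sig |>
    count(.data$method, name = "n_records") |>
    arrange(dplyr::desc(.data$n_records))

  structure(
    list(overall = overall, per_snp = per_snp, pairs = pairs,
         discordant_pairs = filter(pairs, .data$status == "discordant"),
         multi_snp_transcripts = multi_snp, method_counts = method_counts),
    class = "sharing_summary"
  )
}

#' @export
print.sharing_summary <- function(x, ...) {
  o <- x$overall
  cat("<sharing_summary>\n")
  cat(sprintf("  %d significant records over %d SNP-gene pairs\n", o$n_records, o$n_pairs))
  cat(sprintf("  shared: %d | CL-exclusive: %d | NCL-exclusive: %d | discordant: %d\n",
              o$n_shared, o$n_cl_exclusive, o$n_ncl_exclusive, o$n_discordant))
  if (nrow(x$multi_snp_transcripts) > 0) {
    cat(sprintf("  transcripts hit by multiple SNPs: %s\n",
                paste(unique(x$multi_snp_transcripts$gene), collapse = ", ")))
  }
  invisible(x)
}

#' @describeIn sharing_analysis Overall sharing counts as a one-row tibble.
#' @param x A `sharing_summary`.
#' @param ... Unused.
#' @method tidy sharing_summary
#' @export
tidy.sharing_summary <- function(x, ...) x$overall

#' Exact binomial test of the observed eQTL sharing proportion
#'
#' Two-sided exact binomial test of the number of shared (SNP, gene) pairs
#' against a null sharing proportion.
#'
#' @param n_shared Number of shared pairs.
#' @param n_distinct_pairs Total number of distinct significant pairs.
#' @param null_prop Null sharing proportion (default 0.5).
#' @return The two-sided p-value.
#' @export
sharing_test <- function(n_shared, n_distinct_pairs, null_prop = 0.5) {
  if (n_distinct_pairs <= 0) abort("no significant pairs: sharing test undefined")
  if (n_shared < 0 || n_shared > n_distinct_pairs) {
    abort("n_shared must lie between 0 and n_distinct_pairs")
  }
  binom.test(n_shared, n_distinct_pairs, p = null_prop)$p.value
}

#' Exact binomial test of the CL/NCL eQTL count imbalance
#'
#' Two-sided exact binomial test of the NCL share of significant eQTLs
#' against 0.5.
#'
#' @param n_cl_hits,n_ncl_hits Significant eQTL counts per cell type.
#' @return The two-sided p-value.
#' @export
celltype_imbalance_test <- function(n_cl_hits, n_ncl_hits) {
  total <- n_cl_hits + n_ncl_hits
  if (total <= 0) abort("no eQTLs: imbalance test undefined")
  binom.test(n_ncl_hits, total, p = 0.5)$p.value
}
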