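#' Benjamini-Hochberg adjustment with a retention cutoff
#'
#' Step-up BH-adjusted q-values (monotone by construction) and the retention
#' mask `fdr_q < q`. Missing p-values are excluded from the correction and
#' propagate as missing, never retained.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (may contain `NA`).
#' @param q FDR retention cutoff (default 0.1).
#' @return A tibble with `p_value`, `fdr_q`, `retained`.
#' @export
bh_fdr <- function(p_values, q = 0.1) {
  if (length(p_values) == 0) {
    return(tibble(p_value = numeric(), fdr_q = numeric(), retained = logical()))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble(p_value = p_values, fdr_q = adj,
         retained = !is.na(adj) & adj < q)
}

#' Bonferroni significance threshold for a SNP-by-gene scan
#'
#' @param n_genes,n_snps Number of genes and SNPs tested.
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / (n_genes * n_snps)`.
#' @examples
#' bonferroni_threshold(90, 7) # 7.94e-5
#' @export
bonferroni_threshold <- function(n_genes, n_snps, alpha = 0.05) {
  if (n_genes <= 0 || n_snps <= 0) abort("comparison counts must be positive")
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  alpha / (n_genes * n_snps)
}

#' Run the full eQTL scan across SNPs, genes, cell types and methods
#'
#' Fits every (SNP, gene, cell type, method) combination on QC'd expression
#' data, then applies Benjamini-Hochberg FDR separately within each
#' (cell type, method) family. A (SNP, gene, cell type) pair counts as an
#' eQTL when at least one method retains it; every passing method is
#' recorded. Genes whose average on-proportion exceeds
#' `saturation_threshold` are excluded from the logistic method only.
#' Non-convergent or skipped fits never enter the FDR ranks; their reasons
#' are tallied in the `"scan_log"` attribute.
#'
#' @param expr Expression tibble from [ct_to_expression()] (post-QC).
#' @param genotypes Long genotype tibble from [read_genotypes()]; every
#'   individual present in `expr` must appear.
#' @param methods Methods to run, a subset of `"tweedie"`, `"logistic"`,
#'   `"gaussian_nonzero"`, `"proportion_anova"`, `"naive_mw"` (the last is
#'   only meant for calibration comparisons).
#' @param fdr_q FDR retention cutoff (default 0.1).
#' @param saturation_threshold On-proportion cutoff for the logistic-only
#'   saturated-gene drop (default 0.98).
#' @param tweedie_power Optional fixed Tweedie power index.
#' @return A tibble with one row per rsid x gene x cell_type x method:
#'   `estimate`, `std_error`, `p_value`, `fdr_q`, `retained`, `direction`
#'   (`+`/`-`/`undefined`), `n_individuals`, `n_cells`, `converged`,
#'   `reason`. Attribute `"scan_log"` tallies fits by outcome.
#' @export
run_eqtl_scan <- function(expr, genotypes,
                          methods = c("tweedie", "logistic", "gaussian_nonzero",
                                      "proportion_anova"),
                          fdr_q = 0.1, saturation_threshold = 0.98,
                          tweedie_power = NULL) {
  assert_cols(expr, c("cell_id", "individual_id", "cell_type", "gene", "expression"),
              "expression data")
  assert_cols(genotypes, c("individual_id", "rsid", "dosage"), "genotype table")
  methods <- match.arg(methods, c("tweedie", "logistic", "gaussian_nonzero",
                                  "proportion_anova", "naive_mw"),
                       several.ok = TRUE)
  missing_ind <- setdiff(unique(expr$individual_id), unique(genotypes$individual_id))
  if (length(missing_ind) > 0) {
    abort(sprintf("individuals without genotypes: %s",
                  paste(head(missing_ind, 5), collapse = ", ")),
          class = "monoqtl_validation_error")
  }
  genes <- unique(expr$gene)
  rsids <- unique(genotypes$rsid)
  cell_types <- unique(expr$cell_type)
  if (length(genes) == 0) {
    out <- empty_scan_result()
    attr(out, "scan_log") <- tibble(cell_type = character(), method = character(),
                                    n_fit = integer(), n_converged = integer())
    return(out)
  }

  rows <- vector("list", length(cell_types) * length(genes) * length(rsids) * length(methods))
  k <- 0L
  for (ct_level in cell_types) {
    expr_ct <- filter(expr, .data$cell_type == ct_level)
    saturated <- drop_saturated_genes(expr_ct, saturation_threshold)
    saturated_genes <- saturated$gene[saturated$dropped]
    for (g in genes) {
      d_g <- filter(expr_ct, .data$gene == g)
      for (rs in rsids) {
        dos <- genotypes |>
          filter(.data$rsid == rs) |>
          select("individual_id", "dosage")
        d <- dplyr::inner_join(d_g, dos, by = "individual_id")
        for (m in methods) {
          fit <- if (m == "logistic" && g %in% saturated_genes) {
            skipped_fit("logistic", "saturated_gene",
                        n_distinct(d$individual_id), nrow(d))
          } else {
            tryCatch(fit_one_method(d, m, tweedie_power),
                     error = function(e) {
                       skipped_fit(m, paste0("error: ", conditionMessage(e)),
                                   n_distinct(d$individual_id), nrow(d))
                     })
          }
          k <- k + 1L
          rows[[k]] <- dplyr::bind_cols(
            tibble(rsid = rs, gene = g, cell_type = ct_level),
            tidy(fit)
          )
        }
      }
    }
  }
  q_cut <- fdr_q
  res <- bind_rows(rows[seq_len(k)])
  res <- res |>
    group_by(.data$cell_type, .data$method) |>
    mutate(fdr_q = {
      eligible <- .data$converged & !is.na(.data$p_value)
      qv <- rep(NA_real_, dplyr::n())
      qv[eligible] <- p.adjust(.data$p_value[eligible], method = "BH")
      qv
    }) |>
    ungroup() |>
    mutate(
      retained = !is.na(.data$fdr_q) & .data$fdr_q < q_cut,
      direction = sign_label(.data$estimate)
    ) |>
    select("rsid", "gene", "cell_type", "method", "estimate", "std_error",
           "p_value", "fdr_q", "retained", "direction", "n_individuals",
           "n_cells", "converged", "reason")
  log <- res |>
    group_by(.data$cell_type, .data$method) |>
    summarise(n_fit = dplyr::n(),
              n_converged = sum(.data$converged),
              n_skipped = sum(!.data$converged),
              n_retained = sum(.data$retained),
              .groups = "drop")
  attr(res, "scan_log") <- log
  res
}

fit_one_method <- function(d, method, tweedie_power = NULL) {
  switch(method,
    tweedie = fit_tweedie_mixed(d, power = tweedie_power),
    logistic = fit_logistic_mixed(d),
    gaussian_nonzero = fit_gaussian_nonzero_mixed(d),
    proportion_anova = fit_proportion_anova(d),
    naive_mw = fit_naive_mw(d),
    abort(sprintf("unknown method: %s", method))
  )
}

empty_scan_result <- function() {
  tibble(
    rsid = character(), gene = character(), cell_type = character(),
    method = character(), estimate = numeric(), std_error = numeric(),
    p_value = numeric(), fdr_q = numeric(), retained = logical(),
    direction = character(), n_individuals = integer(), n_cells = integer(),
    converged = logical(), reason = character()
  )
}

#' Naive per-cell Mann-Whitney eQTL scan
#'
#' Runs the per-cell Mann-Whitney U comparison (major-allele homozygote cells
#' vs minor-allele-carrier cells) over every SNP x gene x cell type. Cells
#' are treated as independent units, deliberately ignoring the within-person
#' correlation; this scan exists only to demonstrate the resulting type I
#' error inflation and should not be used for discovery.
#'
#' @inheritParams run_eqtl_scan
#' @return A result tibble as from [run_eqtl_scan()] with method
#'   `"naive_mw"`.
#' @export
naive_mw_scan <- function(expr, genotypes, fdr_q = 0.1) {
  run_eqtl_scan(expr, genotypes, methods = "naive_mw", fdr_q = fdr_q)
}

#' Significant hits in a compact, publication-style layout
#'
#' @param results Result tibble from [run_eqtl_scan()].
#' @return Retained records only, with columns `rsid`, `gene`
#'   (associated transcript), `method`, `cell_type`, `direction`, `fdr_q`.
#' @export
significant_hits <- function(results) {
  assert_cols(results, c("rsid", "gene", "cell_type", "method", "retained"),
              "eQTL results")
  results |>
    filter(.data$retained) |>
    arrange(.data$cell_type, .data$rsid, .data$gene) |>
    select(dplyr::any_of(c("rsid", "gene", "method", "cell_type", "direction", "fdr_q")))
}
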