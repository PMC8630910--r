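#' Read a single-cell qPCR CT matrix
#'
#' Reads a Fluidigm-style export: one row per cell, one column per assayed
#' gene, values are threshold cycles (CT). Cell metadata (`cell_id`,
#' `individual_id`, `cell_type`, `capture_flag`) may sit in leading columns of
#' the same file or in a sidecar table joined on `cell_id`. Values matching a
#' configurable sentinel list (instrument software commonly writes `999` for
#' failed reactions) and unparseable cells become missing.
#'
#' @param path Path to a CSV/TSV file. The delimiter is inferred from the
#'   extension (`.tsv`/`.txt` are tab-delimited) unless `delim` is given.
#' @param meta Optional cell metadata: either a path to a CSV/TSV file or a
#'   data frame, with columns `cell_id`, `individual_id`, `cell_type`,
#'   `capture_flag`. When supplied, `path` must contain only `cell_id` plus
#'   gene columns.
#' @param missing_codes Character vector of CT encodings treated as
#'   non-detected/missing (besides empty cells).
#' @param delim Field delimiter override.
#' @return A tibble in long form with columns `cell_id`, `individual_id`,
#'   `cell_type`, `capture_flag`, `gene`, `ct` (`NA` = missing CT).
#' @seealso [write_ct_matrix()], [ct_to_expression()]
#' @export
read_ct_matrix <- function(path, meta = NULL, missing_codes = c("", "NA", "999"),
                           delim = NULL) {
  raw <- read_table_file(path, delim)
  if (!is.null(meta)) {
    meta_df <- if (is.data.frame(meta)) as_tibble(meta) else read_table_file(meta, delim)
    assert_cols(meta_df, c("cell_id", "individual_id", "cell_type", "capture_flag"),
                "cell metadata")
    assert_cols(raw, "cell_id", "CT matrix")
    unknown <- setdiff(raw$cell_id, meta_df$cell_id)
    if (length(unknown) > 0) {
      abort(sprintf("cells without metadata: %s", paste(head(unknown, 5), collapse = ", ")),
            class = "monoqtl_format_error")
    }
    raw <- left_join(raw, meta_df[c("cell_id", "individual_id", "cell_type", "capture_flag")],
                     by = "cell_id")
  }
  meta_cols <- c("cell_id", "individual_id", "cell_type", "capture_flag")
  assert_cols(raw, meta_cols, "CT matrix")
  gene_cols <- names(raw)[!names(raw) %in% meta_cols] # keep duplicates visible
  if (length(gene_cols) == 0) abort("no gene columns found", class = "monoqtl_format_error")
  if (anyDuplicated(gene_cols)) {
    abort(sprintf("duplicate gene name(s): %s",
                  paste(unique(gene_cols[duplicated(gene_cols)]), collapse = ", ")),
          class = "monoqtl_validation_error")
  }
  if (anyDuplicated(raw$cell_id)) {
    abort("duplicate cell_id values", class = "monoqtl_validation_error")
  }
  ct <- raw |>
    tidyr::pivot_longer(dplyr::all_of(gene_cols), names_to = "gene", values_to = "ct_raw") |>
    mutate(
      ct_raw = trimws(as.character(.data$ct_raw)),
      ct = suppressWarnings(as.numeric(.data$ct_raw)),
      ct = if_else(is.na(.data$ct_raw) | .data$ct_raw %in% missing_codes,
                   NA_real_, .data$ct)
    ) |>
    select(-"ct_raw")
  validate_ct(ct)
  ct$gene <- factor(ct$gene, levels = gene_cols)
  ct <- arrange(ct, .data$cell_id, .data$gene)
  ct$gene <- as.character(ct$gene)
  ct
}

validate_ct <- function(ct) {
  assert_cols(ct, c("cell_id", "individual_id", "cell_type", "capture_flag", "gene", "ct"),
              "CT data")
  bad_type <- setdiff(unique(ct$cell_type), CELL_TYPES)
  if (length(bad_type) > 0) {
    abort(sprintf("cell_type must be one of %s; found: %s",
                  paste(CELL_TYPES, collapse = "/"), paste(bad_type, collapse = ", ")),
          class = "monoqtl_validation_error")
  }
  bad_flag <- setdiff(unique(ct$capture_flag), CAPTURE_FLAGS)
  if (length(bad_flag) > 0) {
    abort(sprintf("capture_flag must be one of %s; found: %s",
                  paste(CAPTURE_FLAGS, collapse = "/"), paste(bad_flag, collapse = ", ")),
          class = "monoqtl_validation_error")
  }
  if (any(ct$ct < 0, na.rm = TRUE)) {
    abort("CT values must be missing or >= 0", class = "monoqtl_validation_error")
  }
  invisible(ct)
}

#' Write a CT matrix to disk in wide (cells x genes) form
#'
#' @param ct Long-form CT tibble as returned by [read_ct_matrix()].
#' @param path Output path; delimiter inferred from the extension.
#' @param missing_code String written for missing CT values.
#' @return `path`, invisibly.
#' @export
write_ct_matrix <- function(ct, path, missing_code = "NA") {
  validate_ct(ct)
  wide <- ct |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct") |>
    arrange(.data$cell_id)
  write_table_file(wide, path, na = missing_code)
  invisible(path)
}

#' Read a per-individual SNP genotype table
#'
#' One row per individual, one column per SNP (rsID), entries the minor-allele
#' dosage 0/1/2. Allele labels and locus names, if available, are carried as
#' per-SNP metadata only; all models work on the dosage.
#'
#' @param path Path to a CSV/TSV file with an `individual_id` column followed
#'   by one column per rsID.
#' @param snp_meta Optional per-SNP metadata: path or data frame with columns
#'   `rsid` and any of `locus`, `major_allele`, `minor_allele`; attached as the
#'   `"snp_meta"` attribute.
#' @param delim Field delimiter override.
#' @return A long tibble with columns `individual_id`, `rsid`, `dosage`.
#' @export
read_genotypes <- function(path, snp_meta = NULL, delim = NULL) {
  raw <- read_table_file(path, delim)
  if (nrow(raw) == 0) abort("genotype file has no rows", class = "monoqtl_format_error")
  assert_cols(raw, "individual_id", "genotype table")
  rsids <- names(raw)[names(raw) != "individual_id"]
  if (length(rsids) == 0) abort("no SNP columns found", class = "monoqtl_format_error")
  if (anyDuplicated(rsids)) abort("duplicate rsID columns", class = "monoqtl_validation_error")
  if (anyDuplicated(raw$individual_id)) {
    abort("duplicated individual_id in genotype table", class = "monoqtl_validation_error")
  }
  geno <- raw |>
    tidyr::pivot_longer(dplyr::all_of(rsids), names_to = "rsid", values_to = "dosage_raw") |>
    mutate(dosage = suppressWarnings(as.numeric(.data$dosage_raw)))
  bad <- geno$dosage_raw[is.na(geno$dosage) | !geno$dosage %in% c(0, 1, 2)]
  if (length(bad) > 0) {
    abort(sprintf("dosages must be 0, 1 or 2; found: %s",
                  paste(unique(head(bad, 5)), collapse = ", ")),
          class = "monoqtl_validation_error")
  }
  geno <- geno |>
    mutate(dosage = as.integer(.data$dosage)) |>
    select("individual_id", "rsid", "dosage")
  if (!is.null(snp_meta)) {
    meta_df <- if (is.data.frame(snp_meta)) as_tibble(snp_meta) else read_table_file(snp_meta, delim)
    assert_cols(meta_df, "rsid", "SNP metadata")
    attr(geno, "snp_meta") <- meta_df
  }
  geno
}

#' Write a genotype table in wide (individuals x SNPs) form
#'
#' @param genotypes Long genotype tibble as returned by [read_genotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  assert_cols(genotypes, c("individual_id", "rsid", "dosage"), "genotype table")
  wide <- tidyr::pivot_wider(genotypes, names_from = "rsid", values_from = "dosage")
  write_table_file(wide, path)
  invisible(path)
}

#' Write an eQTL result table as TSV with fixed column order
#'
#' @param results Result tibble from [run_eqtl_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eqtl_results <- function(results, path) {
  cols <- c("rsid", "gene", "cell_type", "method", "estimate", "std_error",
            "p_value", "fdr_q", "retained", "direction", "n_individuals",
            "n_cells", "converged", "reason")
  assert_cols(results, cols, "eQTL results")
  readr::write_tsv(results[cols], path)
  invisible(path)
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' the expected Hardy-Weinberg proportions computed from the sample allele
#' frequency. For a monomorphic SNP the statistic is 0 and a warning is
#' emitted.
#'
#' @param n_hom_major,n_het,n_hom_minor Observed genotype counts.
#' @return A one-row tibble with `chi_square`, `p_value`, `maf`, `n`.
#' @examples
#' hwe_test(25, 50, 25) # exact HWE proportions: chi-square 0
#' @export
hwe_test <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(is.na(counts))) abort("counts must be non-negative")
  n <- sum(counts)
  if (n <= 0) abort("total genotype count must be positive")
  maf <- (n_het + 2 * n_hom_minor) / (2 * n)
  if (maf == 0 || maf == 1) {
    warn("monomorphic SNP: Hardy-Weinberg statistic is 0 by convention")
    return(tibble(chi_square = 0, p_value = 1, maf = maf, n = n))
  }
  expected <- n * c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  chi_square <- sum((counts - expected)^2 / expected)
  tibble(
    chi_square = chi_square,
    p_value = pchisq(chi_square, df = 1, lower.tail = FALSE),
    maf = maf,
    n = n
  )
}

# -- file plumbing -----------------------------------------------------------

read_table_file <- function(path, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- delim %||% infer_delim(path)
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    na = character(), name_repair = "minimal",
                    progress = FALSE, show_col_types = FALSE)
}

write_table_file <- function(df, path, na = "NA") {
  readr::write_delim(df, path, delim = infer_delim(path), na = na)
}

infer_delim <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}
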