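#' Configuration for an end-to-end pipeline run
#'
#' Validated up front, before any data are read; the full configuration is
#' echoed into the output directory alongside the run manifest.
#'
#' @param ct_path Path to the CT matrix file.
#' @param genotype_path Path to the genotype table.
#' @param out_dir Output directory (created if needed).
#' @param meta_path Optional sidecar cell-metadata path.
#' @param lod,total_cycles CT limit of detection and PCR cycle count.
#' @param failure_sd Failure-score cutoff in standard deviations.
#' @param methods eQTL methods to run.
#' @param fdr_q FDR retention cutoff.
#' @param loading_threshold Absolute-loading module cutoff.
#' @param pcs Components used for module extraction.
#' @param missing_codes CT sentinel strings treated as missing.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic given the inputs).
#' @return A `run_config` list.
#' @export
run_config <- function(ct_path, genotype_path, out_dir, meta_path = NULL,
                       lod = 28, total_cycles = 40, failure_sd = 2,
                       methods = c("tweedie", "logistic", "gaussian_nonzero",
                                   "proportion_anova"),
                       fdr_q = 0.1, loading_threshold = 0.7, pcs = 1,
                       missing_codes = c("", "NA", "999"), seed = 1) {
  if (lod >= total_cycles) {
    abort("`lod` must be smaller than `total_cycles`", class = "monoqtl_config_error")
  }
  assert_scalar_number(fdr_q, "fdr_q", lower = 0, upper = 1)
  assert_scalar_number(failure_sd, "failure_sd", lower = 0)
  methods <- match.arg(methods, c("tweedie", "logistic", "gaussian_nonzero",
                                  "proportion_anova", "naive_mw"), several.ok = TRUE)
  structure(
    list(ct_path = ct_path, genotype_path = genotype_path, out_dir = out_dir,
         meta_path = meta_path, lod = lod, total_cycles = total_cycles,
         failure_sd = failure_sd, methods = methods, fdr_q = fdr_q,
         loading_threshold = loading_threshold, pcs = pcs,
         missing_codes = missing_codes, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with fields matching the arguments of
#'   [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full single-cell eQTL pipeline
#'
#' QC (singlet filter, failure-score filter), CT-to-expression
#' transformation, the multi-method eQTL scan with per-(cell type, method)
#' FDR, cross-cell-type sharing bookkeeping, on/off pattern detection, and
#' the per-cell-type co-expression PCA. All stage outputs are written as
#' TSV/JSON files under `config$out_dir`, together with a machine-readable
#' manifest holding the package version, the configuration and per-stage
#' record counts.
#'
#' @param config A [run_config()] (or a path to a YAML file for
#'   [read_run_config()]).
#' @return Invisibly, a list with `expr`, `qc`, `results`, `sharing`,
#'   `on_off`, `coexpression` and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  ct <- read_ct_matrix(config$ct_path, meta = config$meta_path,
                       missing_codes = config$missing_codes)
  genotypes <- read_genotypes(config$genotype_path)
  n_cells_in <- n_distinct(ct$cell_id)

  ct_singlet <- exclude_nonsinglets(ct)
  n_nonsinglet <- n_cells_in - n_distinct(ct_singlet$cell_id)

  qc <- failure_score_filter(ct_singlet, k_sd = config$failure_sd,
                             total_cycles = config$total_cycles)
  keep <- qc$cell_id[!qc$flagged]
  ct_clean <- filter(ct_singlet, .data$cell_id %in% keep)
  n_failed <- sum(qc$flagged)

  expr <- ct_to_expression(ct_clean, total_cycles = config$total_cycles,
                           lod = config$lod)

  results <- run_eqtl_scan(expr, genotypes, methods = config$methods,
                           fdr_q = config$fdr_q)
  sharing <- sharing_analysis(results, fdr_q = config$fdr_q)
  on_off <- detect_on_off_genes(expr)

  coexpr <- list()
  for (ct_level in sort(unique(expr$cell_type))) {
    coexpr[[ct_level]] <- tryCatch(
      run_coexpression(expr, cell_type = ct_level,
                       threshold = config$loading_threshold, pcs = config$pcs),
      error = function(e) e
    )
  }

  # ---- outputs ----
  readr::write_tsv(qc, file.path(config$out_dir, "qc_report.tsv"))
  write_eqtl_results(results, file.path(config$out_dir, "eqtl_full.tsv"))
  readr::write_tsv(significant_hits(results),
                   file.path(config$out_dir, "eqtl_significant.tsv"))
  jsonlite::write_json(
    list(overall = sharing$overall, per_snp = sharing$per_snp,
         method_counts = sharing$method_counts),
    file.path(config$out_dir, "sharing.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(select(on_off, -"per_individual"),
                   file.path(config$out_dir, "on_off_genes.tsv"))
  module_tables <- list()
  for (ct_level in names(coexpr)) {
    cx <- coexpr[[ct_level]]
    if (inherits(cx, "error")) next
    readr::write_tsv(tidy(cx$pca),
                     file.path(config$out_dir, sprintf("eigen_%s.tsv", ct_level)))
    readr::write_tsv(cx$scores,
                     file.path(config$out_dir, sprintf("pc_scores_%s.tsv", ct_level)))
    module_tables[[ct_level]] <- cx$modules$gene
  }
  if (all(c("CL", "NCL") %in% names(module_tables))) {
    readr::write_tsv(module_partition(module_tables$CL, module_tables$NCL),
                     file.path(config$out_dir, "modules.tsv"))
  }

  scan_log <- attr(results, "scan_log")
  manifest <- list(
    package = "monoqtl",
    version = as.character(packageVersion("monoqtl")),
    seed = config$seed,
    config = unclass(config),
    counts = list(
      cells_in = n_cells_in,
      excluded_nonsinglet = n_nonsinglet,
      excluded_failure_score = n_failed,
      cells_analyzed = n_cells_in - n_nonsinglet - n_failed,
      tests_attempted = nrow(results),
      tests_converged = sum(results$converged),
      tests_skipped = sum(!results$converged),
      eqtls_retained = sum(results$retained)
    ),
    scan_log = scan_log,
    stages_completed = c("qc", "expression", "scan", "sharing", "on_off",
                         paste0("coexpression_", names(module_tables)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  invisible(list(expr = expr, qc = qc, results = results, sharing = sharing,
                 on_off = on_off, coexpression = coexpr, manifest = manifest))
}
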