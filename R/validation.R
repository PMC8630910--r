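# Simulation studies that validate the statistical machinery under the
# study conditions the package is designed for (15 individuals, ~30-40
# cells per individual, strong person-level heterogeneity). They back the
# calibration, power and recovery checks in the test suite and the
# acceptance script, and are reusable for sensitivity analyses.

#' Type I error study under the synthetic null
#'
#' Simulates null datasets (no planted effects) at the study scale with
#' person-level heterogeneity, fits every method to the single simulated
#' gene, and reports empirical rejection rates at `alpha`. The naive
#' per-cell Mann-Whitney scan is included as the pseudoreplication
#' contrast: with person heterogeneity it rejects far above nominal while
#' the mixed methods stay close to `alpha`.
#'
#' @param seeds Integer vector of per-replicate generator seeds.
#' @param alpha Nominal level (default 0.05).
#' @param n_individuals,cells_per_individual,person_intercept_sd Study
#'   conditions (defaults: 15 individuals, 30 cells, person SD 1.0).
#' @param maf Minor-allele frequency of the simulated SNP.
#' @param methods Methods to calibrate.
#' @return A tibble with `method`, `rejection_rate`, `n_reps`, `n_missing`;
#'   the per-replicate p-value matrix is in attribute `"p_values"`.
#' @export
type1_error_study <- function(seeds = 1:200, alpha = 0.05,
                              n_individuals = 15, cells_per_individual = 30,
                              person_intercept_sd = 1, maf = 0.3,
                              methods = c("tweedie", "logistic",
                                          "gaussian_nonzero",
                                          "proportion_anova", "naive_mw")) {
  ps <- vapply(seeds, function(seed) {
    cfg <- sim_config(n_individuals = n_individuals,
                      cells_per_individual = cells_per_individual,
                      cell_types = "CL", n_genes = 1, snp_mafs = c(maf),
                      person_intercept_sd = person_intercept_sd, seed = seed)
    sim <- simulate_expression(cfg)
    expr <- ct_to_expression(sim$ct)
    d <- dplyr::inner_join(expr,
                           filter(sim$genotypes, .data$rsid == "snp1"),
                           by = "individual_id")
    vapply(methods, function(m) {
      fit <- tryCatch(fit_one_method(d, m), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) NA_real_ else fit$p_value
    }, numeric(1))
  }, numeric(length(methods)))
  ps <- matrix(ps, nrow = length(methods),
               dimnames = list(methods, NULL))
  out <- tibble(
    method = methods,
    rejection_rate = apply(ps, 1, function(p) mean(p < alpha, na.rm = TRUE)),
    n_reps = length(seeds),
    n_missing = apply(ps, 1, function(p) sum(is.na(p)))
  )
  attr(out, "p_values") <- ps
  out
}

#' Parameter-recovery study for the mixed-model fitters
#'
#' Simulates directly from the model family (compound Poisson-gamma for the
#' Tweedie, Bernoulli-logit for the logistic; see
#' [simulate_tweedie_glmm()]), fits the corresponding mixed model, and
#' summarises the dosage-coefficient estimates across replicates.
#'
#' @param method `"tweedie"` or `"logistic"`.
#' @param beta True dosage effect (log-mean or log-odds per allele).
#' @param seeds Per-replicate seeds.
#' @param n_individuals,cells_per_individual Cohort size.
#' @return A tibble with `method`, `true_effect`, `mean_estimate`,
#'   `sd_estimate`, `bias`, `n_reps`, `n_converged`.
#' @export
effect_recovery_study <- function(method = c("tweedie", "logistic"),
                                  beta = if (match.arg(method) == "tweedie") 0.5 else 1,
                                  seeds = 1:200, n_individuals = 15,
                                  cells_per_individual = 40) {
  method <- match.arg(method)
  est <- vapply(seeds, function(seed) {
    if (method == "tweedie") {
      d <- simulate_tweedie_glmm(n_individuals, cells_per_individual,
                                 beta = beta, seed = seed)
      fit <- fit_tweedie_mixed(d)
    } else {
      d <- simulate_logistic_glmm(n_individuals, cells_per_individual,
                                  beta = beta, seed = seed)
      fit <- fit_logistic_mixed(d)
    }
    if (fit$converged) fit$estimate else NA_real_
  }, numeric(1))
  tibble(
    method = method,
    true_effect = beta,
    mean_estimate = mean(est, na.rm = TRUE),
    sd_estimate = sd(est, na.rm = TRUE),
    bias = mean(est, na.rm = TRUE) - beta,
    n_reps = length(seeds),
    n_converged = sum(!is.na(est))
  )
}

#' Detection-power study for the full eQTL scan
#'
#' Runs [run_eqtl_scan()] on replicates of the powered fixture and reports
#' how often the planted detection-channel eQTL (logit 1.5 per allele) is
#' retained at FDR < `fdr_q` by at least one method.
#'
#' @param seeds Per-replicate seeds.
#' @param n_genes,n_snps Panel size of the powered fixture.
#' @param methods Scan methods (the dropout-channel methods by default).
#' @param fdr_q Retention cutoff.
#' @return A tibble with `detection_rate`, `n_reps`.
#' @export
scan_power_study <- function(seeds = 5001:5050, n_genes = 6, n_snps = 2,
                             methods = c("logistic", "proportion_anova"),
                             fdr_q = 0.1) {
  planted_snp <- paste0("snp", n_snps)
  hits <- vapply(seeds, function(seed) {
    sim <- make_powered_fixture(seed = seed, n_genes = n_genes,
                                n_snps = n_snps, cell_types = "CL")
    expr <- ct_to_expression(sim$ct)
    res <- run_eqtl_scan(expr, sim$genotypes, methods = methods, fdr_q = fdr_q)
    any(res$retained & res$gene == "G001" & res$rsid == planted_snp)
  }, logical(1))
  tibble(detection_rate = mean(hits), n_reps = length(seeds))
}

#' False-discovery behaviour under the global null
#'
#' Runs the full scan on null fixtures (no planted effects) and summarises
#' retention at FDR < `fdr_q`. Under the global null the BH step-up
#' procedure bounds the probability of any retention within a correction
#' family by `fdr_q`, so the familywise rejection rate across
#' (replicate x family) draws should sit near or below that bound.
#'
#' @param seeds Per-replicate seeds.
#' @param n_genes,n_snps Panel size of the null fixture.
#' @param methods Scan methods.
#' @param fdr_q Retention cutoff.
#' @return A tibble with `mean_retained_records` (per scan),
#'   `familywise_rejection_rate` (fraction of (scan, family) pairs with any
#'   retention), `n_reps`, `n_families`.
#' @export
null_scan_study <- function(seeds = 7001:7020, n_genes = 12, n_snps = 2,
                            methods = c("logistic", "gaussian_nonzero",
                                        "proportion_anova"),
                            fdr_q = 0.1) {
  res <- vapply(seeds, function(seed) {
    sim <- make_null_fixture(seed = seed, n_genes = n_genes, n_snps = n_snps,
                             cell_types = "CL")
    expr <- ct_to_expression(sim$ct)
    scan <- run_eqtl_scan(expr, sim$genotypes, methods = methods, fdr_q = fdr_q)
    c(n_retained = sum(scan$retained),
      fam_rej = sum(tapply(scan$retained, scan$method, any)))
  }, c(n_retained = 0, fam_rej = 0))
  tibble(
    mean_retained_records = mean(res["n_retained", ]),
    familywise_rejection_rate = mean(res["fam_rej", ]) / length(methods),
    n_reps = length(seeds),
    n_families = length(methods)
  )
}

#' Co-expression module-recovery study
#'
#' Simulates datasets with a planted 10-gene co-expression block (within-
#' block correlation 0.8) among 30 genes, person-level heterogeneity and no
#' dropout, then checks (i) whether [extract_modules()] at |loading| > 0.7
#' on PC1 returns exactly the block, and (ii) whether projecting cells onto
#' the individual-averaged correlation PCA yields a lower individual-ID
#' eta-squared on PC1 than projecting onto the pooled-correlation PCA (the
#' heterogeneity-removal property).
#'
#' The no-dropout configuration isolates the correlation-averaging PCA from
#' the detection process: on the absolute expression scale, zeros dominate
#' Pearson correlations, so module recovery through dropout would measure
#' co-detection rather than the PCA machinery.
#'
#' @param seeds Per-replicate seeds.
#' @param block_cor Within-block correlation of detected expression.
#' @param block_size,n_genes Block and panel sizes.
#' @param person_intercept_sd,person_shared_frac Person-effect structure.
#' @param threshold Module loading cutoff.
#' @return A tibble with `block_recovery_rate`, `eta2_reduction_rate`,
#'   `n_reps`.
#' @export
coexpression_recovery_study <- function(seeds = 9001:9050, block_cor = 0.8,
                                        block_size = 10, n_genes = 30,
                                        person_intercept_sd = 0.5,
                                        person_shared_frac = 0.6,
                                        threshold = 0.7) {
  block <- sprintf("G%03d", seq_len(block_size))
  res <- vapply(seeds, function(seed) {
    cfg <- sim_config(n_individuals = 15, cells_per_individual = 25,
                      cell_types = "CL", n_genes = n_genes, snp_mafs = c(0.3),
                      gene_mean_range = c(18, 24), sigma = 2,
                      person_intercept_sd = person_intercept_sd,
                      person_shared_frac = person_shared_frac,
                      mcar = TRUE, detection_prob = 1,
                      blocks = list(list(genes = block, cor = block_cor)),
                      seed = seed)
    sim <- simulate_expression(cfg)
    expr <- ct_to_expression(sim$ct)
    cx <- run_coexpression(expr, cell_type = "CL", threshold = threshold)
    pooled <- pca_from_correlation(
      pooled_correlation(expr, cx$gene_universe, "CL"))
    sc_pooled <- project_cells(expr, pooled, "CL")
    c(block = setequal(cx$modules$gene, intersect(block, cx$gene_universe)) &&
        all(block %in% cx$gene_universe),
      eta = individual_eta2(cx$scores) < individual_eta2(sc_pooled))
  }, c(block = TRUE, eta = TRUE))
  tibble(
    block_recovery_rate = mean(res["block", ]),
    eta2_reduction_rate = mean(res["eta", ]),
    n_reps = length(seeds)
  )
}
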