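test_that("simulated genotypes follow Hardy-Weinberg frequencies", {
  g <- simulate_genotypes(0.3, 10000, seed = 17)
  freqs <- tabulate(g + 1, 3) / 10000
  expect_equal(freqs, c(0.49, 0.42, 0.09), tolerance = 0.02 / 0.09)
  expect_true(all(abs(freqs - c(0.49, 0.42, 0.09)) < 0.02))
  expect_error(simulate_genotypes(0.6, 10), "maf")
  expect_error(simulate_genotypes(0, 10), "maf")
  expect_identical(simulate_genotypes(0.2, 50, seed = 3),
                   simulate_genotypes(0.2, 50, seed = 3))
  g_rare <- simulate_genotypes(0.01, 15, seed = 5)
  expect_gte(mean(g_rare == 0), 0.8)
})

test_that("the generator is seed-deterministic end to end", {
  a <- simulate_expression(sim_config(n_genes = 4, snp_mafs = c(0.3, 0.2),
                                      n_individuals = 5, cells_per_individual = 6,
                                      seed = 99))
  b <- simulate_expression(sim_config(n_genes = 4, snp_mafs = c(0.3, 0.2),
                                      n_individuals = 5, cells_per_individual = 6,
                                      seed = 99))
  expect_identical(a$ct, b$ct)
  expect_identical(a$genotypes, b$genotypes)
})

test_that("the generated zero pattern equals the LOD mask by construction", {
  sim <- make_null_fixture(seed = 23, n_genes = 5, n_snps = 2)
  expect_true(all(is.na(sim$ct$ct) | sim$ct$ct < 28))
  expr <- ct_to_expression(sim$ct)
  expect_identical(expr$expression == 0, is.na(sim$ct$ct))
})

test_that("with no heterogeneity and full detection expression is iid Gaussian", {
  cfg <- sim_config(n_individuals = 100, cells_per_individual = 100,
                    cell_types = "CL", n_genes = 1, snp_mafs = c(0.3),
                    gene_mean_range = c(19, 21), sigma = 2,
                    person_intercept_sd = 0, mcar = TRUE, detection_prob = 1,
                    seed = 41)
  sim <- simulate_expression(cfg)
  expr <- ct_to_expression(sim$ct)
  expect_equal(sd(expr$expression), 2, tolerance = 0.1)
  expect_equal(mean(expr$expression), sim$truth$baseline_mean[["G001"]],
               tolerance = 0.1)
})

test_that("a detection-channel plant orders on-proportions with dosage", {
  ordered <- vapply(1:50, function(i) {
    cfg <- sim_config(n_individuals = 40, cells_per_individual = 30,
                      cell_types = "CL", n_genes = 1, snp_mafs = c(0.4),
                      detection_intercept = -4,
                      effects = list(list(gene = "G001", rsid = "snp1",
                                          size = 1.5, channel = "detection")),
                      seed = 60000 + i)
    sim <- simulate_expression(cfg)
    expr <- ct_to_expression(sim$ct)
    d <- dplyr::inner_join(expr, dplyr::filter(sim$genotypes, rsid == "snp1"),
                           by = "individual_id")
    props <- tapply(d$expression > 0, d$dosage, mean)
    length(props) == 3 && !is.unsorted(props)
  }, logical(1))
  expect_gt(mean(ordered), 0.5)
})

test_that("null p-values are uniform when the person effect is switched off", {
  ps <- sapply(1:300, function(i) {
    cfg <- sim_config(n_individuals = 15, cells_per_individual = 20,
                      cell_types = "CL", n_genes = 1, snp_mafs = c(0.3),
                      person_intercept_sd = 0, seed = 70000 + i)
    sim <- simulate_expression(cfg)
    expr <- ct_to_expression(sim$ct)
    d <- dplyr::inner_join(expr, dplyr::filter(sim$genotypes, rsid == "snp1"),
                           by = "individual_id")
    c(anova = tidy(fit_proportion_anova(d))$p_value,
      mw = tidy(fit_naive_mw(d))$p_value)
  })
  expect_gt(stats::ks.test(ps["anova", ], "punif")$p.value, 0.01)
  # per-cell MW p-values are discrete-ish but calibrated without person effects
  expect_lt(abs(mean(ps["mw", ] < 0.05, na.rm = TRUE) - 0.05), 0.035)
})

test_that("person heterogeneity inflates the naive per-cell test specifically", {
  rej <- function(sd_person, seeds) {
    mean(vapply(seeds, function(i) {
      cfg <- sim_config(n_individuals = 15, cells_per_individual = 20,
                        cell_types = "CL", n_genes = 1, snp_mafs = c(0.3),
                        person_intercept_sd = sd_person, seed = 80000 + i)
      sim <- simulate_expression(cfg)
      expr <- ct_to_expression(sim$ct)
      d <- dplyr::inner_join(expr, dplyr::filter(sim$genotypes, rsid == "snp1"),
                             by = "individual_id")
      tidy(fit_naive_mw(d))$p_value < 0.05
    }, logical(1)))
  }
  seeds <- 1:80
  r0 <- rej(0, seeds)
  r05 <- rej(0.5, seeds)
  r1 <- rej(1, seeds)
  expect_lt(r0, r05)
  expect_lt(r05, r1)
  expect_gt(r1, 0.3)
})

test_that("fixtures carry their truth registries and round-trip through files", {
  null <- make_null_fixture(seed = 1, n_genes = 3, n_snps = 2)
  expect_length(null$truth$effects, 0)
  pow <- make_powered_fixture(seed = 1, n_genes = 12, n_snps = 2)
  expect_length(pow$truth$effects, 2)
  expect_setequal(vapply(pow$truth$effects, `[[`, "", "channel"),
                  c("detection", "mean"))
  expect_named(pow$truth$config$on_off, "G003")
  expect_equal(dim(pow$truth$on_off_state), c(15, 12))

  ct_path <- withr::local_tempfile(fileext = ".csv")
  g_path <- withr::local_tempfile(fileext = ".tsv")
  write_ct_matrix(pow$ct, ct_path)
  write_genotypes(pow$genotypes, g_path)
  expect_equal(as.data.frame(read_ct_matrix(ct_path)), as.data.frame(pow$ct),
               tolerance = 1e-9)
  expect_equal(as.data.frame(read_genotypes(g_path)), as.data.frame(pow$genotypes))
})

test_that("Tweedie deviates have the compound Poisson-gamma moments", {
  set.seed(8)
  y <- rtweedie(60000, mu = 3, power = 1.5, phi = 1)
  expect_equal(mean(y), 3, tolerance = 0.03)
  expect_equal(var(y), 1 * 3^1.5, tolerance = 0.05) # phi * mu^power
  expect_gt(mean(y == 0), 0.01) # genuine point mass at zero
  expect_error(rtweedie(5, 2, power = 2.5), "power")
})
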