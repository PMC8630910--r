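test_that("proportion ANOVA reproduces the hand-worked F statistic", {
  # SSB = 0.16, SSW = 0.01, df (1, 2) => F = 32
  d <- tibble::tibble(
    individual_id = paste0("I", 1:4),
    dosage = c(0, 0, 1, 1),
    on_proportion = c(0.2, 0.3, 0.6, 0.7)
  )
  fit <- fit_proportion_anova(d)
  expect_equal(fit$f_statistic, 32, tolerance = 1e-10)
  expect_equal(fit$df, c(1, 2))
  expect_equal(sign(fit$estimate), 1) # carriers have higher on-proportions
})

test_that("proportion ANOVA degenerate cases behave", {
  d_eq <- tibble::tibble(individual_id = paste0("I", 1:4),
                         dosage = c(0, 0, 1, 1),
                         on_proportion = c(0.5, 0.4, 0.5, 0.4))
  fit <- fit_proportion_anova(d_eq)
  expect_equal(fit$f_statistic, 0, tolerance = 1e-10)
  expect_equal(fit$p_value, 1, tolerance = 1e-10)

  # identical group means, unequal spreads: between-group numerator is 0
  d_var <- tibble::tibble(individual_id = paste0("I", 1:6),
                          dosage = c(0, 0, 0, 1, 1, 1),
                          on_proportion = c(0.45, 0.5, 0.55, 0.2, 0.5, 0.8))
  expect_lt(fit_proportion_anova(d_var)$f_statistic, 1e-10)

  # a lone homozygous-minor individual is merged into the heterozygotes
  d_rare <- tibble::tibble(individual_id = paste0("I", 1:6),
                           dosage = c(0, 0, 0, 1, 1, 2),
                           on_proportion = c(0.2, 0.25, 0.3, 0.5, 0.55, 0.9))
  fit_rare <- fit_proportion_anova(d_rare)
  expect_match(fit_rare$reason, "collapsed_hom_minor")
  expect_equal(fit_rare$df[1], 1) # two groups after the collapse
})

test_that("degenerate fitter inputs give skips with reasons, not errors", {
  dos <- c(0, 0, 1, 1, 2, 2)
  zero <- make_fit_data(rep(0, 30), dos, 5)
  expect_false(fit_tweedie_mixed(zero)$converged)
  expect_equal(fit_tweedie_mixed(zero)$reason, "all_zero")

  all_on <- make_fit_data(rep(15, 30), dos, 5)
  expect_equal(fit_logistic_mixed(all_on)$reason, "single_class")

  same <- make_fit_data(rep(c(15, 0), 15), dos, 5)
  expect_equal(fit_gaussian_nonzero_mixed(same)$reason, "zero_variance")

  few <- make_fit_data(c(rep(0, 20), rep(c(14, 15, 16, 17, 18), 2)), dos, 5)
  expect_equal(fit_gaussian_nonzero_mixed(few)$reason,
               "too_few_individuals_with_detection")

  const <- make_fit_data(rnorm(30, 15), rep(1, 6), 5)
  expect_error(fit_tweedie_mixed(const), "no genotype contrast")
})

test_that("naive Mann-Whitney handles ties and empty groups", {
  dos <- c(0, 0, 1, 1)
  tied <- make_fit_data(rep(12, 20), dos, 5)
  expect_equal(fit_naive_mw(tied)$p_value, 1)
  one_group <- make_fit_data(rnorm(20, 15), rep(0, 4), 5)
  expect_error(fit_naive_mw(one_group), "no genotype contrast")
})

test_that("the Gaussian mixed model matches OLS in the no-random-effect limit", {
  set.seed(202)
  dos <- rep(0:2, each = 12)
  d <- make_fit_data(rnorm(36 * 30, mean = 15 + 0.2 * dos[rep(1:36, each = 30)], sd = 2),
                     dos, 30)
  fit <- fit_gaussian_nonzero_mixed(d)
  ols <- summary(lm(expression ~ dosage, data = d))$coefficients
  expect_lt(abs(fit$p_value - ols["dosage", "Pr(>|t|)"]), 0.01)
  expect_equal(fit$estimate, ols["dosage", "Estimate"], tolerance = 0.05)
})

test_that("model p-values are invariant to cell order and individual relabeling", {
  d <- simulate_logistic_glmm(seed = 77, beta = 0.5,
                              cells_per_individual = 20)
  d$expression <- d$expression * rgamma(nrow(d), 10, 1) # make it non-binary
  set.seed(3)
  perm <- d[sample(nrow(d)), ]
  relab <- dplyr::mutate(perm, individual_id = paste0("X_", individual_id))
  for (f in list(fit_logistic_mixed, fit_gaussian_nonzero_mixed,
                 fit_proportion_anova, fit_naive_mw)) {
    expect_equal(f(d)$p_value, f(perm)$p_value, tolerance = 1e-4)
    expect_equal(f(d)$p_value, f(relab)$p_value, tolerance = 1e-4)
  }
})

test_that("the Tweedie fitter honours a fixed power index", {
  d <- simulate_tweedie_glmm(seed = 9, beta = 0.4, power = 1.5)
  fit <- fit_tweedie_mixed(d, power = 1.4)
  expect_equal(fit$tweedie_power, 1.4, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("BH adjustment matches the worked example and the brute-force oracle", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.1)
  expect_equal(out$fdr_q, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(sum(out$retained), 3)

  expect_false(any(bh_fdr(rep(1, 5))$retained))
  expect_equal(bh_fdr(0.05)$fdr_q, 0.05)
  expect_equal(nrow(bh_fdr(numeric())), 0)

  set.seed(55)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p)$fdr_q, bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("missing p-values are excluded from the BH ranks", {
  p <- c(0.01, NA, 0.04)
  out <- bh_fdr(p)
  expect_true(is.na(out$fdr_q[2]))
  expect_equal(out$fdr_q[c(1, 3)], bh_oracle(c(0.01, 0.04)))
  expect_false(out$retained[2])
})

test_that("the Bonferroni threshold is alpha over the comparison count", {
  expect_equal(bonferroni_threshold(1, 1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(10, 10, 0.05), 5e-4)
  expect_error(bonferroni_threshold(0, 7), "positive")
})
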