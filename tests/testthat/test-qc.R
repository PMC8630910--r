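test_that("CT-to-expression transformation applies the LOD rule", {
  ct <- make_ct_tbl(matrix(c(25, 28, NA), ncol = 1), individual_id = rep("I1", 3))
  expr <- ct_to_expression(ct, total_cycles = 40, lod = 28)
  expect_equal(expr$expression, c(15, 0, 0)) # 40 - 25; >= LOD; missing
  expect_error(ct_to_expression(ct, total_cycles = 28, lod = 28),
               class = "monoqtl_config_error")
})

test_that("expression is monotone decreasing in CT and zero iff non-detected", {
  cts <- seq(5, 39.5, by = 0.5)
  ct <- make_ct_tbl(matrix(cts, ncol = 1), individual_id = rep("I1", length(cts)))
  expr <- ct_to_expression(ct)
  detected <- expr$expression[ct$ct < 28]
  expect_true(all(diff(detected) < 0))
  expect_identical(expr$expression == 0, is.na(ct$ct) | ct$ct >= 28)
})

test_that("failure scores are CT totals and outliers are flagged", {
  ct <- make_ct_tbl(matrix(c(20, 21, 19, 22, 20, 21, 24, 19, 20), nrow = 3),
                    individual_id = rep("I1", 3))
  rep_tbl <- failure_score_filter(ct, scope = "global")
  expect_equal(sort(rep_tbl$failure_score), c(60, 60, 66)) # per-cell CT sums

  set.seed(101)
  scores <- rnorm(100, 60, 5)
  all_scores <- c(scores, 200)
  ct_big <- make_ct_tbl(matrix(all_scores, ncol = 1),
                        individual_id = rep("I1", 101))
  rep_big <- failure_score_filter(ct_big, k_sd = 2, scope = "global")
  # independent oracle: direct mean + 2 sd on the realised scores
  cutoff <- mean(all_scores) + 2 * sd(all_scores)
  expect_identical(rep_big$flagged, rep_big$failure_score > cutoff)
  expect_equal(sum(rep_big$flagged), 1L)
  expect_equal(rep_big$failure_score[rep_big$flagged], 200)
})

test_that("identical failure scores flag nothing; missing CTs are penalised", {
  ct <- make_ct_tbl(matrix(20, nrow = 4, ncol = 2), individual_id = rep("I1", 4))
  expect_false(any(failure_score_filter(ct)$flagged))

  ct_na <- make_ct_tbl(matrix(c(20, 20, NA, 20, 20, 20), nrow = 3),
                       individual_id = rep("I1", 3))
  rep_na <- failure_score_filter(ct_na, total_cycles = 40, scope = "global")
  expect_equal(max(rep_na$failure_score), 60) # NA contributes total_cycles
})

test_that("non-singlet exclusion keeps exactly the singlet cells", {
  ct <- make_ct_tbl(matrix(20, nrow = 5, ncol = 1),
                    capture_flag = c("singlet", "doublet", "singlet", "doublet", "singlet"))
  expect_equal(dplyr::n_distinct(exclude_nonsinglets(ct)$cell_id), 3)
  all_single <- make_ct_tbl(matrix(20, nrow = 3, ncol = 1))
  expect_identical(exclude_nonsinglets(all_single), all_single)
  all_doub <- make_ct_tbl(matrix(20, nrow = 3, ncol = 1), capture_flag = "doublet")
  expect_warning(out <- exclude_nonsinglets(all_doub), "no singlet")
  expect_equal(nrow(out), 0)
})

test_that("on-proportions cover the boundary cases", {
  vals <- matrix(c(rep(20, 4), rep(30, 6)), ncol = 1) # 4 detected of 10
  expr <- ct_to_expression(make_ct_tbl(vals, individual_id = rep("I1", 10)))
  expect_equal(on_proportions(expr, "individual")$on_proportion, 0.4)
  expr0 <- ct_to_expression(make_ct_tbl(matrix(30, 5, 1), individual_id = rep("I1", 5)))
  expect_equal(on_proportions(expr0, "individual")$on_proportion, 0)
  expr1 <- ct_to_expression(make_ct_tbl(matrix(20, 5, 1), individual_id = rep("I1", 5)))
  expect_equal(on_proportions(expr1, "individual")$on_proportion, 1)
})

test_that("saturated-gene rule is a strict 98% cutoff on the individual average", {
  # gene A: on in 99/100 cells for each individual; gene B: exactly 98/100;
  # gene C: never expressed
  vals <- function(n_on, n) matrix(c(rep(20, n_on), rep(35, n - n_on)), ncol = 1)
  build <- function(n_on) {
    rbind(vals(n_on, 100), vals(n_on, 100))
  }
  ct <- make_ct_tbl(cbind(build(99), build(98), build(0)),
                    individual_id = rep(c("I1", "I2"), each = 100),
                    genes = c("A", "B", "C"))
  out <- drop_saturated_genes(ct_to_expression(ct), threshold = 0.98)
  expect_identical(out$dropped[out$gene == "A"], TRUE)
  expect_identical(out$dropped[out$gene == "B"], FALSE) # exactly 0.98 kept
  expect_identical(out$dropped[out$gene == "C"], FALSE) # never expressed kept
})

test_that("on/off pattern detection follows the two-sided individual rule", {
  # individuals with on-proportions 0, 0, 0.8, 0.9 over 10 cells each
  props <- c(0, 0, 0.8, 0.9)
  vals <- unlist(lapply(props, function(p) c(rep(20, round(10 * p)),
                                             rep(35, 10 - round(10 * p)))))
  ct <- make_ct_tbl(matrix(vals, ncol = 1), individual_id = rep(paste0("I", 1:4), each = 10))
  out <- detect_on_off_genes(ct_to_expression(ct))
  expect_true(out$flagged)
  expect_equal(out$n_off, 2)
  expect_equal(out$n_on, 2)

  props2 <- c(0.4, 0.5, 0.5, 0.6)
  vals2 <- unlist(lapply(props2, function(p) c(rep(20, round(10 * p)),
                                               rep(35, 10 - round(10 * p)))))
  ct2 <- make_ct_tbl(matrix(vals2, ncol = 1), individual_id = rep(paste0("I", 1:4), each = 10))
  expect_false(detect_on_off_genes(ct_to_expression(ct2))$flagged)
})

test_that("gene-level QC is invariant to cell-order permutation", {
  sim <- make_powered_fixture(seed = 31, n_genes = 5, n_snps = 2)
  expr <- ct_to_expression(sim$ct)
  set.seed(1)
  shuffled <- expr[sample(nrow(expr)), ]
  expect_equal(drop_saturated_genes(expr), drop_saturated_genes(shuffled))
  a <- detect_on_off_genes(expr)
  b <- detect_on_off_genes(shuffled)
  expect_equal(a[c("gene", "n_off", "n_on", "flagged")],
               b[c("gene", "n_off", "n_on", "flagged")])
})

test_that("generator-planted person-level on/off genes are detected reliably", {
  hits <- vapply(1:100, function(i) {
    cfg <- sim_config(n_individuals = 15, cells_per_individual = 30,
                      cell_types = "CL", n_genes = 2, snp_mafs = c(0.3),
                      on_off = c(G002 = 0.4), seed = 40000 + i)
    sim <- simulate_expression(cfg)
    out <- detect_on_off_genes(ct_to_expression(sim$ct))
    out$flagged[out$gene == "G002"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
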