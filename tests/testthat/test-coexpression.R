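make_expr <- function(values, individual_id, genes = NULL, cell_type = "CL") {
  ct_to_expression(make_ct_tbl(40 - values, individual_id = individual_id,
                               genes = genes, cell_type = cell_type))
}

test_that("the common gene universe requires variance in every individual", {
  set.seed(6)
  v_ok <- matrix(rnorm(12, 20, 2), 6, 2)
  v_allzero <- c(rnorm(3, 20), rep(40, 3))   # expression 0 for individual I2
  v_const <- c(rnorm(3, 20), rep(22, 3))     # constant non-zero for I2
  values <- cbind(v_ok, v_allzero, v_const)
  expr <- make_expr(values, individual_id = rep(c("I1", "I2"), each = 3),
                    genes = c("A", "B", "C", "D"))
  expect_setequal(common_gene_universe(expr), c("A", "B"))
})

test_that("matrix averaging is element-wise and validates dimensions", {
  m <- matrix(c(1, 0.8, 0.8, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(average_correlation(list(m, m)), m)
  m2 <- m; m2[1, 2] <- m2[2, 1] <- -0.8
  avg <- average_correlation(list(m, m2))
  expect_equal(avg[1, 2], 0)
  expect_equal(average_correlation(list(m)), m)
  bad <- matrix(1, 3, 3)
  expect_error(average_correlation(list(m, bad)), "share dimensions")
})

test_that("correlation PCA matches closed forms", {
  id5 <- diag(5)
  p <- pca_from_correlation(id5)
  expect_equal(p$eigenvalues, rep(1, 5))
  expect_equal(p$var_explained, rep(0.2, 5))

  r <- 0.8
  m <- matrix(c(1, r, r, 1), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  p2 <- pca_from_correlation(m)
  expect_equal(p2$eigenvalues, c(1 + r, 1 - r))
  expect_equal(p2$var_explained[1], 0.9)
  expect_equal(unname(p2$loadings[, 1]), c(sqrt(1.8 / 2), sqrt(1.8 / 2)))

  ns <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(pca_from_correlation(ns), "symmetric")
})

test_that("eigen-structure invariants hold on random averaged matrices", {
  set.seed(21)
  for (i in 1:10) {
    p <- sample(4:12, 1)
    n_ind <- 5
    mats <- lapply(1:n_ind, function(j) {
      x <- matrix(rnorm(40 * p), 40, p, dimnames = list(NULL, paste0("g", 1:p)))
      cor(x)
    })
    avg <- average_correlation(mats)
    pc <- pca_from_correlation(avg)
    expect_equal(sum(pc$eigenvalues), p, tolerance = 1e-8) # trace preserved
    recon <- pc$vectors %*% diag(pc$eigenvalues) %*% t(pc$vectors)
    expect_equal(unname(recon), unname(avg), tolerance = 1e-8)
    expect_gte(min(pc$eigenvalues), -1e-8) # average of PSD matrices is PSD
    expect_lte(max(abs(pc$loadings)), 1 + 1e-8)
    expect_equal(sum(pc$var_explained), 1, tolerance = 1e-8)
  }
})

test_that("module extraction applies a strict absolute-loading cutoff", {
  pca <- structure(list(
    eigenvalues = c(2, 1),
    vectors = matrix(0, 3, 2, dimnames = list(c("A", "B", "C"), c("PC1", "PC2"))),
    var_explained = c(2 / 3, 1 / 3),
    loadings = matrix(c(0.95, 0.90, 0.10, -0.8, 0.1, 0.2), 3, 2,
                      dimnames = list(c("A", "B", "C"), c("PC1", "PC2"))),
    genes = c("A", "B", "C")
  ), class = "cor_pca")
  expect_setequal(extract_modules(pca, pcs = 1)$gene, c("A", "B"))
  # negative loadings count through the absolute value
  expect_true("A" %in% extract_modules(pca, pcs = 2)$gene)
  # invariant to a global sign flip of the eigenvector
  flipped <- pca
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  expect_setequal(abs(extract_modules(flipped, pcs = 1)$loading),
                  abs(extract_modules(pca, pcs = 1)$loading))
})

test_that("module partition mirrors the classical/shared/non-classical layout", {
  part <- module_partition(c("A", "B", "C"), c("A", "B", "D"))
  expect_equal(part$gene[part$set == "shared"], c("A", "B"))
  expect_equal(part$gene[part$set == "classical"], "C")
  expect_equal(part$gene[part$set == "non_classical"], "D")
})

test_that("cell projection is centred and linear", {
  set.seed(33)
  vals <- matrix(rnorm(40 * 4, 20, 2), 40, 4)
  expr <- make_expr(vals, individual_id = rep(c("I1", "I2"), each = 20),
                    genes = c("A", "B", "C", "D"))
  cx <- run_coexpression(expr, cell_type = "CL")
  # scores are centred: a cell at the pooled gene means scores 0, so the
  # column means of scores over cells are 0
  expect_equal(colMeans(as.matrix(cx$scores[c("PC1", "PC2")])), c(PC1 = 0, PC2 = 0),
               tolerance = 1e-10)
  # linearity on standardised rows: score(a + b) = score(a) + score(b)
  z <- scale(vals)
  v <- cx$pca$vectors[, 1]
  expect_equal(sum((z[1, ] + z[2, ]) * v), sum(z[1, ] * v) + sum(z[2, ] * v),
               tolerance = 1e-12)
})

test_that("a planted correlation block dominates PC1 and is recovered exactly", {
  cfg <- sim_config(n_individuals = 12, cells_per_individual = 25,
                    cell_types = "CL", n_genes = 30, snp_mafs = c(0.3),
                    gene_mean_range = c(18, 24), person_intercept_sd = 0.5,
                    person_shared_frac = 0.6, mcar = TRUE, detection_prob = 1,
                    blocks = list(list(genes = sprintf("G%03d", 1:10), cor = 0.8)),
                    seed = 61)
  sim <- simulate_expression(cfg)
  expr <- ct_to_expression(sim$ct)
  cx <- run_coexpression(expr, cell_type = "CL")
  block <- sprintf("G%03d", 1:10)
  # the ten largest |PC1 loadings| are exactly the block genes
  lo <- tidy(cx$pca, matrix = "loadings") |> dplyr::filter(pc == 1)
  top10 <- lo$gene[order(-abs(lo$loading))][1:10]
  expect_setequal(top10, block)
  expect_setequal(cx$modules$gene, block)
})
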