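# Individual-averaged gene-gene correlation PCA. Correlating within each
# individual and averaging the matrices removes between-person mean
# differences before the eigendecomposition, so the leading components
# describe within-cell co-expression rather than who the cell came from.

#' Genes usable for per-individual correlation in a cell type
#'
#' The common gene universe: genes whose expression has non-zero variance
#' within every individual's cells of the given cell type, so that the
#' per-individual Pearson correlation is defined everywhere. Genes that are
#' all-zero or constant in any one individual are excluded.
#'
#' @param expr Expression tibble.
#' @param cell_type Cell type to restrict to (`NULL` = all cells).
#' @return Character vector of gene names.
#' @export
common_gene_universe <- function(expr, cell_type = NULL) {
  assert_cols(expr, c("individual_id", "cell_type", "gene", "expression"),
              "expression data")
  if (!is.null(cell_type)) {
    expr <- filter(expr, .data$cell_type == !!cell_type)
  }
  if (n_distinct(expr$individual_id) < 2) abort("need at least 2 individuals")
  per_ind <- expr |>
    group_by(.data$individual_id, .data$gene) |>
    summarise(v = var(.data$expression), .groups = "drop")
  universe <- per_ind |>
    group_by(.data$gene) |>
    summarise(ok = all(!is.na(.data$v) & .data$v > 0),
              n_ind = dplyr::n(), .groups = "drop") |>
    filter(.data$ok, .data$n_ind == n_distinct(expr$individual_id)) |>
    pull("gene")
  if (length(universe) == 0) {
    diag_tbl <- per_ind |>
      group_by(.data$individual_id) |>
      summarise(n_degenerate = sum(is.na(.data$v) | .data$v == 0), .groups = "drop")
    abort(paste0(
      "no gene has positive variance in every individual; degenerate genes per individual: ",
      paste(sprintf("%s=%d", diag_tbl$individual_id, diag_tbl$n_degenerate), collapse = ", ")
    ))
  }
  universe
}

#' Per-individual gene-gene correlation matrices
#'
#' @param expr Expression tibble.
#' @param genes Gene universe (see [common_gene_universe()]).
#' @param cell_type Cell type restriction (`NULL` = all cells).
#' @param method Correlation type passed to [stats::cor()] (default
#'   `"pearson"`); zeros are included as observed values.
#' @return Named list (by individual) of genes x genes correlation matrices.
#' @export
individual_correlations <- function(expr, genes, cell_type = NULL,
                                    method = "pearson") {
  if (!is.null(cell_type)) {
    expr <- filter(expr, .data$cell_type == !!cell_type)
  }
  wide <- expression_wide(expr, genes)
  split(seq_len(nrow(wide$meta)), wide$meta$individual_id) |>
    lapply(function(idx) cor(wide$values[idx, , drop = FALSE], method = method))
}

#' Pooled gene-gene correlation matrix (no individual averaging)
#'
#' Correlation over all cells at once, ignoring individual structure. Used
#' as the comparison point when showing that averaging per-individual
#' matrices removes inter-individual heterogeneity.
#'
#' @inheritParams individual_correlations
#' @return A genes x genes correlation matrix.
#' @export
pooled_correlation <- function(expr, genes, cell_type = NULL, method = "pearson") {
  if (!is.null(cell_type)) {
    expr <- filter(expr, .data$cell_type == !!cell_type)
  }
  wide <- expression_wide(expr, genes)
  cor(wide$values, method = method)
}

#' Element-wise average of per-individual correlation matrices
#'
#' @param matrices List of correlation matrices on an identical gene universe.
#' @return The unweighted element-wise mean matrix.
#' @export
average_correlation <- function(matrices) {
  if (length(matrices) == 0) abort("no correlation matrices supplied")
  ref <- dimnames(matrices[[1]])
  for (m in matrices) {
    if (!identical(dim(m), dim(matrices[[1]])) || !identical(dimnames(m), ref)) {
      abort("correlation matrices must share dimensions and gene names")
    }
  }
  Reduce(`+`, matrices) / length(matrices)
}

#' PCA of a (mean) correlation matrix
#'
#' Eigendecomposition of a symmetric correlation matrix, sorted by
#' descending eigenvalue. The variance explained by component *i* is
#' `eigenvalue_i / p` (the trace of a p-gene correlation matrix is p), and
#' the loading of a gene on a component is its eigenvector entry scaled by
#' the square root of the eigenvalue, i.e. the gene-component correlation.
#' Eigenvector signs are fixed so that each component's largest-magnitude
#' loading is positive.
#'
#' @param mean_matrix Symmetric correlation matrix (e.g. from
#'   [average_correlation()]).
#' @return A `cor_pca` object: list with `eigenvalues`, `vectors` (columns =
#'   components), `var_explained`, `loadings` (genes x components), `genes`.
#' @export
pca_from_correlation <- function(mean_matrix) {
  if (!is.matrix(mean_matrix) || !isSymmetric(unname(mean_matrix), tol = 1e-8)) {
    abort("input must be a symmetric matrix")
  }
  p <- ncol(mean_matrix)
  eig <- eigen(mean_matrix, symmetric = TRUE)
  vectors <- eig$vectors
  values <- eig$values
  loadings <- vectors %*% diag(sqrt(pmax(values, 0)), nrow = p)
  for (j in seq_len(p)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      vectors[, j] <- -vectors[, j]
    }
  }
  genes <- rownames(mean_matrix) %||% paste0("gene", seq_len(p))
  pcs <- paste0("PC", seq_len(p))
  dimnames(vectors) <- list(genes, pcs)
  dimnames(loadings) <- list(genes, pcs)
  structure(
    list(eigenvalues = values, vectors = vectors,
         var_explained = values / p, loadings = loadings, genes = genes),
    class = "cor_pca"
  )
}

#' @export
print.cor_pca <- function(x, ...) {
  cat(sprintf("<cor_pca: %d genes>\n", length(x$genes)))
  k <- min(3, length(x$eigenvalues))
  cat(sprintf("  PC%d: eigenvalue %.3f (%.1f%% variance)\n",
              seq_len(k), x$eigenvalues[seq_len(k)],
              100 * x$var_explained[seq_len(k)]), sep = "")
  invisible(x)
}

#' @describeIn pca_from_correlation Tidy eigen table (`pc`, `eigenvalue`,
#'   `var_explained`) or, with `matrix = "loadings"`, the long loadings table.
#' @param x A `cor_pca` object.
#' @param matrix `"eigenvalues"` (default) or `"loadings"`.
#' @param ... Unused.
#' @method tidy cor_pca
#' @export
tidy.cor_pca <- function(x, matrix = c("eigenvalues", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    tibble(pc = seq_along(x$eigenvalues),
           eigenvalue = x$eigenvalues,
           var_explained = x$var_explained)
  } else {
    as_tibble(x$loadings, rownames = "gene") |>
      tidyr::pivot_longer(-"gene", names_to = "pc", values_to = "loading") |>
      mutate(pc = as.integer(sub("^PC", "", .data$pc)))
  }
}

#' Project cells onto the correlation-PCA space
#'
#' Standardises each gene with the pooled per-gene mean and standard
#' deviation over all cells of the cell type (per-individual centring would
#' trivially erase individual effects and defeat the comparison), then
#' multiplies by the eigenvectors.
#'
#' @param expr Expression tibble.
#' @param pca A `cor_pca` object (or an eigenvector matrix with gene
#'   rownames).
#' @param cell_type Cell type restriction (`NULL` = all cells).
#' @param n_pcs Number of components to return (default 2).
#' @return A tibble with `cell_id`, `individual_id`, `cell_type` and one
#'   column per component (`PC1`, `PC2`, ...).
#' @export
project_cells <- function(expr, pca, cell_type = NULL, n_pcs = 2) {
  vectors <- if (inherits(pca, "cor_pca")) pca$vectors else pca
  genes <- rownames(vectors)
  if (is.null(genes)) abort("eigenvector matrix must carry gene rownames")
  if (!is.null(cell_type)) {
    expr <- filter(expr, .data$cell_type == !!cell_type)
  }
  wide <- expression_wide(expr, genes)
  z <- scale(wide$values)
  if (any(!is.finite(z))) {
    abort("a gene has zero pooled variance; restrict to the common gene universe")
  }
  n_pcs <- min(n_pcs, ncol(vectors))
  scores <- z %*% vectors[, seq_len(n_pcs), drop = FALSE]
  dplyr::bind_cols(wide$meta, as_tibble(scores))
}

#' Extract co-expression modules from PCA loadings
#'
#' For each selected ("highly explanatory") component, returns the genes
#' whose absolute loading exceeds the threshold. By default only PC1 is
#' used; `pcs = "auto"` selects components whose variance-explained share is
#' at least `auto_factor` times the median share.
#'
#' @param pca A `cor_pca` object.
#' @param threshold Absolute-loading cutoff (default 0.7, strict `>`).
#' @param pcs Integer vector of components, or `"auto"`.
#' @param auto_factor Multiple of the median variance-explained share used
#'   by `pcs = "auto"` (default 10).
#' @return A tibble with `pc`, `gene`, `loading`, ordered by `|loading|`.
#' @export
extract_modules <- function(pca, threshold = 0.7, pcs = 1, auto_factor = 10) {
  stopifnot(inherits(pca, "cor_pca"))
  if (identical(pcs, "auto")) {
    med <- median(x <- pmax(pca$var_explained, 0))
    pcs <- which(x >= auto_factor * med)
    if (length(pcs) == 0) pcs <- 1L
  }
  tidy(pca, matrix = "loadings") |>
    filter(.data$pc %in% pcs, abs(.data$loading) > threshold) |>
    arrange(.data$pc, dplyr::desc(abs(.data$loading)))
}

#' Partition two cell types' module genes into shared and unique sets
#'
#' @param cl_genes,ncl_genes Module gene vectors for the classical and
#'   non-classical cell types.
#' @return A tibble with `gene` and `set` in
#'   `{"classical", "shared", "non_classical"}`.
#' @export
module_partition <- function(cl_genes, ncl_genes) {
  tibble(
    gene = union(cl_genes, ncl_genes)
  ) |>
    mutate(set = dplyr::case_when(
      .data$gene %in% cl_genes & .data$gene %in% ncl_genes ~ "shared",
      .data$gene %in% cl_genes ~ "classical",
      TRUE ~ "non_classical"
    )) |>
    arrange(factor(.data$set, levels = c("classical", "shared", "non_classical")),
            .data$gene)
}

#' Run the full co-expression analysis for one cell type
#'
#' Common gene universe, per-individual Pearson correlations, element-wise
#' averaging, PCA, cell projection and module extraction in one call.
#'
#' @inheritParams individual_correlations
#' @param threshold Absolute-loading module cutoff (default 0.7).
#' @param pcs Components used for module extraction (default PC1).
#' @param n_pcs Components kept in the cell scores.
#' @return A `coexpression_result`: list with `gene_universe`,
#'   `individual_correlations`, `mean_correlation`, `pca`, `scores`,
#'   `modules`.
#' @export
run_coexpression <- function(expr, cell_type = NULL, method = "pearson",
                             threshold = 0.7, pcs = 1, n_pcs = 2) {
  universe <- common_gene_universe(expr, cell_type)
  mats <- individual_correlations(expr, universe, cell_type, method)
  mean_mat <- average_correlation(mats)
  pca <- pca_from_correlation(mean_mat)
  scores <- project_cells(expr, pca, cell_type, n_pcs = n_pcs)
  modules <- extract_modules(pca, threshold = threshold, pcs = pcs)
  structure(
    list(gene_universe = universe, individual_correlations = mats,
         mean_correlation = mean_mat, pca = pca, scores = scores,
         modules = modules, cell_type = cell_type),
    class = "coexpression_result"
  )
}

#' @export
print.coexpression_result <- function(x, ...) {
  cat(sprintf("<coexpression_result%s>\n",
              if (is.null(x$cell_type)) "" else paste0(": ", x$cell_type)))
  cat(sprintf("  %d genes in universe, %d individuals\n",
              length(x$gene_universe), length(x$individual_correlations)))
  cat(sprintf("  PC1 explains %.1f%% of variance; %d module gene(s)\n",
              100 * x$pca$var_explained[1], nrow(x$modules)))
  invisible(x)
}

#' @describeIn run_coexpression One-row summary of the co-expression result.
#' @param x A `coexpression_result`.
#' @param ... Unused.
#' @method glance coexpression_result
#' @export
glance.coexpression_result <- function(x, ...) {
  tibble(
    cell_type = x$cell_type %||% NA_character_,
    n_genes = length(x$gene_universe),
    n_individuals = length(x$individual_correlations),
    pc1_var_explained = x$pca$var_explained[1],
    pc2_var_explained = x$pca$var_explained[2],
    n_module_genes = nrow(x$modules)
  )
}

#' Proportion of PC-score variance explained by individual identity
#'
#' One-way eta-squared of individual ID on a score column: the
#' between-individual sum of squares over the total. Used to quantify how
#' much a principal-component axis separates people rather than cells.
#'
#' @param scores Score tibble from [project_cells()].
#' @param pc Score column name (default `"PC1"`).
#' @return Eta-squared in \[0, 1\].
#' @export
individual_eta2 <- function(scores, pc = "PC1") {
  assert_cols(scores, c("individual_id", pc), "score table")
  y <- scores[[pc]]
  mu <- mean(y)
  between <- scores |>
    group_by(.data$individual_id) |>
    summarise(ss = dplyr::n() * (mean(.data[[pc]]) - mu)^2, .groups = "drop")
  sum(between$ss) / sum((y - mu)^2)
}

# wide cells x genes matrix plus per-cell metadata, genes in fixed order
expression_wide <- function(expr, genes) {
  assert_cols(expr, c("cell_id", "individual_id", "cell_type", "gene", "expression"),
              "expression data")
  missing <- setdiff(genes, unique(expr$gene))
  if (length(missing) > 0) {
    abort(sprintf("gene(s) missing from expression data: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  wide <- expr |>
    filter(.data$gene %in% genes) |>
    select("cell_id", "individual_id", "cell_type", "gene", "expression") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "expression")
  meta <- wide[c("cell_id", "individual_id", "cell_type")]
  values <- as.matrix(wide[genes])
  rownames(values) <- wide$cell_id
  list(meta = meta, values = values)
}
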