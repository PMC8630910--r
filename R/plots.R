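#' Plot per-cell PC scores with per-individual confidence ellipses
#'
#' Scatter of cells in the first two components of the correlation-PCA
#' space, colour-coded by individual with 95% normal-theory confidence
#' ellipses. Tight overlap of the ellipses indicates that the
#' individual-averaged correlation PCA has removed person-specific
#' heterogeneity.
#'
#' @param scores Score tibble from [project_cells()].
#' @param x,y Score columns to plot.
#' @param ellipse_level Confidence level of the per-individual ellipses.
#' @return A ggplot object.
#' @export
plot_pc_scores <- function(scores, x = "PC1", y = "PC2", ellipse_level = 0.95) {
  assert_cols(scores, c("individual_id", x, y), "score table")
  ggplot2::ggplot(scores, ggplot2::aes(.data[[x]], .data[[y]],
                                       colour = .data$individual_id)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::stat_ellipse(level = ellipse_level, linewidth = 0.4) +
    ggplot2::labs(colour = "Individual") +
    ggplot2::theme_minimal()
}

#' Plot a gene's per-individual expression pattern
#'
#' One column of cells per individual, as used to display person-level
#' on/off expression patterns; optionally annotates each individual with
#' their dosage for a SNP.
#'
#' @param expr Expression tibble.
#' @param gene Gene to display.
#' @param genotypes Optional long genotype tibble.
#' @param rsid SNP whose dosage labels the x axis (requires `genotypes`).
#' @return A ggplot object.
#' @export
plot_gene_by_individual <- function(expr, gene, genotypes = NULL, rsid = NULL) {
  assert_cols(expr, c("individual_id", "cell_type", "gene", "expression"),
              "expression data")
  d <- filter(expr, .data$gene == !!gene)
  if (nrow(d) == 0) abort(sprintf("gene %s not found", gene))
  if (!is.null(genotypes) && !is.null(rsid)) {
    dos <- genotypes |>
      filter(.data$rsid == !!rsid) |>
      select("individual_id", "dosage")
    d <- left_join(d, dos, by = "individual_id") |>
      mutate(individual_id = sprintf("%s\n(%d)", .data$individual_id, .data$dosage))
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$individual_id, .data$expression,
                                  colour = .data$cell_type)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.7, size = 1) +
    ggplot2::labs(x = "Individual", y = "Expression (cycles above threshold)",
                  colour = "Subset", title = gene) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scree plot for a correlation PCA
#'
#' @param object A `cor_pca` object.
#' @param n_pcs Number of leading components to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cor_pca
#' @export
autoplot.cor_pca <- function(object, n_pcs = 10, ...) {
  d <- head(tidy(object), n_pcs)
  ggplot2::ggplot(d, ggplot2::aes(.data$pc, .data$var_explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = d$pc) +
    ggplot2::labs(x = "Principal component", y = "Variance explained") +
    ggplot2::theme_minimal()
}

#' Bar chart of eQTL sharing counts
#'
#' @param object A `sharing_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sharing_summary
#' @export
autoplot.sharing_summary <- function(object, ...) {
  o <- object$overall
  d <- tibble(
    class = factor(c("CL exclusive", "Shared", "NCL exclusive"),
                   levels = c("CL exclusive", "Shared", "NCL exclusive")),
    n = c(o$n_cl_exclusive, o$n_shared, o$n_ncl_exclusive)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$class, .data$n, fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "SNP-gene pairs") +
    ggplot2::theme_minimal()
}
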