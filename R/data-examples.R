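#' Published significant monocyte eQTL associations (worked example)
#'
#' The list of 25 significant SNP-transcript associations reported by a
#' single-cell qPCR eQTL study of SLE-risk SNPs in classical (CL) and
#' non-classical (NCL) monocytes from lupus patients, as printed: one row
#' per association with the detecting method and the monocyte subset.
#' Effect directions were not printed; the `direction` column is set to
#' `"+"` throughout, which assumes concordance for the single pair detected
#' in both subsets (SPP1 rs9138 with the IRF1 transcript). The table is the
#' standard worked example for [sharing_analysis()]: it yields 1 shared
#' pair, 5 CL-exclusive and 18 NCL-exclusive pairs.
#'
#' @return A tibble with columns `locus`, `rsid`, `gene`, `method`,
#'   `cell_type`, `direction`.
#' @export
monocyte_eqtl_hits <- function() {
  path <- system.file("extdata", "monocyte_eqtl_hits.tsv", package = "monoqtl",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}
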