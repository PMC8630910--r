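# shared fixture builders and independent oracles

# tiny long-form CT tibble from a wide matrix of CT values
make_ct_tbl <- function(values, individual_id = NULL, cell_type = "CL",
                        capture_flag = "singlet", genes = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  genes <- genes %||% paste0("G", seq_len(ncol(values)))
  individual_id <- individual_id %||% paste0("I", seq_len(n))
  tibble::tibble(
    cell_id = rep(sprintf("C%03d", seq_len(n)), times = ncol(values)),
    individual_id = rep(individual_id, times = ncol(values)),
    cell_type = rep(rep_len(cell_type, n), times = ncol(values)),
    capture_flag = rep(rep_len(capture_flag, n), times = ncol(values)),
    gene = rep(genes, each = n),
    ct = as.vector(values)
  )
}

# per-cell model-fit data frame
make_fit_data <- function(expression, dosage_by_ind, cells_per_ind) {
  n_ind <- length(dosage_by_ind)
  ind <- rep(seq_len(n_ind), each = cells_per_ind)
  tibble::tibble(
    expression = expression,
    dosage = dosage_by_ind[ind],
    individual_id = sprintf("I%02d", ind)
  )
}

# independent brute-force Benjamini-Hochberg step-up oracle:
# sort, adjust by m/i, enforce monotonicity by cumulative minimum from the top
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# independent set-intersection oracle for sharing counts
sharing_oracle <- function(sig) {
  key <- function(d) paste(d$rsid, d$gene)
  cl <- sig[sig$cell_type == "CL", ]
  ncl <- sig[sig$cell_type == "NCL", ]
  cl_pairs <- unique(key(cl))
  ncl_pairs <- unique(key(ncl))
  both <- intersect(cl_pairs, ncl_pairs)
  dir_of <- function(d, k) {
    d <- d[key(d) == k, ]
    d$direction[which.min(rank(d$fdr_q %||% rep(1, nrow(d)), ties.method = "first"))]
  }
  shared <- vapply(both, function(k) {
    identical(dir_of(cl, k), dir_of(ncl, k))
  }, logical(1))
  list(
    n_shared = sum(shared),
    n_discordant = sum(!shared),
    n_cl_exclusive = length(setdiff(cl_pairs, ncl_pairs)) + sum(!shared),
    n_ncl_exclusive = length(setdiff(ncl_pairs, cl_pairs)) + sum(!shared)
  )
}
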