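# Seeded synthetic-data generator. Emulates the statistical structure the
# analysis assumes: a latent per-(gene, individual) log-mean with person
# random effects, detection (dropout) probability that rises with the latent
# mean (missing-not-at-random), a truncated-Normal detected amplitude mapped
# back to CT values, optional person-level on/off switches, planted dosage
# effects in the mean or detection channel, and cell-level co-expression
# block factors.

#' Configuration for the synthetic single-cell qPCR generator
#'
#' Defaults mirror the scale of a 15-person, two-monocyte-subset qPCR panel
#' study: ~30 cells per individual per cell type, 90 genes, 7 biallelic SNPs.
#'
#' @param n_individuals Number of individuals.
#' @param cells_per_individual Cells per individual per cell type.
#' @param cell_types Cell-type labels.
#' @param n_genes Number of genes (ids `G001`, ...).
#' @param snp_mafs Named or unnamed vector of minor-allele frequencies, one
#'   per SNP (unnamed SNPs get ids `snp1`, ...).
#' @param total_cycles,lod PCR cycle count and limit-of-detection CT.
#' @param gene_mean_range Range of per-gene baseline detected-expression
#'   means (cycles above threshold); baselines are drawn uniformly and enter
#'   the model on the log scale.
#' @param sigma Within-cell standard deviation of detected expression.
#' @param person_intercept_sd SD of the per-(gene, individual) random
#'   intercept on the log-mean scale.
#' @param person_shared_frac Fraction of the person-intercept variance shared
#'   across genes within an individual (creates the cross-gene
#'   between-person structure that pooled correlations pick up).
#' @param detection_intercept,detection_slope Logistic model for detection
#'   probability as a function of the latent log-mean.
#' @param mcar If `TRUE`, detection ignores the latent mean and uses the
#'   fixed `detection_prob` (missing-completely-at-random toggle for oracle
#'   checks).
#' @param detection_prob Detection probability under `mcar = TRUE`.
#' @param effects List of planted dosage effects; each element is a list with
#'   `gene`, `rsid`, `size`, `channel` (`"mean"` adds `size * dosage` to the
#'   latent log-mean; `"detection"` adds it to the detection logit) and
#'   optional `cell_type` (default: both).
#' @param on_off Named numeric vector: per-gene probability that an
#'   individual's cells are all forced off (the person-level on/off
#'   pattern).
#' @param blocks List of co-expression blocks; each element is a list with
#'   `genes` and `cor` (target within-block correlation of detected
#'   expression, induced by a shared per-cell latent factor).
#' @param doublet_rate Probability a captured well is flagged a doublet.
#' @param seed Mandatory RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_individuals = 15, cells_per_individual = 30,
                       cell_types = c("CL", "NCL"), n_genes = 90,
                       snp_mafs = seq(0.1, 0.4, length.out = 7),
                       total_cycles = 40, lod = 28,
                       gene_mean_range = c(14, 24), sigma = 2,
                       person_intercept_sd = 1, person_shared_frac = 0.5,
                       detection_intercept = -2, detection_slope = 1,
                       mcar = FALSE, detection_prob = 0.8,
                       effects = list(), on_off = numeric(0),
                       blocks = list(), doublet_rate = 0, seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory in sim_config()")
  if (lod >= total_cycles) abort("`lod` must be smaller than `total_cycles`",
                                 class = "monoqtl_config_error")
  if (any(snp_mafs <= 0 | snp_mafs >= 0.5)) abort("snp_mafs must lie in (0, 0.5)")
  if (person_shared_frac < 0 || person_shared_frac > 1) {
    abort("person_shared_frac must lie in [0, 1]")
  }
  if (detection_prob < 0 || detection_prob > 1) abort("detection_prob must lie in [0, 1]")
  if (doublet_rate < 0 || doublet_rate > 1) abort("doublet_rate must lie in [0, 1]")
  genes <- sprintf("G%03d", seq_len(n_genes))
  if (is.null(names(snp_mafs))) names(snp_mafs) <- paste0("snp", seq_along(snp_mafs))
  for (eff in effects) {
    if (!all(c("gene", "rsid", "size", "channel") %in% names(eff))) {
      abort("each planted effect needs gene, rsid, size and channel")
    }
    if (!eff$gene %in% genes) abort(sprintf("planted effect gene %s not in panel", eff$gene))
    if (!eff$rsid %in% names(snp_mafs)) {
      abort(sprintf("planted effect SNP %s not among simulated SNPs", eff$rsid))
    }
    if (!eff$channel %in% c("mean", "detection")) {
      abort("effect channel must be 'mean' or 'detection'")
    }
  }
  if (length(on_off) > 0) {
    if (is.null(names(on_off)) || !all(names(on_off) %in% genes)) {
      abort("on_off must be a named vector over panel genes")
    }
    if (any(on_off < 0 | on_off > 1)) abort("on_off probabilities must lie in [0, 1]")
  }
  for (b in blocks) {
    if (!all(c("genes", "cor") %in% names(b)) || !all(b$genes %in% genes)) {
      abort("each block needs `genes` (in the panel) and `cor`")
    }
    if (b$cor < 0 || b$cor >= 1) abort("block correlation must lie in [0, 1)")
  }
  structure(
    list(n_individuals = n_individuals, cells_per_individual = cells_per_individual,
         cell_types = cell_types, n_genes = n_genes, genes = genes,
         snp_mafs = snp_mafs, total_cycles = total_cycles, lod = lod,
         gene_mean_range = gene_mean_range, sigma = sigma,
         person_intercept_sd = person_intercept_sd,
         person_shared_frac = person_shared_frac,
         detection_intercept = detection_intercept,
         detection_slope = detection_slope,
         mcar = mcar, detection_prob = detection_prob,
         effects = effects, on_off = on_off, blocks = blocks,
         doublet_rate = doublet_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' @param maf Minor-allele frequency in (0, 0.5).
#' @param n_individuals Number of individuals.
#' @param seed Optional seed (set only if supplied).
#' @return Integer dosage vector with entries in 0/1/2.
#' @export
simulate_genotypes <- function(maf, n_individuals, seed = NULL) {
  if (maf <= 0 || maf >= 0.5) abort("maf must lie in (0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  sample(0:2, n_individuals, replace = TRUE, prob = probs)
}

#' Simulate a single-cell qPCR dataset with known truth
#'
#' Generates genotypes, latent per-(gene, individual) log-means with person
#' random effects, dropout via a logistic detection model on the latent
#' mean, detected expression as truncated Normal amplitudes mapped to CT
#' values (`ct = total_cycles - expression`; non-detected cells carry a
#' missing CT, which downstream scoring treats as expression 0), planted
#' dosage effects, person-level on/off switches and co-expression block
#' factors.
#'
#' @param config A [sim_config()].
#' @return A list with `ct` (long CT tibble as from [read_ct_matrix()]),
#'   `genotypes` (long dosage tibble) and `truth` (realised person effects,
#'   planted-effect registry, block membership, on/off switch states, the
#'   config and seed).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_ind <- config$n_individuals
  individuals <- sprintf("I%02d", seq_len(n_ind))
  genes <- config$genes
  n_genes <- length(genes)

  dosages <- vapply(config$snp_mafs, simulate_genotypes,
                    integer(n_ind), n_individuals = n_ind)
  rownames(dosages) <- individuals
  genotypes <- as_tibble(dosages, rownames = "individual_id") |>
    tidyr::pivot_longer(-"individual_id", names_to = "rsid", values_to = "dosage") |>
    mutate(dosage = as.integer(.data$dosage))

  baseline_mean <- runif(n_genes, config$gene_mean_range[1], config$gene_mean_range[2])
  names(baseline_mean) <- genes

  # person intercepts: shared-across-genes component + gene-specific component
  f <- config$person_shared_frac
  shared <- rnorm(n_ind)
  gene_specific <- matrix(rnorm(n_ind * n_genes), n_ind, n_genes)
  person_intercept <- config$person_intercept_sd *
    (sqrt(f) * shared + sqrt(1 - f) * gene_specific)
  dimnames(person_intercept) <- list(individuals, genes)

  # person-level on/off switches
  off_state <- matrix(FALSE, n_ind, n_genes, dimnames = list(individuals, genes))
  for (g in names(config$on_off)) {
    off_state[, g] <- runif(n_ind) < config$on_off[g]
  }

  block_of <- rep(NA_integer_, n_genes)
  names(block_of) <- genes
  for (bi in seq_along(config$blocks)) {
    block_of[config$blocks[[bi]]$genes] <- bi
  }

  # planted effect lookups: per (gene, individual) log-mean / logit shifts
  shift_for <- function(channel, ct_level) {
    out <- matrix(0, n_ind, n_genes, dimnames = list(individuals, genes))
    for (eff in config$effects) {
      if (eff$channel != channel) next
      eff_types <- eff$cell_type %||% config$cell_types
      if (!ct_level %in% eff_types) next
      out[, eff$gene] <- out[, eff$gene] + eff$size * dosages[, eff$rsid]
    }
    out
  }

  floor_expr <- config$total_cycles - config$lod
  rows <- list()
  cell_counter <- 0L
  for (ct_level in config$cell_types) {
    mean_shift <- shift_for("mean", ct_level)
    det_shift <- shift_for("detection", ct_level)
    for (i in seq_len(n_ind)) {
      n_cells <- config$cells_per_individual
      cell_ids <- sprintf("C%05d", cell_counter + seq_len(n_cells))
      cell_counter <- cell_counter + n_cells
      flags <- ifelse(runif(n_cells) < config$doublet_rate, "doublet", "singlet")
      # cell x gene latent log-mean
      eta <- matrix(log(baseline_mean), n_cells, n_genes, byrow = TRUE) +
        matrix(person_intercept[i, ] + mean_shift[i, ], n_cells, n_genes, byrow = TRUE)
      # block factors: shared per-cell factor; sqrt(cor) loading on the
      # amplitude noise keeps the within-block correlation of detected
      # expression at the configured value
      block_noise <- matrix(rnorm(n_cells * n_genes), n_cells, n_genes)
      for (bi in seq_along(config$blocks)) {
        b <- config$blocks[[bi]]
        f_cell <- rnorm(n_cells)
        idx <- match(b$genes, genes)
        block_noise[, idx] <- sqrt(b$cor) * f_cell +
          sqrt(1 - b$cor) * block_noise[, idx]
      }
      # detection
      if (config$mcar) {
        p_det <- matrix(config$detection_prob, n_cells, n_genes)
      } else {
        p_det <- stats::plogis(config$detection_intercept +
                                 config$detection_slope * eta +
                                 matrix(det_shift[i, ], n_cells, n_genes, byrow = TRUE))
      }
      detected <- matrix(runif(n_cells * n_genes) < p_det, n_cells, n_genes)
      detected[, off_state[i, ]] <- FALSE
      # detected amplitude: Normal around the latent mean, truncated to the
      # detectable expression window. The standard-normal noise (correlated
      # within blocks) enters through a Gaussian copula so the truncated
      # marginals keep the block correlation without a boundary point mass.
      mu <- pmin(exp(eta), config$total_cycles - 1e-3)
      amp <- matrix(NA_real_, n_cells, n_genes)
      idx_det <- which(detected)
      if (length(idx_det) > 0) {
        u <- pnorm(block_noise[idx_det])
        pl <- pnorm(floor_expr, mu[idx_det], config$sigma)
        pu <- pnorm(config$total_cycles, mu[idx_det], config$sigma)
        z <- qnorm(pl + u * (pu - pl), mu[idx_det], config$sigma)
        amp[idx_det] <- pmin(pmax(z, floor_expr + 1e-6), config$total_cycles)
      }
      ct_vals <- config$total_cycles - amp # NA where non-detected
      rows[[length(rows) + 1L]] <- tibble(
        cell_id = rep(cell_ids, times = n_genes),
        individual_id = individuals[i],
        cell_type = ct_level,
        capture_flag = rep(flags, times = n_genes),
        gene = rep(genes, each = n_cells),
        ct = as.vector(ct_vals)
      )
    }
  }
  ct <- bind_rows(rows) |> arrange(.data$cell_id, .data$gene)

  truth <- list(
    genotypes = genotypes,
    baseline_mean = baseline_mean,
    person_intercept = person_intercept,
    effects = config$effects,
    on_off_state = off_state,
    block_of = block_of,
    seed = config$seed,
    config = config
  )
  list(ct = ct, genotypes = genotypes, truth = truth)
}

#' Canned fixtures for calibration and power studies
#'
#' `make_null_fixture()` generates a dataset with no planted effects;
#' `make_powered_fixture()` plants documented effects: a detection-channel
#' eQTL (logit 1.5/allele) and a mean-channel eQTL (log-mean 0.5/allele) on
#' separate genes and SNPs, a person-level on/off gene, and a 10-gene
#' co-expression block when the panel is large enough.
#'
#' @param seed RNG seed.
#' @param n_genes,n_snps Panel size (scans over large panels with the
#'   slower mixed models can take long; fixtures default to a compact panel).
#' @param ... Further arguments passed to [sim_config()].
#' @return As [simulate_expression()].
#' @export
make_null_fixture <- function(seed, n_genes = 12, n_snps = 2, ...) {
  cfg <- sim_config(n_genes = n_genes,
                    snp_mafs = seq(0.2, 0.35, length.out = n_snps),
                    seed = seed, ...)
  simulate_expression(cfg)
}

#' @rdname make_null_fixture
#' @param detection_intercept Detection-logit intercept; the powered fixture
#'   lowers it so baseline detection sits mid-range, where the planted
#'   dropout-channel effect is informative.
#' @param cells_per_individual Cells per individual per cell type; the
#'   powered fixture defaults to 40, the size used by the fitter-validation
#'   simulations.
#' @export
make_powered_fixture <- function(seed, n_genes = 12, n_snps = 2,
                                 detection_intercept = -3.5,
                                 cells_per_individual = 40, ...) {
  # detection-channel plant goes on the last (highest-MAF) SNP so the
  # genotype groups are as balanced as a 15-person cohort allows
  effects <- list(
    list(gene = "G001", rsid = paste0("snp", n_snps), size = 1.5,
         channel = "detection"),
    list(gene = "G002", rsid = "snp1", size = 0.5, channel = "mean")
  )
  on_off <- c(G003 = 0.4)
  blocks <- if (n_genes >= 20) {
    list(list(genes = sprintf("G%03d", 5:14), cor = 0.8))
  } else {
    list()
  }
  cfg <- sim_config(n_genes = n_genes,
                    snp_mafs = seq(0.3, 0.4, length.out = n_snps),
                    detection_intercept = detection_intercept,
                    cells_per_individual = cells_per_individual,
                    effects = effects, on_off = on_off, blocks = blocks,
                    seed = seed, ...)
  simulate_expression(cfg)
}

#' Simulate directly from a Tweedie or logistic GLMM
#'
#' Oracle-check generators that draw responses straight from the fitted
#' model families (compound Poisson-gamma for the Tweedie; Bernoulli with a
#' logit link for the logistic), with an additive dosage effect and a
#' Normal person random intercept. Used to verify that the fitters recover
#' planted coefficients.
#'
#' @param n_individuals,cells_per_individual Cohort and cell counts.
#' @param beta Dosage effect (log-mean or log-odds per minor allele).
#' @param intercept Fixed intercept on the link scale.
#' @param re_sd Person random-intercept SD.
#' @param maf Minor-allele frequency for the simulated SNP.
#' @param power,phi Tweedie power index and dispersion.
#' @param seed Optional seed.
#' @return A tibble with `expression`, `dosage`, `individual_id`.
#' @export
simulate_tweedie_glmm <- function(n_individuals = 15, cells_per_individual = 40,
                                  beta = 0.5, intercept = log(5), re_sd = 0.5,
                                  maf = 0.3, power = 1.5, phi = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dosage <- simulate_genotypes(maf, n_individuals)
  u <- rnorm(n_individuals, 0, re_sd)
  ind <- rep(seq_len(n_individuals), each = cells_per_individual)
  mu <- exp(intercept + beta * dosage[ind] + u[ind])
  tibble(
    expression = rtweedie(length(ind), mu = mu, power = power, phi = phi),
    dosage = dosage[ind],
    individual_id = sprintf("I%02d", ind)
  )
}

#' @rdname simulate_tweedie_glmm
#' @export
simulate_logistic_glmm <- function(n_individuals = 15, cells_per_individual = 40,
                                   beta = 1, intercept = 0, re_sd = 1,
                                   maf = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dosage <- simulate_genotypes(maf, n_individuals)
  u <- rnorm(n_individuals, 0, re_sd)
  ind <- rep(seq_len(n_individuals), each = cells_per_individual)
  p <- stats::plogis(intercept + beta * dosage[ind] + u[ind])
  tibble(
    expression = rbinom(length(ind), 1, p),
    dosage = dosage[ind],
    individual_id = sprintf("I%02d", ind)
  )
}

#' Compound Poisson-gamma (Tweedie) deviates
#'
#' Draws from the Tweedie family with power index in (1, 2): a Poisson
#' number of gamma jumps, giving a point mass at zero and a continuous
#' positive part.
#'
#' @param n Number of deviates.
#' @param mu Mean (scalar or length-n vector).
#' @param power Power index in (1, 2).
#' @param phi Dispersion.
#' @return Numeric vector of non-negative deviates.
#' @export
rtweedie <- function(n, mu, power = 1.5, phi = 1) {
  if (power <= 1 || power >= 2) abort("power must lie in (1, 2)")
  mu <- rep_len(mu, n)
  lambda <- mu^(2 - power) / (phi * (2 - power))
  shape <- (2 - power) / (power - 1)
  scale <- phi * (power - 1) * mu^(power - 1)
  n_jumps <- rpois(n, lambda)
  out <- numeric(n)
  pos <- n_jumps > 0
  out[pos] <- rgamma(sum(pos), shape = shape * n_jumps[pos], scale = scale[pos])
  out
}
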