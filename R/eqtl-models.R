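# The four dropout-aware association methods plus the naive per-cell
# Mann-Whitney comparison. Each fitter takes a data frame with one row per
# cell and columns `expression`, `dosage`, `individual_id`, and returns an
# `eqtl_fit`. Inference on the dosage coefficient is Wald-type; because
# genotype varies only between individuals, the reference distribution is a
# t with `n_individuals - 2` degrees of freedom rather than a normal, which
# keeps small-cohort type I error close to nominal.

new_eqtl_fit <- function(method, estimate = NA_real_, std_error = NA_real_,
                         p_value = NA_real_, converged = FALSE,
                         n_individuals = NA_integer_, n_cells = NA_integer_,
                         reason = NA_character_, model = NULL, extra = list()) {
  structure(
    c(list(method = method, estimate = estimate, std_error = std_error,
           p_value = p_value, converged = converged,
           n_individuals = n_individuals, n_cells = n_cells,
           reason = reason, model = model), extra),
    class = "eqtl_fit"
  )
}

skipped_fit <- function(method, reason, n_individuals = NA_integer_,
                        n_cells = NA_integer_) {
  new_eqtl_fit(method, reason = reason, converged = FALSE,
               n_individuals = n_individuals, n_cells = n_cells)
}

#' @export
print.eqtl_fit <- function(x, ...) {
  cat(sprintf("<eqtl_fit: %s>\n", x$method))
  if (!x$converged) {
    cat(sprintf("  not converged (%s)\n", x$reason %||% "unknown"))
  }
  cat(sprintf("  estimate %.4g (se %.4g), p = %.4g; %d individuals, %d cells\n",
              x$estimate, x$std_error, x$p_value, x$n_individuals, x$n_cells))
  invisible(x)
}

#' @describeIn fit_tweedie_mixed One-row tibble of the dosage-effect estimate.
#' @param x An `eqtl_fit` object.
#' @method tidy eqtl_fit
#' @export
tidy.eqtl_fit <- function(x, ...) {
  tibble(
    method = x$method,
    estimate = x$estimate,
    std_error = x$std_error,
    p_value = x$p_value,
    converged = x$converged,
    n_individuals = x$n_individuals,
    n_cells = x$n_cells,
    reason = x$reason
  )
}

#' @describeIn fit_tweedie_mixed Fit-level summary (convergence, sizes,
#'   Tweedie power where applicable).
#' @method glance eqtl_fit
#' @export
glance.eqtl_fit <- function(x, ...) {
  tibble(
    method = x$method,
    converged = x$converged,
    n_individuals = x$n_individuals,
    n_cells = x$n_cells,
    tweedie_power = x$tweedie_power %||% NA_real_,
    reason = x$reason
  )
}

check_fit_data <- function(data, method) {
  assert_cols(data, c("expression", "dosage", "individual_id"), "model data")
  per_ind <- distinct(data, .data$individual_id, .data$dosage)
  if (anyDuplicated(per_ind$individual_id)) {
    abort("dosage must be constant within individual")
  }
  if (n_distinct(per_ind$dosage) < 2) {
    abort(sprintf("%s: dosage is constant across individuals (no genotype contrast)",
                  method))
  }
  invisible(per_ind)
}

wald_p <- function(estimate, se, n_individuals) {
  df <- max(n_individuals - 2, 1)
  2 * pt(-abs(estimate / se), df = df)
}

#' Dropout-aware mixed-model eQTL fitters
#'
#' Four single-gene association methods designed for zero-inflated
#' single-cell qPCR expression with strong within-person correlation. All
#' model an additive minor-allele dosage effect with a random intercept per
#' individual and return a Wald-type p-value for the dosage coefficient
#' (t reference with `n_individuals - 2` degrees of freedom, since genotype
#' only varies between people):
#'
#' * `fit_tweedie_mixed()` — Tweedie GLMM (power index in (1,2), log link) on
#'   the full expression values, handling the point mass at zero and the
#'   continuous positive part in one model.
#' * `fit_logistic_mixed()` — logistic GLMM on the detection indicator
#'   (`expression > 0`), i.e. the on/off channel.
#' * `fit_gaussian_nonzero_mixed()` — Gaussian linear mixed model on the
#'   detected (non-zero) values only, with Satterthwaite denominator degrees
#'   of freedom.
#' * `fit_proportion_anova()` — one-way ANOVA of per-individual on-proportions
#'   with genotype as a categorical factor (individuals, not cells, are the
#'   units).
#'
#' Degenerate inputs (all-zero gene, single outcome class, too few
#' individuals) yield a non-converged fit with a `reason` rather than an
#' error; a dosage with no between-individual contrast is an error.
#'
#' @param data A data frame with one row per cell and columns `expression`,
#'   `dosage` (minor-allele count 0/1/2, constant within individual) and
#'   `individual_id`.
#' @param power Optional fixed Tweedie power index in (1, 2); the default
#'   `NULL` estimates it alongside the other parameters. Variance parameters
#'   are estimated by REML, which keeps small-cohort Wald tests close to
#'   nominal.
#' @return An `eqtl_fit` object; use [tidy()] for a one-row tibble.
#' @name eqtl_fitters
#' @export
fit_tweedie_mixed <- function(data, power = NULL) {
  check_fit_data(data, "tweedie")
  n_ind <- n_distinct(data$individual_id)
  n_cells <- nrow(data)
  if (all(data$expression == 0)) {
    return(skipped_fit("tweedie", "all_zero", n_ind, n_cells))
  }
  d <- data.frame(y = data$expression, dosage = data$dosage,
                  individual_id = factor(data$individual_id))
  args <- list(
    formula = y ~ dosage + (1 | individual_id),
    data = d,
    family = glmmTMB::tweedie(link = "log"),
    REML = TRUE
  )
  if (!is.null(power)) {
    assert_scalar_number(power, "power", lower = 1 + 1e-6, upper = 2 - 1e-6)
    args$start <- list(psi = stats::qlogis(power - 1))
    args$map <- list(psi = factor(NA))
  }
  fit <- tryCatch(suppressWarnings(do.call(glmmTMB::glmmTMB, args)),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    return(skipped_fit("tweedie", paste0("fit_error: ", conditionMessage(fit)),
                       n_ind, n_cells))
  }
  ok <- isTRUE(fit$sdr$pdHess) && isTRUE(fit$fit$convergence == 0)
  co <- tryCatch(summary(fit)$coefficients$cond, error = function(e) NULL)
  if (is.null(co) || !"dosage" %in% rownames(co) || anyNA(co["dosage", 1:2])) {
    return(skipped_fit("tweedie", "no_dosage_coefficient", n_ind, n_cells))
  }
  est <- co["dosage", "Estimate"]
  se <- co["dosage", "Std. Error"]
  new_eqtl_fit("tweedie", est, se, wald_p(est, se, n_ind),
               converged = ok, n_individuals = n_ind, n_cells = n_cells,
               model = fit,
               reason = if (ok) NA_character_ else "non_convergence",
               extra = list(tweedie_power = unname(glmmTMB::family_params(fit)[1])))
}

#' @rdname eqtl_fitters
#' @param se_max Standard-error ceiling above which a logistic fit is flagged
#'   as (quasi-)separated and excluded from FDR.
#' @export
fit_logistic_mixed <- function(data, se_max = 10) {
  check_fit_data(data, "logistic")
  n_ind <- n_distinct(data$individual_id)
  n_cells <- nrow(data)
  on <- as.numeric(data$expression > 0)
  if (length(unique(on)) < 2) {
    return(skipped_fit("logistic", "single_class", n_ind, n_cells))
  }
  d <- data.frame(on = on, dosage = data$dosage,
                  individual_id = factor(data$individual_id))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(on ~ dosage + (1 | individual_id), data = d, family = stats::binomial)
    )),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(skipped_fit("logistic", paste0("fit_error: ", conditionMessage(fit)),
                       n_ind, n_cells))
  }
  co <- coef(summary(fit))
  est <- co["dosage", "Estimate"]
  se <- co["dosage", "Std. Error"]
  ok <- is.finite(est) && is.finite(se) && se <= se_max
  new_eqtl_fit("logistic", est, se, wald_p(est, se, n_ind),
               converged = ok, n_individuals = n_ind, n_cells = n_cells,
               model = fit,
               reason = if (ok) NA_character_ else "possible_separation")
}

#' @rdname eqtl_fitters
#' @param min_individuals Minimum number of individuals contributing at least
#'   one detected cell for the Gaussian-on-detected model.
#' @export
fit_gaussian_nonzero_mixed <- function(data, min_individuals = 3) {
  check_fit_data(data, "gaussian_nonzero")
  n_ind_all <- n_distinct(data$individual_id)
  pos <- filter(data, .data$expression > 0)
  n_ind <- n_distinct(pos$individual_id)
  if (n_ind < min_individuals) {
    return(skipped_fit("gaussian_nonzero", "too_few_individuals_with_detection",
                       n_ind_all, nrow(pos)))
  }
  if (n_distinct(distinct(pos, .data$individual_id, .data$dosage)$dosage) < 2) {
    return(skipped_fit("gaussian_nonzero", "no_genotype_contrast_in_detected_subset",
                       n_ind, nrow(pos)))
  }
  if (sd(pos$expression) == 0) {
    return(skipped_fit("gaussian_nonzero", "zero_variance", n_ind, nrow(pos)))
  }
  d <- data.frame(y = pos$expression, dosage = pos$dosage,
                  individual_id = factor(pos$individual_id))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ dosage + (1 | individual_id), data = d)
    )),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(skipped_fit("gaussian_nonzero", paste0("fit_error: ", conditionMessage(fit)),
                       n_ind, nrow(pos)))
  }
  co <- coef(summary(fit))
  est <- co["dosage", "Estimate"]
  se <- co["dosage", "Std. Error"]
  p <- co["dosage", "Pr(>|t|)"]
  ok <- is.finite(est) && is.finite(se) && is.finite(p)
  new_eqtl_fit("gaussian_nonzero", est, se, p,
               converged = ok, n_individuals = n_ind, n_cells = nrow(pos),
               model = fit, reason = if (ok) NA_character_ else "non_convergence")
}

#' @rdname eqtl_fitters
#' @param collapse_rare Merge a homozygous-minor group holding fewer than 2
#'   individuals into the heterozygote group before the ANOVA (default TRUE);
#'   the collapse is recorded in the fit's `reason`.
#' @details `fit_proportion_anova()` accepts either per-cell data (columns
#'   `expression`, `dosage`, `individual_id`; on-proportions are computed per
#'   individual) or precomputed per-individual data (columns `on_proportion`,
#'   `dosage`, `individual_id`, one row per individual).
#' @export
fit_proportion_anova <- function(data, collapse_rare = TRUE) {
  if ("on_proportion" %in% names(data) && !"expression" %in% names(data)) {
    assert_cols(data, c("on_proportion", "dosage", "individual_id"), "model data")
    if (anyDuplicated(data$individual_id)) {
      abort("per-individual input must have one row per individual")
    }
    if (n_distinct(data$dosage) < 2) {
      abort("proportion_anova: dosage is constant across individuals (no genotype contrast)")
    }
    props <- as_tibble(data[c("individual_id", "dosage", "on_proportion")])
    n_cells <- NA_integer_
  } else {
    check_fit_data(data, "proportion_anova")
    n_cells <- nrow(data)
    props <- data |>
      group_by(.data$individual_id, .data$dosage) |>
      summarise(on_proportion = mean(.data$expression > 0), .groups = "drop")
  }
  n_ind <- nrow(props)
  props$genotype <- props$dosage
  note <- NA_character_
  if (collapse_rare && sum(props$genotype == 2) > 0 && sum(props$genotype == 2) < 2) {
    props$genotype[props$genotype == 2] <- 1
    note <- "collapsed_hom_minor_into_het"
  }
  if (n_distinct(props$genotype) < 2) {
    return(skipped_fit("proportion_anova", "single_genotype_group_after_collapse",
                       n_ind, n_cells))
  }
  small <- props |>
    count(.data$genotype) |>
    filter(.data$n < 2)
  if (nrow(small) > 0 && !collapse_rare) {
    note <- paste0(c(note[!is.na(note)], "group_with_single_individual"), collapse = ";")
  }
  props$genotype <- factor(props$genotype)
  fit <- aov(on_proportion ~ genotype, data = props)
  tab <- anova(fit)
  f_stat <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  # direction summary: carriers (het + hom-minor) vs major homozygotes
  mean_major <- mean(props$on_proportion[props$dosage == 0])
  mean_carrier <- mean(props$on_proportion[props$dosage > 0])
  est <- mean_carrier - mean_major
  ok <- is.finite(f_stat) && is.finite(p)
  new_eqtl_fit("proportion_anova", estimate = est, std_error = NA_real_,
               p_value = if (ok) p else NA_real_, converged = ok,
               n_individuals = n_ind, n_cells = n_cells, model = fit,
               reason = if (ok) note else "zero_within_group_variance",
               extra = list(f_statistic = f_stat,
                            df = unname(tab$Df[1:2])))
}

#' @rdname eqtl_fitters
#' @details `fit_naive_mw()` is the deliberately naive per-cell comparison
#'   used only as a calibration contrast: a two-sided Mann-Whitney U test of
#'   major-allele homozygote cells against minor-allele-carrier cells that
#'   ignores the within-person correlation (pseudoreplication), which
#'   inflates its type I error.
#' @export
fit_naive_mw <- function(data) {
  check_fit_data(data, "naive_mw")
  n_ind <- n_distinct(data$individual_id)
  n_cells <- nrow(data)
  g0 <- data$expression[data$dosage == 0]
  g1 <- data$expression[data$dosage > 0]
  if (length(g0) == 0 || length(g1) == 0) {
    return(skipped_fit("naive_mw", "empty_genotype_group", n_ind, n_cells))
  }
  if (length(unique(data$expression)) == 1) {
    return(new_eqtl_fit("naive_mw", estimate = 0, std_error = NA_real_,
                        p_value = 1, converged = TRUE,
                        n_individuals = n_ind, n_cells = n_cells,
                        reason = "all_values_tied"))
  }
  wt <- suppressWarnings(wilcox.test(g1, g0, exact = FALSE))
  new_eqtl_fit("naive_mw", estimate = median(g1) - median(g0),
               std_error = NA_real_, p_value = wt$p.value, converged = TRUE,
               n_individuals = n_ind, n_cells = n_cells)
}
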