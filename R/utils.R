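# internal helpers shared across modules

CELL_TYPES <- c("CL", "NCL")
CAPTURE_FLAGS <- c("singlet", "doublet", "empty")

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "monoqtl_format_error")
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# sample from Normal(mean, sd) truncated to (lower, upper] by inverse CDF
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  u <- runif(n, pl, pu)
  q <- qnorm(u, mean, sd)
  # guard against u numerically equal to 0/1
  pmin(pmax(q, lower + 1e-9), upper)
}

sign_label <- function(x) {
  dplyr::case_when(
    is.na(x) | x == 0 ~ "undefined",
    x > 0 ~ "+",
    TRUE ~ "-"
  )
}
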