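#' Fisher-z confidence interval for a correlation coefficient
#'
#' Transforms `r` to `atanh(r)`, whose sampling distribution is
#' approximately normal with standard error `1/sqrt(n - 3)`, and
#' back-transforms the symmetric normal interval.
#'
#' @param r Correlation coefficient in (-1, 1); at exactly +/-1 the
#'   interval degenerates to the point `r` itself.
#' @param n Number of pairs (> 3).
#' @param level Coverage probability, default 0.95.
#' @return List with `lower` and `upper`.
#' @examples
#' fisher_ci(0.934, 5391)  # upper ~ 0.937
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  stopifnot(n > 3, level > 0, level < 1, abs(r) <= 1)
  if (abs(r) == 1) return(list(lower = r, upper = r))
  z <- atanh(r)
  half <- stats::qnorm((1 + level) / 2) / sqrt(n - 3)
  list(lower = tanh(z - half), upper = tanh(z + half))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Computes the sample Pearson coefficient over pairwise-complete entries
#' of `x` and `y` with its Fisher-z interval.
#'
#' @param x,y Numeric vectors of equal length.
#' @param level Coverage probability.
#' @return List with `r`, `ci_low`, `ci_high` and `n` (complete pairs).
#'   Fewer than 4 complete pairs, or zero variance in either vector, is an
#'   error.
#' @export
pearson_with_ci <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  n <- sum(ok)
  if (n < 4)
    stop("pearson_with_ci: need at least 4 complete pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_with_ci: correlation undefined for zero-variance input")
  r <- stats::cor(x, y)
  ci <- fisher_ci(r, n, level)
  list(r = r, ci_low = ci$lower, ci_high = ci$upper, n = n)
}

#' Age-adjusted residuals of a trait
#'
#' Ordinary least-squares residuals of `values` regressed on `ages`
#' (intercept plus linear age term). Fitted separately per sex by the
#' caller, this removes the linear age trend so that remaining within-pair
#' correlation cannot be an artefact of partners having similar ages.
#'
#' @param values Numeric vector.
#' @param ages Numeric vector of the same length.
#' @return Residual vector aligned with the input; entries with a missing
#'   value or age are `NA`. Residuals over complete entries sum to zero.
#'   Fewer than 3 complete pairs, or all ages identical, is an error.
#' @export
age_residuals <- function(values, ages) {
  stopifnot(length(values) == length(ages))
  ok <- !(is.na(values) | is.na(ages))
  if (sum(ok) < 3)
    stop("age_residuals: need at least 3 complete (value, age) pairs")
  if (stats::sd(ages[ok]) == 0)
    stop("age_residuals: age coefficient unidentifiable (all ages equal)")
  fit <- stats::lm(values[ok] ~ ages[ok])
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::residuals(fit)
  out
}

# mapping from user-facing variable names to derived columns; `eligible`
# marks variables restricted to treatment-eligible individuals
.similarity_variables <- list(
  age = list(col = "age", transform = "none", adjustable = FALSE),
  weight = list(col = "weight", transform = "none"),
  height = list(col = "height", transform = "none"),
  waist = list(col = "waist", transform = "none"),
  bmi = list(col = "bmi", transform = "none"),
  sbp = list(col = "sbp_adj", transform = "none"),
  dbp = list(col = "dbp_adj", transform = "none"),
  hba1c = list(col = "hba1c", transform = "none", eligible = TRUE),
  tc = list(col = "tc_adj", transform = "none"),
  tg = list(col = "log_tg", transform = "log10"),
  hdl = list(col = "hdl", transform = "none"),
  ldl = list(col = "ldl_adj", transform = "none")
)

#' Names of the continuous similarity variables
#' @return Character vector accepted by [pair_correlation()].
#' @export
similarity_variables <- function() names(.similarity_variables)

#' Within-pair correlation of a continuous risk factor
#'
#' Assembles the (male value, female value) pairs for one variable using
#' pairwise-complete deletion — a pair is dropped if either member lacks
#' the (harmonized, outlier-filtered) value, and for HbA1c additionally if
#' either member is on glucose-lowering medication or their medication
#' status is unknown — and returns the simple Pearson correlation plus,
#' unless suppressed or the variable is age itself, the correlation of
#' sex-stratified age residuals computed over exactly the individuals
#' entering the analysis. Triglycerides are analysed on the log10 scale;
#' blood pressure and cholesterol as their medication back-adjusted values.
#'
#' @param derived A [derive_all()] result.
#' @param variable One of [similarity_variables()].
#' @param adjusted Compute the age-adjusted correlation as well?
#' @param level Coverage probability for the Fisher-z intervals. The
#'   adjusted interval reuses the `n - 3` Fisher formula without a
#'   degrees-of-freedom correction for the age regressions, a documented
#'   approximation.
#' @return A one-row data frame of class `correlation_result`: `variable`,
#'   `n_pairs`, `r_simple`, `ci_simple_low/high`, `r_adjusted`,
#'   `ci_adjusted_low/high` (`NA` when not computed), `transform`.
#' @export
pair_correlation <- function(derived, variable, adjusted = TRUE,
                             level = 0.95) {
  spec <- .similarity_variables[[variable]]
  if (is.null(spec))
    stop(sprintf("pair_correlation: unknown variable '%s'", variable))
  part <- derived$participants
  pairs <- derived$pairs
  im <- match(pairs$male_id, part$id)
  iff <- match(pairs$female_id, part$id)
  xm <- part[[spec$col]][im]
  xf <- part[[spec$col]][iff]
  ok <- !(is.na(xm) | is.na(xf))
  if (isTRUE(spec$eligible)) {
    em <- part$hba1c_analysis_eligible[im]
    ef <- part$hba1c_analysis_eligible[iff]
    ok <- ok & !is.na(em) & !is.na(ef) & em & ef
  }
  if (sum(ok) < 4)
    stop(sprintf("pair_correlation: fewer than 4 usable pairs for '%s'",
                 variable))
  xm <- xm[ok]; xf <- xf[ok]
  simple <- pearson_with_ci(xm, xf, level)

  r_adj <- ci_adj_lo <- ci_adj_hi <- NA_real_
  if (adjusted && !isFALSE(spec$adjustable)) {
    am <- part$age[im][ok]
    af <- part$age[iff][ok]
    rm_ <- age_residuals(xm, am)
    rf_ <- age_residuals(xf, af)
    adj <- pearson_with_ci(rm_, rf_, level)
    r_adj <- adj$r; ci_adj_lo <- adj$ci_low; ci_adj_hi <- adj$ci_high
  }
  structure(data.frame(variable = variable, n_pairs = simple$n,
                       r_simple = simple$r,
                       ci_simple_low = simple$ci_low,
                       ci_simple_high = simple$ci_high,
                       r_adjusted = r_adj,
                       ci_adjusted_low = ci_adj_lo,
                       ci_adjusted_high = ci_adj_hi,
                       transform = spec$transform,
                       stringsAsFactors = FALSE),
            class = c("correlation_result", "data.frame"))
}

#' Correlation table for all continuous risk factors
#'
#' Runs [pair_correlation()] over every variable in `variables` and stacks
#' the rows into the shape of the study's correlation table: per variable,
#' the number of usable pairs, the simple correlation with its interval and
#' the age-adjusted correlation with its interval (age has no adjusted
#' entry).
#'
#' @param derived A [derive_all()] result.
#' @param variables Subset of [similarity_variables()].
#' @param level Coverage probability.
#' @return Data frame, one row per variable.
#' @export
correlation_table <- function(derived, variables = similarity_variables(),
                              level = 0.95) {
  rows <- lapply(variables, function(v)
    pair_correlation(derived, v, adjusted = TRUE, level = level))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
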