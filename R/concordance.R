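#' Odds ratio of a 2x2 table with Woolf interval
#'
#' Cross-product odds ratio `(a*d)/(b*c)` with the Woolf confidence
#' interval `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. This is
#' also the exact maximum-likelihood estimate of the saturated logistic
#' model, which makes it the independent oracle for the crude concordance
#' fit.
#'
#' @param a,b,c,d Cell counts: `a` exposed cases, `b` exposed non-cases,
#'   `c` unexposed cases, `d` unexposed non-cases. Any zero cell is an
#'   error (no automatic continuity correction is applied; sparse tables
#'   should be handled explicitly by the caller).
#' @param level Coverage probability.
#' @return List with `or`, `ci_low`, `ci_high`.
#' @examples
#' two_by_two_or(30, 20, 20, 30)$or  # 2.25
#' @export
two_by_two_or <- function(a, b, c, d, level = 0.95) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0))
  if (any(counts == 0))
    stop(paste("two_by_two_or: zero cell; the Woolf interval is undefined.",
               "Consider a continuity correction explicitly",
               "(none is applied automatically)."))
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm((1 + level) / 2)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se))
}

# user-facing outcome names -> derived logical columns
.concordance_outcomes <- c(
  current_smoker = "current_smoker",
  current_drinker = "current_drinker",
  sufficiently_active = "sufficiently_active",
  hypertension = "hypertension",
  diabetes = "diabetes",
  metabolic_syndrome = "metabolic_syndrome"
)

#' Names of the binary concordance outcomes
#' @return Character vector accepted by [fit_concordance()].
#' @export
concordance_outcomes <- function() names(.concordance_outcomes)

#' Crude and age-adjusted concordance odds ratios for a binary trait
#'
#' Quantifies within-pair concordance by logistic regression of the male
#' partner's status on the female partner's status (the exposure). The
#' crude model has the female status as sole covariate; the age-adjusted
#' model adds the pair's mean age `(age_m + age_f)/2` and age difference
#' `age_m - age_f`, which together carry the full two-dimensional age
#' information of the pair. Odds ratios above 1 indicate concordance.
#' Confidence intervals are Wald intervals on the log-odds scale.
#'
#' @param derived A [derive_all()] result (spouse or randomized pairing).
#' @param outcome One of [concordance_outcomes()]. Pairs with either
#'   member's status missing are dropped.
#' @param level Coverage probability.
#' @return A one-row data frame of class `concordance_result`: `outcome`,
#'   `n_pairs`, `crude_or`, `crude_ci_low/high`, `crude_p`, `adjusted_or`,
#'   `adjusted_ci_low/high`, `adjusted_p`.
#' @export
fit_concordance <- function(derived, outcome, level = 0.95) {
  if (!outcome %in% names(.concordance_outcomes))
    stop(sprintf("fit_concordance: unknown outcome '%s'", outcome))
  col <- .concordance_outcomes[[outcome]]
  part <- derived$participants
  pairs <- derived$pairs
  im <- match(pairs$male_id, part$id)
  iff <- match(pairs$female_id, part$id)
  d <- data.frame(
    y_m = as.integer(part[[col]][im]),
    y_f = as.integer(part[[col]][iff]),
    mean_age = (part$age[im] + part$age[iff]) / 2,
    age_diff = part$age[im] - part$age[iff]
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10)
    stop(sprintf("fit_concordance: fewer than 10 usable pairs for '%s'",
                 outcome))
  crude <- glm_or(y_m ~ y_f, d, "y_f", outcome, level)
  adjusted <- glm_or(y_m ~ y_f + mean_age + age_diff, d, "y_f", outcome,
                     level)
  structure(data.frame(outcome = outcome, n_pairs = nrow(d),
                       crude_or = crude$or,
                       crude_ci_low = crude$ci_low,
                       crude_ci_high = crude$ci_high,
                       crude_p = crude$p,
                       adjusted_or = adjusted$or,
                       adjusted_ci_low = adjusted$ci_low,
                       adjusted_ci_high = adjusted$ci_high,
                       adjusted_p = adjusted$p,
                       stringsAsFactors = FALSE),
            class = c("concordance_result", "data.frame"))
}

# Wald OR for one coefficient of a logistic fit; fails loudly on
# non-convergence or separation (runaway coefficient / standard error)
glm_or <- function(formula, data, term, outcome, level) {
  fit <- stats::glm(formula, data = data, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 50))
  if (!fit$converged)
    stop(sprintf("fit_concordance: model for '%s' did not converge", outcome))
  sm <- summary(fit)$coefficients
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  if (abs(est) > 15 || se > 100)
    stop(sprintf(paste("fit_concordance: apparent separation for '%s'",
                       "(|log OR| or its standard error is extreme)"),
         outcome))
  z <- stats::qnorm((1 + level) / 2)
  list(or = exp(est), ci_low = exp(est - z * se), ci_high = exp(est + z * se),
       p = 2 * stats::pnorm(-abs(est / se)))
}

#' Concordance table for all binary outcomes
#'
#' Runs [fit_concordance()] over the lifestyle and disease outcomes and
#' adds conventional significance markers (* p < 0.05, ** p < 0.01,
#' *** p < 0.001) for the crude and adjusted estimates.
#'
#' @param derived A [derive_all()] result.
#' @param outcomes Subset of [concordance_outcomes()].
#' @param level Coverage probability.
#' @return Data frame, one row per outcome, with `crude_sig` and
#'   `adjusted_sig` marker columns.
#' @export
concordance_table <- function(derived, outcomes = concordance_outcomes(),
                              level = 0.95) {
  rows <- lapply(outcomes, function(o) fit_concordance(derived, o, level))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  marker <- function(p) ifelse(p < 0.001, "***",
                               ifelse(p < 0.01, "**",
                                      ifelse(p < 0.05, "*", "")))
  out$crude_sig <- marker(out$crude_p)
  out$adjusted_sig <- marker(out$adjusted_p)
  out
}
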