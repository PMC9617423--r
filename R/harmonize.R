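#' Medication back-adjustment policy
#'
#' Constants used to reconstruct an individual's pre-treatment ranking:
#' treated blood pressure has the expected treatment effect added back
#' (SBP +15 mmHg, DBP +10 mmHg) and treated lipids are divided by the
#' expected proportional reduction (total cholesterol by 0.8, LDL
#' cholesterol by 0.7).
#'
#' @param sbp_add,dbp_add mmHg added to treated SBP/DBP (>= 0).
#' @param tc_divisor,ldl_divisor Proportional reductions in (0, 1].
#' @return A list of class `treatment_policy`.
#' @export
treatment_policy <- function(sbp_add = 15, dbp_add = 10,
                             tc_divisor = 0.8, ldl_divisor = 0.7) {
  stopifnot(sbp_add >= 0, dbp_add >= 0,
            tc_divisor > 0, tc_divisor <= 1,
            ldl_divisor > 0, ldl_divisor <= 1)
  structure(list(sbp_add = sbp_add, dbp_add = dbp_add,
                 tc_divisor = tc_divisor, ldl_divisor = ldl_divisor),
            class = "treatment_policy")
}

#' Disease and lifestyle classification criteria
#'
#' Thresholds for hypertension (SBP >= 140 or DBP >= 90 mmHg or medication),
#' type 2 diabetes (HbA1c >= 6.5% or medication) and the Japanese metabolic
#' syndrome definition: a mandatory waist-circumference criterion (>= 85 cm
#' in men, >= 90 cm in women) plus at least two of elevated blood pressure
#' (>= 130/85 mmHg or medication), hyperglycaemia (HbA1c >= 6.0% or
#' medication) and dyslipidaemia (TG >= 150 mg/dL or HDL < 40 mg/dL or
#' medication). Also carries the outlier rule (exclude beyond mean +/- 5 SD)
#' and the activity cut-off (80th percentile of the men's MET hours/day).
#'
#' @param htn_sbp,htn_dbp Hypertension thresholds, mmHg.
#' @param dm_hba1c Diabetes HbA1c threshold, percent.
#' @param mets_waist_m,mets_waist_f Waist thresholds, cm.
#' @param mets_sbp,mets_dbp,mets_hba1c,mets_tg,mets_hdl Metabolic-syndrome
#'   component thresholds.
#' @param outlier_sd SD multiples beyond which a value is excluded.
#' @param activity_percentile Percentile of the men's MET hours/day used as
#'   the sufficient-activity cut-off, in (0, 100).
#' @return A list of class `disease_criteria`.
#' @export
disease_criteria <- function(htn_sbp = 140, htn_dbp = 90, dm_hba1c = 6.5,
                             mets_waist_m = 85, mets_waist_f = 90,
                             mets_sbp = 130, mets_dbp = 85,
                             mets_hba1c = 6.0, mets_tg = 150, mets_hdl = 40,
                             outlier_sd = 5, activity_percentile = 80) {
  vals <- c(htn_sbp, htn_dbp, dm_hba1c, mets_waist_m, mets_waist_f,
            mets_sbp, mets_dbp, mets_hba1c, mets_tg, mets_hdl, outlier_sd)
  stopifnot(all(vals > 0),
            activity_percentile > 0, activity_percentile < 100)
  structure(list(htn_sbp = htn_sbp, htn_dbp = htn_dbp, dm_hba1c = dm_hba1c,
                 mets_waist_m = mets_waist_m, mets_waist_f = mets_waist_f,
                 mets_sbp = mets_sbp, mets_dbp = mets_dbp,
                 mets_hba1c = mets_hba1c, mets_tg = mets_tg,
                 mets_hdl = mets_hdl, outlier_sd = outlier_sd,
                 activity_percentile = activity_percentile),
            class = "disease_criteria")
}

#' Body mass index
#'
#' @param weight Weight in kg (> 0).
#' @param height Height in cm (> 0).
#' @return BMI in kg/m^2: `weight / (height/100)^2`. Missing inputs give
#'   missing output; non-positive inputs are a domain error.
#' @examples
#' compute_bmi(80, 200)  # 20
#' @export
compute_bmi <- function(weight, height) {
  ok <- is.na(weight) | is.na(height)
  if (any(!ok & (weight <= 0 | height <= 0)))
    stop("compute_bmi: weight and height must be positive")
  weight / (height / 100)^2
}

#' Friedewald LDL cholesterol
#'
#' Estimates LDL cholesterol as `tc - hdl - tg/5` (all mg/dL). The estimate
#' is invalid at triglycerides of 400 mg/dL and above, where it returns
#' missing; the bound is the standard clinical validity restriction and can
#' be changed via `tg_limit`.
#'
#' @param tc,hdl,tg Total cholesterol, HDL cholesterol and triglycerides in
#'   mg/dL (all >= 0).
#' @param tg_limit Triglyceride validity bound, mg/dL.
#' @return LDL in mg/dL, or `NA` where `tg >= tg_limit` or any input is
#'   missing.
#' @examples
#' friedewald_ldl(200, 50, 100)  # 130
#' friedewald_ldl(200, 50, 400)  # NA
#' @export
friedewald_ldl <- function(tc, hdl, tg, tg_limit = 400) {
  present <- !(is.na(tc) | is.na(hdl) | is.na(tg))
  if (any(present & (tc < 0 | hdl < 0 | tg < 0)))
    stop("friedewald_ldl: inputs must be non-negative")
  out <- tc - hdl - tg / 5
  out[!present | tg >= tg_limit] <- NA_real_
  out
}

#' Back-adjust measurements for medication use
#'
#' Adds the policy's expected treatment effects to the blood pressure of
#' individuals on antihypertensive medication and divides the cholesterol
#' values of individuals on lipid-lowering medication by the expected
#' proportional reduction, producing `sbp_adj`, `dbp_adj`, `tc_adj` and
#' `ldl_adj` columns. Untreated individuals keep their measured values. A
#' missing measurement, or a missing medication flag, yields a missing
#' adjusted value (treatment status unknown means the ranking cannot be
#' reconstructed).
#'
#' @param participants Data frame with `sbp`, `dbp`, `tc`, `ldl`,
#'   `on_antihypertensive` and `on_lipid_lowering` columns.
#' @param policy A [treatment_policy()].
#' @return `participants` with the four `*_adj` columns added.
#' @export
apply_treatment_adjustment <- function(participants,
                                       policy = treatment_policy()) {
  adj_add <- function(x, flag, add)
    ifelse(is.na(flag), NA_real_, x + ifelse(flag, add, 0))
  adj_div <- function(x, flag, div)
    ifelse(is.na(flag), NA_real_, x / ifelse(flag, div, 1))
  participants$sbp_adj <- adj_add(participants$sbp,
                                  participants$on_antihypertensive,
                                  policy$sbp_add)
  participants$dbp_adj <- adj_add(participants$dbp,
                                  participants$on_antihypertensive,
                                  policy$dbp_add)
  participants$tc_adj <- adj_div(participants$tc,
                                 participants$on_lipid_lowering,
                                 policy$tc_divisor)
  participants$ldl_adj <- adj_div(participants$ldl,
                                  participants$on_lipid_lowering,
                                  policy$ldl_divisor)
  participants
}

#' Flag values inside the mean +/- k SD band
#'
#' Computes the mean and SD once over all non-missing values (single pass;
#' the band is not recomputed after exclusions) and returns a logical
#' inclusion mask. Missing values are excluded from the mean/SD and marked
#' not included.
#'
#' @param values Numeric vector with at least 2 non-missing entries.
#' @param k Positive SD multiple; values with `|x - mean| > k * SD` are
#'   excluded.
#' @return Logical vector, `TRUE` where the value is retained.
#' @export
flag_outliers <- function(values, k = 5) {
  stopifnot(k > 0)
  ok <- !is.na(values)
  if (sum(ok) < 2)
    stop("flag_outliers: need at least 2 non-missing values")
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  inc <- ok & abs(values - m) <= k * s
  inc[is.na(inc)] <- FALSE
  inc
}

#' Classify hypertension, diabetes and metabolic syndrome
#'
#' Applies the [disease_criteria()] definitions to measured (not
#' back-adjusted) values. A flag is missing whenever any component the
#' definition needs is missing, even if the observed components would
#' already decide it: the per-disease analysis sets are meant to contain
#' only fully assessable individuals.
#'
#' @param participants Data frame with `sex`, `waist`, `sbp`, `dbp`,
#'   `hba1c`, `tg`, `hdl` and the three medication flags.
#' @param criteria A [disease_criteria()].
#' @return `participants` with logical (`NA`-able) `hypertension`,
#'   `diabetes` and `metabolic_syndrome` columns added.
#' @export
classify_diseases <- function(participants, criteria = disease_criteria()) {
  p <- participants
  all_present <- function(...) Reduce(`&`, lapply(list(...), Negate(is.na)))

  htn_ok <- all_present(p$sbp, p$dbp, p$on_antihypertensive)
  htn <- p$sbp >= criteria$htn_sbp | p$dbp >= criteria$htn_dbp |
    p$on_antihypertensive
  htn[!htn_ok] <- NA
  p$hypertension <- htn

  dm_ok <- all_present(p$hba1c, p$on_glucose_lowering)
  dm <- p$hba1c >= criteria$dm_hba1c | p$on_glucose_lowering
  dm[!dm_ok] <- NA
  p$diabetes <- dm

  mets_ok <- all_present(p$waist, p$sbp, p$dbp, p$on_antihypertensive,
                         p$hba1c, p$on_glucose_lowering, p$tg, p$hdl,
                         p$on_lipid_lowering)
  waist_crit <- ifelse(p$sex == "male",
                       p$waist >= criteria$mets_waist_m,
                       p$waist >= criteria$mets_waist_f)
  bp_crit <- p$sbp >= criteria$mets_sbp | p$dbp >= criteria$mets_dbp |
    p$on_antihypertensive
  gly_crit <- p$hba1c >= criteria$mets_hba1c | p$on_glucose_lowering
  lip_crit <- p$tg >= criteria$mets_tg | p$hdl < criteria$mets_hdl |
    p$on_lipid_lowering
  mets <- waist_crit & (bp_crit + gly_crit + lip_crit >= 2)
  mets[!mets_ok] <- NA
  p$metabolic_syndrome <- mets
  p
}

#' Physical-activity cut-off from the men's distribution
#'
#' Returns the stated percentile of the men's MET hours/day by linear
#' interpolation between order statistics (0-based index `(p/100)*(n-1)`,
#' i.e. R's default type-7 quantile). The same cut-off is applied to both
#' sexes downstream: `sufficiently_active` is `met_hours >= threshold`.
#'
#' @param men_met_values Men's MET hours/day; needs >= 2 non-missing values.
#' @param percentile Percentile in \[0, 100\].
#' @return The threshold in MET hours/day.
#' @examples
#' activity_threshold(1:10, 80)  # 8.2
#' @export
activity_threshold <- function(men_met_values, percentile = 80) {
  stopifnot(percentile >= 0, percentile <= 100)
  x <- men_met_values[!is.na(men_met_values)]
  if (length(x) < 2)
    stop("activity_threshold: need at least 2 non-missing values")
  unname(stats::quantile(x, percentile / 100, type = 7))
}

#' Recode raw educational categories to low/medium/high
#'
#' Elementary or junior high school maps to low; high school and vocational
#' school to medium; college or technical college, university and graduate
#' school to high; "other" is treated as missing.
#'
#' @param raw Character vector of the seven raw questionnaire categories.
#' @return Character vector in `{"low", "medium", "high"}` with `NA` for
#'   "other" or missing input; an unknown label is an error.
#' @export
recode_education <- function(raw) {
  map <- c("elementary school or junior high school" = "low",
           "high school" = "medium",
           "vocational school" = "medium",
           "college or technical college" = "high",
           "university" = "high",
           "graduate school" = "high",
           "other" = NA_character_)
  known <- is.na(raw) | raw %in% names(map)
  if (!all(known))
    stop(sprintf("recode_education: unknown category: %s",
                 paste(unique(raw[!known]), collapse = ", ")))
  out <- unname(map[raw])
  out[is.na(raw)] <- NA_character_
  out
}

# variables subject to the mean +/- k SD exclusion, with the raw columns
# blanked alongside the analysis column so descriptives stay consistent
.outlier_vars <- list(
  height = "height", weight = "weight", waist = "waist", bmi = "bmi",
  sbp_adj = c("sbp_adj", "sbp"), dbp_adj = c("dbp_adj", "dbp"),
  hba1c = "hba1c", tc_adj = c("tc_adj", "tc"),
  log_tg = c("log_tg", "tg"), hdl = "hdl",
  ldl_adj = c("ldl_adj", "ldl"), met_hours = "met_hours"
)

#' Derive all analysis variables for a cohort
#'
#' Runs the full harmonization on a paired cohort: BMI; Friedewald LDL
#' where the record has no LDL value but complete lipids; medication
#' back-adjustment (`sbp_adj`, `dbp_adj`, `tc_adj`, `ldl_adj`); log10
#' triglycerides (missing for non-positive TG); per-variable, per-sex
#' outlier exclusion at mean +/- `outlier_sd` SD, applied after the
#' back-adjustment by setting excluded values to missing; disease flags
#' from the measured (unadjusted) values; current-smoker/drinker and
#' sufficient-activity flags (cut-off from the men's cleaned MET hours);
#' education recode; and the HbA1c analysis-eligibility flag (individuals
#' on glucose-lowering medication are excluded from HbA1c analyses because
#' treatment alters HbA1c).
#'
#' Deriving an already-derived cohort re-derives from the stored raw
#' participant table, so the operation is idempotent.
#'
#' @param cohort A [paired_cohort()] or a previously derived cohort.
#' @param criteria A [disease_criteria()].
#' @param policy A [treatment_policy()].
#' @return A list of class `derived_cohort` with elements `participants`
#'   (raw columns, post-exclusion, plus derived columns), `pairs`, `raw`
#'   (the untouched input participant table) and `activity_cutoff`.
#' @export
derive_all <- function(cohort, criteria = disease_criteria(),
                       policy = treatment_policy()) {
  raw <- if (inherits(cohort, "derived_cohort")) cohort$raw
  else cohort$participants
  pairs <- cohort$pairs
  p <- raw

  p$bmi <- compute_bmi(p$weight, p$height)
  fill <- which(is.na(p$ldl) & !is.na(p$tc) & !is.na(p$hdl) & !is.na(p$tg) &
                  p$tc >= 0 & p$hdl >= 0 & p$tg >= 0)
  p$ldl[fill] <- friedewald_ldl(p$tc[fill], p$hdl[fill], p$tg[fill])
  p <- apply_treatment_adjustment(p, policy)
  p$log_tg <- ifelse(!is.na(p$tg) & p$tg > 0, log10(p$tg), NA_real_)

  if (nrow(p)) {
    for (v in names(.outlier_vars)) {
      for (s in c("male", "female")) {
        idx <- which(p$sex == s)
        vals <- p[[v]][idx]
        if (sum(!is.na(vals)) < 2) next
        keep <- flag_outliers(vals, k = criteria$outlier_sd)
        drop <- idx[!keep & !is.na(vals)]
        for (col in .outlier_vars[[v]]) p[[col]][drop] <- NA
      }
    }
  }

  p <- classify_diseases(p, criteria)
  p$current_smoker <- ifelse(is.na(p$smoking), NA, p$smoking == "current")
  p$current_drinker <- ifelse(is.na(p$drinking), NA, p$drinking == "current")
  men_met <- p$met_hours[p$sex == "male"]
  cutoff <- if (sum(!is.na(men_met)) >= 2)
    activity_threshold(men_met, criteria$activity_percentile) else NA_real_
  p$sufficiently_active <- if (is.na(cutoff))
    rep(NA, nrow(p)) else p$met_hours >= cutoff
  p$education <- recode_education(p$education_raw)
  p$hba1c_analysis_eligible <- !p$on_glucose_lowering

  structure(list(participants = p, pairs = pairs, raw = raw,
                 activity_cutoff = cutoff),
            class = "derived_cohort")
}

#' @export
print.derived_cohort <- function(x, ...) {
  cat(sprintf("<derived_cohort> %d participants, %d pairs (%s)\n",
              nrow(x$participants), nrow(x$pairs),
              paste(unique(x$pairs$origin), collapse = "/")))
  invisible(x)
}
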