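#' Specification of one simulated continuous trait
#'
#' Describes how the cohort generator simulates a continuous risk factor for
#' the two members of a couple. Each member's value is
#' `mean_sex + age_slope_sex * (age - age_mean_sex) + residual`, where the
#' residual is split into a couple-shared latent factor and individual noise
#' so that the marginal standard deviation equals `sd_sex` and the residual
#' (age-independent) within-couple correlation equals `couple_corr`.
#'
#' @param mean_m,mean_f Sex-specific marginal means.
#' @param sd_m,sd_f Sex-specific marginal standard deviations (> 0).
#' @param age_slope_m,age_slope_f Linear age trends, units per year.
#' @param couple_corr Residual within-couple correlation in \[-1, 1\]. This is
#'   the "assortment/cohabitation" dial: it adds spousal similarity beyond
#'   what correlated ages induce.
#' @param scale `"natural"`, or `"log10"` for right-skewed traits
#'   (triglycerides, activity volume) that are simulated as Gaussian on the
#'   log10 scale and back-transformed; means/SDs are then on the log10 scale.
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(mean_m, sd_m, mean_f, sd_f,
                       age_slope_m = 0, age_slope_f = 0,
                       couple_corr = 0, scale = c("natural", "log10")) {
  scale <- match.arg(scale)
  structure(list(mean_m = mean_m, sd_m = sd_m, mean_f = mean_f, sd_f = sd_f,
                 age_slope_m = age_slope_m, age_slope_f = age_slope_f,
                 couple_corr = couple_corr, scale = scale),
            class = "trait_spec")
}

#' Specification of one simulated binary (current-status) trait
#'
#' The female partner's status is drawn from
#' `logit p = intercept_f + age_slope_f * (age - age_mean_f)`; the male
#' partner's log-odds then receive `couple_log_or * (y_f - p_f)` on top of
#' his own sex-specific linear predictor. Centring on the female's expected
#' status keeps the male marginal prevalence at its configured level while
#' making `couple_log_or` the conditional within-couple log odds ratio.
#'
#' @param intercept_m,intercept_f Log-odds of the trait at the sex mean age.
#' @param age_slope_m,age_slope_f Log-odds change per year of age.
#' @param couple_log_or Shared-couple effect on the log-odds scale; 0 means
#'   partners are independent given age.
#' @return A list of class `binary_spec`.
#' @export
binary_spec <- function(intercept_m, intercept_f,
                        age_slope_m = 0, age_slope_f = 0,
                        couple_log_or = 0) {
  structure(list(intercept_m = intercept_m, intercept_f = intercept_f,
                 age_slope_m = age_slope_m, age_slope_f = age_slope_f,
                 couple_log_or = couple_log_or),
            class = "binary_spec")
}

# raw questionnaire categories for educational attainment
.education_levels <- c("elementary school or junior high school",
                       "high school", "vocational school",
                       "college or technical college", "university",
                       "graduate school", "other")

#' Default couple-cohort generator configuration
#'
#' Returns the fully populated configuration used throughout the package: a
#' cohort of 5,391 couples whose age structure (men 63.2 (SD 10.5) years,
#' women 60.4 (SD 10.2) years, spousal age correlation 0.934) and
#' sex-specific trait means/SDs match a large Japanese community cohort of
#' spouse pairs, with couple-shared effects defaulting to that cohort's
#' age-adjusted spousal correlations and concordance odds ratios. The
#' function is pure: it takes no arguments and always returns the same
#' configuration.
#'
#' Triglycerides and physical-activity volume (MET hours/day) are simulated
#' log10-normally; their `trait_spec` means/SDs are on the log10 scale,
#' derived from the reported medians and interquartile ranges.
#'
#' @return A list of class `spousim_config` with components:
#'   \describe{
#'     \item{n_pairs}{number of couples}
#'     \item{age_mean_m, age_sd_m, age_mean_f, age_sd_f, age_corr}{bivariate
#'       integer age model, truncated below 20 by resampling}
#'     \item{traits}{named list of [trait_spec()] for weight (kg), height
#'       (cm), waist (cm), sbp/dbp (mmHg), hba1c (%), tc/hdl (mg/dL), tg
#'       (log10 mg/dL) and met_hours (log10 MET h/day)}
#'     \item{binary}{named list of [binary_spec()] for current_smoker and
#'       current_drinker}
#'     \item{smoking_past_given_noncurrent, drinking_past_given_noncurrent}{
#'       sex-named probabilities splitting non-current status into past vs
#'       never}
#'     \item{medication}{thresholded-Bernoulli treatment model per class:
#'       treatment is assigned with probability `p_treated` when the
#'       underlying (pre-treatment) trait exceeds its threshold}
#'     \item{treatment_policy}{the [treatment_policy()] whose constants the
#'       generator subtracts from treated individuals' stored measurements,
#'       making the analysis-side back-adjustment exactly invertible}
#'     \item{education_probs}{sex-named probability vectors over the seven
#'       raw education categories (including "other")}
#'     \item{missing_rates}{per-variable independent (MCAR) missingness}
#'     \item{seed}{default RNG seed used when [generate_cohort()] is called
#'       without one}
#'   }
#' @examples
#' cfg <- default_config()
#' cfg$age_mean_m   # 63.2
#' cfg$age_corr     # 0.934
#' @export
default_config <- function() {
  traits <- list(
    weight = trait_spec(66.5, 9.6, 54.1, 8.7,
                        age_slope_m = -0.15, age_slope_f = -0.10,
                        couple_corr = 0.110),
    height = trait_spec(166.7, 6.0, 154.3, 5.6,
                        age_slope_m = -0.20, age_slope_f = -0.20,
                        couple_corr = 0.175),
    waist = trait_spec(85.6, 8.2, 81.9, 9.2,
                       age_slope_m = 0.08, age_slope_f = 0.15,
                       couple_corr = 0.126),
    sbp = trait_spec(129.7, 16.3, 125.9, 17.7,
                     age_slope_m = 0.45, age_slope_f = 0.65,
                     couple_corr = 0.086),
    dbp = trait_spec(78.9, 10.6, 75.2, 10.6,
                     age_slope_m = 0.08, age_slope_f = 0.10,
                     couple_corr = 0.073),
    hba1c = trait_spec(5.5, 0.5, 5.5, 0.4,
                       age_slope_m = 0.011, age_slope_f = 0.011,
                       couple_corr = 0.080),
    tc = trait_spec(201.5, 33.5, 213.7, 35.9,
                    age_slope_m = 0.2, age_slope_f = 0.5,
                    couple_corr = 0.101),
    # log10 scale: medians 104 / 88 mg/dL, SDs from IQR / 1.349
    tg = trait_spec(2.017, 0.225, 1.944, 0.205,
                    age_slope_m = 0.000, age_slope_f = 0.004,
                    couple_corr = 0.129, scale = "log10"),
    hdl = trait_spec(57.0, 14.5, 66.5, 15.5,
                     age_slope_m = 0, age_slope_f = 0,
                     couple_corr = 0.100),
    # log10 scale: men's median ~5 MET h/day; women's shifted down so that
    # ~10% of women clear the men's 80th percentile
    met_hours = trait_spec(0.699, 0.35, 0.551, 0.35,
                           age_slope_m = 0, age_slope_f = 0,
                           couple_corr = 0.20, scale = "log10")
  )
  binary <- list(
    current_smoker = binary_spec(
      intercept_m = stats::qlogis(0.208), intercept_f = stats::qlogis(0.047),
      age_slope_m = -0.035, age_slope_f = -0.030,
      couple_log_or = log(4.60)),
    current_drinker = binary_spec(
      intercept_m = stats::qlogis(0.784), intercept_f = stats::qlogis(0.408),
      age_slope_m = -0.005, age_slope_f = -0.015,
      couple_log_or = log(2.83))
  )
  structure(list(
    n_pairs = 5391L,
    age_mean_m = 63.2, age_sd_m = 10.5,
    age_mean_f = 60.4, age_sd_f = 10.2,
    age_corr = 0.934,
    traits = traits,
    binary = binary,
    smoking_past_given_noncurrent = c(male = 0.728, female = 0.132),
    drinking_past_given_noncurrent = c(male = 0.170, female = 0.027),
    medication = list(
      antihypertensive = list(threshold_sbp = 140, threshold_dbp = 90,
                              p_treated = 0.7),
      # gate at the hyperglycaemia (not diagnostic) threshold: most treated
      # individuals have controlled HbA1c below 6.5, and a 6.5 gate would
      # leave diabetes prevalence far below its observed level
      glucose_lowering = list(threshold_hba1c = 6.0, p_treated = 0.6),
      lipid_lowering = list(threshold_tc = 240, p_treated = 0.5)
    ),
    treatment_policy = treatment_policy(),
    education_probs = list(
      male = stats::setNames(
        c(0.119, 0.450, 0.135, 0.080, 0.170, 0.021, 0.025),
        .education_levels),
      female = stats::setNames(
        c(0.082, 0.550, 0.170, 0.100, 0.060, 0.012, 0.026),
        .education_levels)
    ),
    missing_rates = c(
      height = 0, weight = 0.001, waist = 0.23,
      sbp = 0.027, dbp = 0.027, hba1c = 0.076,
      tc = 0.396, tg = 0.001, hdl = 0.001, ldl = 0.231,
      smoking = 0.007, drinking = 0.003, met_hours = 0.005,
      on_antihypertensive = 0.08, on_glucose_lowering = 0.08,
      on_lipid_lowering = 0.08
    ),
    seed = 1L
  ), class = "spousim_config")
}

#' Validate a generator configuration
#'
#' Checks the structural invariants of a [default_config()]-shaped list:
#' non-negative pair count, positive standard deviations, correlations in
#' \[-1, 1\], probabilities and missing rates in \[0, 1\], and — for every
#' continuous trait — that the age slope does not claim more marginal
#' variance than the trait has, so the residual variance stays positive.
#'
#' @param config A `spousim_config` list.
#' @return `config`, invisibly, if valid; otherwise a configuration error
#'   naming the offending field.
#' @export
validate_config <- function(config) {
  chk <- function(ok, field, what) {
    if (!ok) config_error(sprintf("invalid configuration: `%s` %s", field, what))
  }
  chk(is_number(config$n_pairs) && config$n_pairs >= 0 &&
        config$n_pairs == trunc(config$n_pairs), "n_pairs",
      "must be a non-negative integer")
  for (f in c("age_sd_m", "age_sd_f"))
    chk(is_number(config[[f]]) && config[[f]] > 0, f, "must be > 0")
  for (f in c("age_mean_m", "age_mean_f"))
    chk(is_number(config[[f]]), f, "must be a finite number")
  chk(is_number(config$age_corr) && abs(config$age_corr) <= 1,
      "age_corr", "must lie in [-1, 1]")
  for (nm in names(config$traits)) {
    tr <- config$traits[[nm]]
    for (f in c("sd_m", "sd_f"))
      chk(is_number(tr[[f]]) && tr[[f]] > 0,
          paste0("traits$", nm, "$", f), "must be > 0")
    chk(is_number(tr$couple_corr) && abs(tr$couple_corr) <= 1,
        paste0("traits$", nm, "$couple_corr"), "must lie in [-1, 1]")
    age_sd <- c(m = config$age_sd_m, f = config$age_sd_f)
    for (s in c("m", "f")) {
      slope_var <- tr[[paste0("age_slope_", s)]]^2 * age_sd[[s]]^2
      chk(slope_var < tr[[paste0("sd_", s)]]^2,
          paste0("traits$", nm, "$age_slope_", s),
          "implies age-driven variance exceeding the marginal variance")
    }
  }
  for (nm in names(config$binary)) {
    b <- config$binary[[nm]]
    for (f in c("intercept_m", "intercept_f", "age_slope_m", "age_slope_f",
                "couple_log_or"))
      chk(is_number(b[[f]]), paste0("binary$", nm, "$", f),
          "must be a finite number")
  }
  for (nm in c("smoking_past_given_noncurrent",
               "drinking_past_given_noncurrent")) {
    p <- config[[nm]]
    chk(is.numeric(p) && all(p >= 0 & p <= 1), nm, "must lie in [0, 1]")
  }
  for (nm in names(config$medication)) {
    p <- config$medication[[nm]]$p_treated
    chk(is_number(p) && p >= 0 && p <= 1,
        paste0("medication$", nm, "$p_treated"), "must lie in [0, 1]")
  }
  for (s in c("male", "female")) {
    p <- config$education_probs[[s]]
    chk(is.numeric(p) && all(p >= 0) && abs(sum(p) - 1) < 1e-8,
        paste0("education_probs$", s), "must be probabilities summing to 1")
  }
  mr <- config$missing_rates
  chk(is.numeric(mr) && all(mr >= 0 & mr <= 1), "missing_rates",
      "must lie in [0, 1]")
  invisible(config)
}

#' Read or write a generator configuration as YAML
#'
#' The on-disk form is plain YAML mirroring the list structure of
#' [default_config()]; reading validates the result before returning it.
#'
#' @param config A `spousim_config` list.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   validated configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(raw)) cfg[[nm]] <- merge_config_field(cfg[[nm]], raw[[nm]])
  # yaml drops names on scalars-in-sequences; restore named vectors
  for (nm in c("smoking_past_given_noncurrent", "drinking_past_given_noncurrent"))
    cfg[[nm]] <- unlist(cfg[[nm]])
  cfg$missing_rates <- unlist(cfg$missing_rates)
  cfg$education_probs <- lapply(cfg$education_probs, unlist)
  validate_config(cfg)
  cfg
}

merge_config_field <- function(base, value) {
  if (is.list(value) && is.list(base)) {
    for (nm in names(value)) base[[nm]] <- merge_config_field(base[[nm]], value[[nm]])
    base
  } else {
    value
  }
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (!is.null(names(x))) as.list(x)  # keep names through YAML/JSON
  else x
}
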