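#' Construct a paired couple cohort
#'
#' Bundles a participant table with a husband-wife pair table and checks the
#' structural invariants: every id referenced by a pair exists, `male_id`
#' rows are male and `female_id` rows are female, and no participant appears
#' in more than one pair.
#'
#' @param participants Data frame, one row per person. Required columns:
#'   `id` (character, unique), `sex` (`"male"`/`"female"`), `age` (integer
#'   years, >= 20 when present). Measurement, lifestyle and medication
#'   columns are free-form; [generate_cohort()] documents the full schema.
#' @param pairs Data frame with columns `male_id`, `female_id` and `origin`
#'   (`"spouse"` or `"randomized"`).
#' @return A list of class `paired_cohort` with elements `participants` and
#'   `pairs`.
#' @export
paired_cohort <- function(participants, pairs) {
  stopifnot(is.data.frame(participants), is.data.frame(pairs))
  if (anyDuplicated(participants$id))
    stop("participant ids must be unique")
  need <- c("male_id", "female_id", "origin")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns male_id, female_id, origin")
  idx_m <- match(pairs$male_id, participants$id)
  idx_f <- match(pairs$female_id, participants$id)
  if (anyNA(idx_m) || anyNA(idx_f))
    stop("pairs reference ids absent from participants")
  if (nrow(pairs)) {
    if (any(participants$sex[idx_m] != "male"))
      stop("male_id must refer to male participants")
    if (any(participants$sex[idx_f] != "female"))
      stop("female_id must refer to female participants")
  }
  if (anyDuplicated(pairs$male_id) || anyDuplicated(pairs$female_id))
    stop("a participant may appear in at most one pair")
  structure(list(participants = participants, pairs = pairs),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %d participants, %d pairs (%s)\n",
              nrow(x$participants), nrow(x$pairs),
              paste(unique(x$pairs$origin), collapse = "/")))
  invisible(x)
}

participant_columns <- function() {
  c("id", "sex", "age", "height", "weight", "waist", "sbp", "dbp", "hba1c",
    "tc", "tg", "hdl", "ldl", "smoking", "drinking", "met_hours",
    "education_raw", "on_antihypertensive", "on_glucose_lowering",
    "on_lipid_lowering")
}

empty_participants <- function() {
  data.frame(id = character(), sex = character(), age = integer(),
             height = numeric(), weight = numeric(), waist = numeric(),
             sbp = numeric(), dbp = numeric(), hba1c = numeric(),
             tc = numeric(), tg = numeric(), hdl = numeric(),
             ldl = numeric(), smoking = character(), drinking = character(),
             met_hours = numeric(), education_raw = character(),
             on_antihypertensive = logical(),
             on_glucose_lowering = logical(),
             on_lipid_lowering = logical(),
             stringsAsFactors = FALSE)
}

empty_pairs <- function() {
  data.frame(male_id = character(), female_id = character(),
             origin = character(), stringsAsFactors = FALSE)
}

#' Generate a synthetic couple cohort
#'
#' Simulates `config$n_pairs` married couples. Ages come from a bivariate
#' normal with the configured means, SDs and spousal correlation, rounded to
#' whole years; couples where either member would be under 20 are redrawn
#' rather than clipped, so the eligibility bound leaves no point mass at 20.
#' Each continuous trait is the sex mean plus a linear age trend plus a
#' residual split between a couple-shared latent factor (variance fraction
#' `|couple_corr|`) and individual noise, so the marginal SD matches the
#' configuration and the residual spousal correlation equals `couple_corr`.
#' Binary lifestyle traits follow sex-specific logistic age models with a
#' shared-couple log-odds effect. Medication classes are thresholded
#' Bernoulli draws on the pre-treatment value; stored measurements of
#' treated individuals are attenuated by exactly the constants in
#' `config$treatment_policy` (SBP -15, DBP -10 mmHg; TC x0.8, LDL x0.7), so
#' the harmonization back-adjustment recovers the pre-treatment values.
#' LDL cholesterol is the Friedewald combination of the pre-treatment
#' lipids. Missingness is applied independently per variable (MCAR) at
#' `config$missing_rates`.
#'
#' @param config A [default_config()]-shaped configuration; validated first.
#' @param seed Integer seed; defaults to `config$seed`. The same
#'   `(config, seed)` always yields an identical cohort, and the caller's
#'   RNG stream is left untouched.
#' @return A [paired_cohort()] with `origin = "spouse"` pairs.
#' @examples
#' coh <- generate_cohort(default_config(), seed = 1)
#' nrow(coh$pairs)
#' @export
generate_cohort <- function(config, seed = NULL) {
  validate_config(config)
  with_seed(seed %||% config$seed, {
    n <- as.integer(config$n_pairs)
    if (n == 0L)
      return(paired_cohort(empty_participants(), empty_pairs()))

    ages <- draw_couple_ages(n, config)
    age_m <- ages$male
    age_f <- ages$female
    cam <- age_m - config$age_mean_m   # centred ages
    caf <- age_f - config$age_mean_f

    true <- list()  # pre-treatment trait values, natural scale
    for (nm in names(config$traits)) {
      tr <- config$traits[[nm]]
      v <- draw_couple_trait(tr, cam, caf,
                             config$age_sd_m, config$age_sd_f)
      if (tr$scale == "log10") v <- lapply(v, function(x) 10^x)
      true[[nm]] <- v
    }

    med <- draw_medication(true, config$medication, n)

    pol <- config$treatment_policy
    meas <- true
    meas$sbp <- Map(function(x, rx) x - pol$sbp_add * rx, true$sbp, med$antihypertensive)
    meas$dbp <- Map(function(x, rx) x - pol$dbp_add * rx, true$dbp, med$antihypertensive)
    meas$tc <- Map(function(x, rx) x * ifelse(rx, pol$tc_divisor, 1), true$tc, med$lipid_lowering)
    # Friedewald combination of the pre-treatment lipids; guard against the
    # (vanishingly rare) negative Gaussian tail draw the strict domain check
    # in friedewald_ldl() would reject
    ldl_true <- Map(function(tc, hdl, tg) {
      ifelse(tc >= 0 & hdl >= 0 & tg >= 0 & tg < 400,
             tc - hdl - tg / 5, NA_real_)
    }, true$tc, true$hdl, true$tg)
    meas$ldl <- Map(function(x, rx) x * ifelse(rx, pol$ldl_divisor, 1),
                    ldl_true, med$lipid_lowering)

    smoke <- draw_couple_binary(config$binary$current_smoker, cam, caf)
    smoking <- three_level_status(smoke, config$smoking_past_given_noncurrent)
    drink <- draw_couple_binary(config$binary$current_drinker, cam, caf)
    drinking <- three_level_status(drink, config$drinking_past_given_noncurrent)

    edu <- list(
      male = sample(.education_levels, n, replace = TRUE,
                    prob = config$education_probs$male),
      female = sample(.education_levels, n, replace = TRUE,
                      prob = config$education_probs$female)
    )

    build_side <- function(s, prefix, sexname) {
      data.frame(
        id = sprintf("%s%05d", prefix, seq_len(n)),
        sex = sexname,
        age = if (s == "male") age_m else age_f,
        height = meas$height[[s]], weight = meas$weight[[s]],
        waist = meas$waist[[s]], sbp = meas$sbp[[s]], dbp = meas$dbp[[s]],
        hba1c = meas$hba1c[[s]], tc = meas$tc[[s]], tg = meas$tg[[s]],
        hdl = meas$hdl[[s]], ldl = meas$ldl[[s]],
        smoking = smoking[[s]], drinking = drinking[[s]],
        met_hours = meas$met_hours[[s]],
        education_raw = edu[[s]],
        on_antihypertensive = med$antihypertensive[[s]],
        on_glucose_lowering = med$glucose_lowering[[s]],
        on_lipid_lowering = med$lipid_lowering[[s]],
        stringsAsFactors = FALSE
      )
    }
    participants <- rbind(build_side("male", "M", "male"),
                          build_side("female", "F", "female"))
    participants <- apply_missingness(participants, config$missing_rates)

    pairs <- data.frame(male_id = sprintf("M%05d", seq_len(n)),
                        female_id = sprintf("F%05d", seq_len(n)),
                        origin = "spouse", stringsAsFactors = FALSE)
    paired_cohort(participants, pairs)
  })
}

# bivariate-normal integer ages, truncated below 20 by resampling
draw_couple_ages <- function(n, config) {
  rho <- config$age_corr
  draw <- function(k) {
    z1 <- stats::rnorm(k)
    z2 <- stats::rnorm(k)
    m <- round(config$age_mean_m + config$age_sd_m * z1)
    f <- round(config$age_mean_f +
                 config$age_sd_f * (rho * z1 + sqrt(1 - rho^2) * z2))
    list(male = as.integer(m), female = as.integer(f))
  }
  a <- draw(n)
  bad <- which(a$male < 20L | a$female < 20L)
  while (length(bad)) {
    r <- draw(length(bad))
    a$male[bad] <- r$male
    a$female[bad] <- r$female
    bad <- bad[r$male < 20L | r$female < 20L]
  }
  a
}

# shared-factor residual structure; returns list(male=, female=) on the
# trait's working scale (log10 values for log-scale traits)
draw_couple_trait <- function(tr, cam, caf, age_sd_m, age_sd_f) {
  n <- length(cam)
  sd_res_m <- sqrt(tr$sd_m^2 - tr$age_slope_m^2 * age_sd_m^2)
  sd_res_f <- sqrt(tr$sd_f^2 - tr$age_slope_f^2 * age_sd_f^2)
  cc <- tr$couple_corr
  shared <- stats::rnorm(n)
  res_m <- sd_res_m * (sqrt(abs(cc)) * shared +
                         sqrt(1 - abs(cc)) * stats::rnorm(n))
  res_f <- sd_res_f * (sign(cc) * sqrt(abs(cc)) * shared +
                         sqrt(1 - abs(cc)) * stats::rnorm(n))
  list(male = tr$mean_m + tr$age_slope_m * cam + res_m,
       female = tr$mean_f + tr$age_slope_f * caf + res_f)
}

draw_couple_binary <- function(b, cam, caf) {
  n <- length(cam)
  p_f <- stats::plogis(b$intercept_f + b$age_slope_f * caf)
  y_f <- stats::rbinom(n, 1L, p_f)
  lp_m <- b$intercept_m + b$age_slope_m * cam + b$couple_log_or * (y_f - p_f)
  y_m <- stats::rbinom(n, 1L, stats::plogis(lp_m))
  list(male = y_m == 1L, female = y_f == 1L)
}

three_level_status <- function(current, past_given_noncurrent) {
  split_one <- function(cur, p_past) {
    out <- ifelse(cur, "current",
                  ifelse(stats::runif(length(cur)) < p_past, "past", "never"))
    out
  }
  list(male = split_one(current$male, past_given_noncurrent[["male"]]),
       female = split_one(current$female, past_given_noncurrent[["female"]]))
}

draw_medication <- function(true, medication, n) {
  draw_class <- function(eligible, p) {
    list(male = eligible$male & stats::runif(n) < p,
         female = eligible$female & stats::runif(n) < p)
  }
  bp <- medication$antihypertensive
  glu <- medication$glucose_lowering
  lip <- medication$lipid_lowering
  list(
    antihypertensive = draw_class(
      list(male = true$sbp$male >= bp$threshold_sbp |
             true$dbp$male >= bp$threshold_dbp,
           female = true$sbp$female >= bp$threshold_sbp |
             true$dbp$female >= bp$threshold_dbp),
      bp$p_treated),
    glucose_lowering = draw_class(
      list(male = true$hba1c$male >= glu$threshold_hba1c,
           female = true$hba1c$female >= glu$threshold_hba1c),
      glu$p_treated),
    lipid_lowering = draw_class(
      list(male = true$tc$male >= lip$threshold_tc,
           female = true$tc$female >= lip$threshold_tc),
      lip$p_treated)
  )
}

apply_missingness <- function(participants, rates) {
  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (r <= 0 || !nm %in% names(participants)) next
    hole <- stats::runif(nrow(participants)) < r
    participants[[nm]][hole] <- NA
  }
  participants
}

#' Write or read a paired cohort as two CSV files
#'
#' The on-disk schema is `participants.csv` (columns as documented in
#' [generate_cohort()]) and `pairs.csv` (`male_id`, `female_id`, `origin`).
#' Missing values are written as empty fields; logical medication flags as
#' `TRUE`/`FALSE`.
#'
#' @param cohort A [paired_cohort()].
#' @param dir Directory to write into (created if needed).
#' @param participants_csv,pairs_csv File paths for reading.
#' @return `write_cohort()` returns the two paths invisibly; `read_cohort()`
#'   a validated [paired_cohort()].
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pp <- file.path(dir, "participants.csv")
  pq <- file.path(dir, "pairs.csv")
  utils::write.csv(cohort$participants, pp, row.names = FALSE, na = "")
  utils::write.csv(cohort$pairs, pq, row.names = FALSE, na = "")
  invisible(c(participants = pp, pairs = pq))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(participants_csv, pairs_csv) {
  for (p in c(participants_csv, pairs_csv))
    if (!file.exists(p)) stop(sprintf("input path does not exist: %s", p))
  classes <- c(id = "character", sex = "character", age = "integer",
               height = "numeric", weight = "numeric", waist = "numeric",
               sbp = "numeric", dbp = "numeric", hba1c = "numeric",
               tc = "numeric", tg = "numeric", hdl = "numeric",
               ldl = "numeric", smoking = "character",
               drinking = "character", met_hours = "numeric",
               education_raw = "character",
               on_antihypertensive = "logical",
               on_glucose_lowering = "logical",
               on_lipid_lowering = "logical")
  participants <- utils::read.csv(participants_csv, na.strings = "",
                                  colClasses = classes,
                                  stringsAsFactors = FALSE)
  pairs <- utils::read.csv(pairs_csv, na.strings = "",
                           colClasses = c(male_id = "character",
                                          female_id = "character",
                                          origin = "character"),
                           stringsAsFactors = FALSE)
  paired_cohort(participants, pairs)
}
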