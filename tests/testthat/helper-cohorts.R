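# Shared fixture builders. Everything is generated in code; no stored data.

# A complete, healthy participant row with overridable fields.
toy_participant <- function(id, sex, age, ...) {
  base <- list(id = id, sex = sex, age = as.integer(age),
               height = if (sex == "male") 170 else 155,
               weight = if (sex == "male") 70 else 55,
               waist = if (sex == "male") 84 else 80,
               sbp = 120, dbp = 75, hba1c = 5.5,
               tc = 200, tg = 100, hdl = 55, ldl = 125,
               smoking = "never", drinking = "never", met_hours = 5,
               education_raw = "high school",
               on_antihypertensive = FALSE, on_glucose_lowering = FALSE,
               on_lipid_lowering = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  as.data.frame(base, stringsAsFactors = FALSE)
}

# n couples with given integer ages; `jitter_sd` adds seeded measurement
# noise so tests needing variance have it.
toy_cohort <- function(ages_m, ages_f = ages_m, jitter_sd = 0, seed = 99) {
  stopifnot(length(ages_m) == length(ages_f))
  n <- length(ages_m)
  rows <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    rows[[i]] <- toy_participant(sprintf("M%03d", i), "male", ages_m[i])
    rows[[n + i]] <- toy_participant(sprintf("F%03d", i), "female", ages_f[i])
  }
  participants <- do.call(rbind, rows)
  if (jitter_sd > 0) {
    participants <- spousim_jitter(participants, jitter_sd, seed)
  }
  pairs <- data.frame(male_id = sprintf("M%03d", seq_len(n)),
                      female_id = sprintf("F%03d", seq_len(n)),
                      origin = rep("spouse", n), stringsAsFactors = FALSE)
  if (n == 0L)
    participants <- toy_participant("x", "male", 30)[0, , drop = FALSE]
  paired_cohort(participants, pairs)
}

spousim_jitter <- function(participants, sd, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (col in c("height", "weight", "waist", "sbp", "dbp", "hba1c",
                "tc", "tg", "hdl", "ldl", "met_hours")) {
    scale <- if (col == "hba1c") sd / 20 else sd
    participants[[col]] <- participants[[col]] +
      rnorm(nrow(participants), 0, scale)
  }
  participants
}

# Default configuration with couple effects and/or age trends removed and
# missingness switched off, for null-calibration experiments.
null_config <- function(n_pairs, zero_couple = TRUE, zero_slopes = TRUE,
                        no_missing = TRUE) {
  cfg <- default_config()
  cfg$n_pairs <- as.integer(n_pairs)
  if (zero_couple) {
    for (nm in names(cfg$traits)) cfg$traits[[nm]]$couple_corr <- 0
    for (nm in names(cfg$binary)) cfg$binary[[nm]]$couple_log_or <- 0
  }
  if (zero_slopes) {
    for (nm in names(cfg$traits)) {
      cfg$traits[[nm]]$age_slope_m <- 0
      cfg$traits[[nm]]$age_slope_f <- 0
    }
    for (nm in names(cfg$binary)) {
      cfg$binary[[nm]]$age_slope_m <- 0
      cfg$binary[[nm]]$age_slope_f <- 0
    }
  }
  if (no_missing) cfg$missing_rates[] <- 0
  cfg
}

# Raw spousal correlation of a generated (pre-harmonization) trait,
# computed directly from the participant table.
raw_pair_cor <- function(cohort, column) {
  part <- cohort$participants
  im <- match(cohort$pairs$male_id, part$id)
  iff <- match(cohort$pairs$female_id, part$id)
  stats::cor(part[[column]][im], part[[column]][iff],
             use = "complete.obs")
}
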