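test_that("body mass index follows weight over squared height in metres", {
  expect_equal(compute_bmi(80, 200), 20.0)
  expect_equal(compute_bmi(66.5, 166.7), 23.93, tolerance = 0.01 / 23.93)
  expect_equal(compute_bmi(54.1, 154.4), 22.70, tolerance = 0.01 / 22.70)
  expect_true(is.na(compute_bmi(NA, 170)))
  expect_error(compute_bmi(-1, 170), "positive")
  expect_error(compute_bmi(70, 0), "positive")
})

test_that("Friedewald LDL applies tc - hdl - tg/5 below the validity bound", {
  expect_equal(friedewald_ldl(200, 50, 100), 130)
  expect_true(is.na(friedewald_ldl(200, 50, 400)))
  expect_equal(friedewald_ldl(180, 60, 0), 120)
  expect_error(friedewald_ldl(-1, 50, 100), "non-negative")
  expect_equal(friedewald_ldl(c(200, 200), c(50, 50), c(100, 500)),
               c(130, NA))
})

test_that("treatment back-adjustment shifts treated values only", {
  p <- rbind(
    toy_participant("M1", "male", 60, sbp = 130, dbp = 80, tc = 160,
                    ldl = 100, on_antihypertensive = TRUE,
                    on_lipid_lowering = TRUE),
    toy_participant("M2", "male", 60, sbp = 130, dbp = 80, tc = 160,
                    ldl = 100),
    toy_participant("M3", "male", 60, sbp = 130,
                    on_antihypertensive = NA)
  )
  out <- apply_treatment_adjustment(p, treatment_policy())
  expect_equal(out$sbp_adj, c(145, 130, NA))
  expect_equal(out$dbp_adj[1:2], c(90, 80))
  expect_equal(out$tc_adj[1:2], c(200, 160))
  expect_equal(out$ldl_adj[1:2], c(100 / 0.7, 100))
})

test_that("back-adjustment inverts the generator's treatment attenuation", {
  # the generator stores measured values with the treatment effect removed;
  # adjusted values of treated individuals must land back above the
  # treatment-initiation gates, which only pre-treatment values can satisfy
  cfg <- null_config(1500, zero_slopes = FALSE)
  d <- derive_all(generate_cohort(cfg, seed = 61))
  p <- d$participants
  trt <- which(p$on_antihypertensive)
  expect_true(all(p$sbp_adj[trt] - p$sbp[trt] == 15, na.rm = TRUE))
  expect_true(all(p$dbp_adj[trt] - p$dbp[trt] == 10, na.rm = TRUE))
  lip <- which(p$on_lipid_lowering)
  expect_equal(p$tc_adj[lip], p$tc[lip] / 0.8)
  expect_true(all(p$sbp_adj[trt] >= 140 | p$dbp_adj[trt] >= 90,
                  na.rm = TRUE))
})

test_that("the 5-SD rule keeps bounded samples and drops a gross outlier", {
  expect_true(all(flag_outliers(rep(1, 5), k = 5)))
  # any modest bounded sample survives: range well inside +/- 5 SD
  x <- c(1:20, 40) / 3
  expect_true(all(flag_outliers(x, k = 5)))

  set.seed(424)
  vals <- c(rnorm(1000), 8.0)
  keep <- flag_outliers(vals, k = 5)
  # oracle: recompute the single-pass band directly
  m <- mean(vals); s <- sd(vals)
  expect_true(abs(8 - m) > 5 * s)
  expect_identical(which(!keep), 1001L)

  expect_error(flag_outliers(7), "at least 2")
  expect_error(flag_outliers(c(NA, NA, 3)), "at least 2")
  xna <- c(rnorm(10), NA)
  expect_false(flag_outliers(xna)[11])
})

test_that("disease definitions follow the thresholds with strict inequalities", {
  crit <- disease_criteria()
  # mandatory waist criterion fails despite florid other components
  p1 <- toy_participant("M1", "male", 60, waist = 84, sbp = 160,
                        hba1c = 7.0, tg = 300)
  expect_false(classify_diseases(p1, crit)$metabolic_syndrome)
  # waist + blood pressure + glycaemia criteria met
  p2 <- toy_participant("M2", "male", 60, waist = 90, sbp = 135, dbp = 80,
                        hba1c = 6.1, tg = 100, hdl = 60)
  expect_true(classify_diseases(p2, crit)$metabolic_syndrome)
  # thresholds are >= : 139/89 untreated is not hypertension
  p3 <- toy_participant("M3", "male", 60, sbp = 139, dbp = 89)
  expect_false(classify_diseases(p3, crit)$hypertension)
  p4 <- toy_participant("M4", "male", 60, sbp = 140)
  expect_true(classify_diseases(p4, crit)$hypertension)
  # medication alone qualifies
  p5 <- toy_participant("M5", "male", 60, sbp = 110, dbp = 70,
                        on_antihypertensive = TRUE, hba1c = 5.0,
                        on_glucose_lowering = TRUE)
  out5 <- classify_diseases(p5, crit)
  expect_true(out5$hypertension)
  expect_true(out5$diabetes)
  # female waist threshold is 90
  p6 <- toy_participant("F1", "female", 60, waist = 88, sbp = 150,
                        dbp = 90, hba1c = 6.2)
  expect_false(classify_diseases(p6, crit)$metabolic_syndrome)
})

test_that("a missing component makes the disease flag missing", {
  crit <- disease_criteria()
  p <- toy_participant("M1", "male", 60, sbp = 180, dbp = NA)
  expect_true(is.na(classify_diseases(p, crit)$hypertension))
  p <- toy_participant("M2", "male", 60, hba1c = 7.5,
                       on_glucose_lowering = NA)
  expect_true(is.na(classify_diseases(p, crit)$diabetes))
  p <- toy_participant("M3", "male", 60, waist = NA)
  expect_true(is.na(classify_diseases(p, crit)$metabolic_syndrome))
})

test_that("raising systolic pressure never un-diagnoses hypertension", {
  crit <- disease_criteria()
  set.seed(77)
  for (i in 1:25) {
    base <- toy_participant("X", "male", 60,
                            sbp = runif(1, 100, 180),
                            dbp = runif(1, 60, 100),
                            on_antihypertensive = runif(1) < 0.3)
    flags <- sapply(c(0, 5, 10, 20, 40), function(delta) {
      b <- base; b$sbp <- b$sbp + delta
      classify_diseases(b, crit)$hypertension
    })
    expect_true(all(diff(as.integer(flags)) >= 0))
  }
})

test_that("the activity cut-off interpolates between order statistics", {
  expect_equal(activity_threshold(1:10, 80), 8.2)
  expect_equal(activity_threshold(c(5, 5, 5, 5), 37), 5)
  expect_equal(activity_threshold(c(3, 1, 2), 0), 1)
  expect_error(activity_threshold(numeric(0), 80), "at least 2")
  expect_error(activity_threshold(c(4, NA), 80), "at least 2")
})

test_that("education recodes to low/medium/high with 'other' missing", {
  expect_equal(recode_education("high school"), "medium")
  expect_equal(recode_education("vocational school"), "medium")
  expect_equal(recode_education("graduate school"), "high")
  expect_equal(recode_education("college or technical college"), "high")
  expect_equal(
    recode_education("elementary school or junior high school"), "low")
  expect_true(is.na(recode_education("other")))
  expect_true(is.na(recode_education(NA_character_)))
  expect_error(recode_education("night school"), "unknown category")
})

test_that("derive_all populates every analysis field and is idempotent", {
  coh <- toy_cohort(c(60, 62, 58, 65, 61), jitter_sd = 5)
  d1 <- derive_all(coh)
  p <- d1$participants
  for (col in c("bmi", "sbp_adj", "dbp_adj", "tc_adj", "ldl_adj", "log_tg",
                "hypertension", "diabetes", "metabolic_syndrome",
                "current_smoker", "current_drinker", "sufficiently_active",
                "education", "hba1c_analysis_eligible"))
    expect_true(col %in% names(p), info = col)
  expect_equal(p$bmi, p$weight / (p$height / 100)^2)
  expect_equal(p$log_tg, log10(p$tg))
  d2 <- derive_all(d1)
  expect_identical(d1$participants, d2$participants)
  expect_identical(d1$activity_cutoff, d2$activity_cutoff)
})

test_that("derivation handles degenerate values per the analysis rules", {
  coh <- toy_cohort(c(60, 62, 58))
  coh$participants$tg[1] <- 0
  coh$participants$on_glucose_lowering[2] <- TRUE
  coh$participants$ldl[3] <- NA  # refilled via Friedewald
  d <- derive_all(coh)
  p <- d$participants
  expect_true(is.na(p$log_tg[1]))
  expect_false(p$hba1c_analysis_eligible[2])
  expect_equal(p$ldl[3], p$tc[3] - p$hdl[3] - p$tg[3] / 5)
})
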