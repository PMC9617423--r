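test_that("default configuration is pure and carries the calibrated values", {
  cfg <- default_config()
  expect_identical(cfg, default_config())
  expect_equal(cfg$age_mean_m, 63.2)
  expect_equal(cfg$age_sd_m, 10.5)
  expect_equal(cfg$age_mean_f, 60.4)
  expect_equal(cfg$age_sd_f, 10.2)
  expect_equal(cfg$age_corr, 0.934)
  expect_equal(cfg$traits$weight$mean_m, 66.5)
  expect_equal(cfg$traits$weight$sd_f, 8.7)
  expect_equal(cfg$traits$hdl$mean_f, 66.5)
  expect_identical(validate_config(cfg), cfg)
})

test_that("configuration validation names the offending field", {
  cfg <- default_config()
  cfg$age_sd_m <- -1
  expect_error(validate_config(cfg), "age_sd_m")
  cfg <- default_config()
  cfg$age_corr <- 1.2
  expect_error(validate_config(cfg), "age_corr")
  cfg <- default_config()
  cfg$traits$sbp$couple_corr <- -2
  expect_error(validate_config(cfg), "sbp")
  cfg <- default_config()
  cfg$missing_rates[["waist"]] <- 1.5
  expect_error(validate_config(cfg), "missing_rates")
  cfg <- default_config()
  cfg$n_pairs <- -3
  expect_error(generate_cohort(cfg), "n_pairs")
  # an age slope cannot claim more variance than the trait's marginal SD
  cfg <- default_config()
  cfg$traits$hba1c$age_slope_m <- 1
  expect_error(validate_config(cfg), "age_slope_m")
})

test_that("generation is seeded, deterministic and respects n_pairs = 0", {
  cfg <- default_config()
  cfg$n_pairs <- 0L
  empty <- generate_cohort(cfg, seed = 5)
  expect_equal(nrow(empty$participants), 0L)
  expect_equal(nrow(empty$pairs), 0L)

  cfg$n_pairs <- 200L
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a, c))
})

test_that("generated cohorts satisfy the structural invariants", {
  cfg <- default_config()
  cfg$n_pairs <- 300L
  coh <- generate_cohort(cfg, seed = 11)
  p <- coh$participants
  expect_equal(nrow(p), 600L)
  expect_false(anyDuplicated(p$id) > 0)
  expect_true(all(p$age >= 20L))
  expect_true(is.integer(p$age))
  expect_setequal(coh$pairs$male_id, p$id[p$sex == "male"])
  expect_setequal(coh$pairs$female_id, p$id[p$sex == "female"])
  expect_true(all(coh$pairs$origin == "spouse"))
  expect_true(all(p$met_hours >= 0, na.rm = TRUE))
  expect_true(all(p$tg >= 0, na.rm = TRUE))
  expect_true(all(p$smoking %in% c("current", "past", "never") |
                    is.na(p$smoking)))
})

test_that("marginal means and SDs calibrate to the configuration", {
  cfg <- default_config()
  cfg$n_pairs <- 5000L
  cfg$missing_rates[] <- 0
  coh <- generate_cohort(cfg, seed = 21)
  # configured moments describe the pre-treatment values: stored
  # measurements of treated individuals are attenuated by design, and the
  # back-adjustment recovers the configured distribution
  p <- derive_all(coh, disease_criteria(outlier_sd = 100))$participants
  adj_cols <- c(sbp = "sbp_adj", dbp = "dbp_adj", tc = "tc_adj")
  for (nm in names(cfg$traits)) {
    tr <- cfg$traits[[nm]]
    col <- if (nm %in% names(adj_cols)) adj_cols[[nm]] else nm
    for (s in c("m", "f")) {
      x <- p[[col]][p$sex == if (s == "m") "male" else "female"]
      if (tr$scale == "log10") x <- log10(x)
      mu <- tr[[paste0("mean_", s)]]
      sg <- tr[[paste0("sd_", s)]]
      n <- length(x)
      expect_lt(abs(mean(x) - mu), 3 * sg / sqrt(n))
      expect_lt(abs(sd(x) - sg), 3 * sg / sqrt(2 * n))
    }
  }
  # age structure, including the spousal age correlation
  am <- p$age[p$sex == "male"]; af <- p$age[p$sex == "female"]
  expect_lt(abs(mean(am) - 63.2), 3 * 10.5 / sqrt(5000))
  expect_lt(abs(mean(af) - 60.4), 3 * 10.2 / sqrt(5000))
  expect_gt(raw_pair_cor(coh, "age"), 0.92)
})

test_that("without couple effects or age trends, spouses are uncorrelated", {
  cfg <- null_config(5000)
  coh <- generate_cohort(cfg, seed = 31)
  # joint 3-SE band for seven simultaneous checks; nominal 95% coverage of
  # the Fisher interval is asserted separately over replicates
  half <- 3 / sqrt(5000 - 3)
  for (nm in c("weight", "height", "sbp", "hba1c", "tg", "hdl",
               "met_hours")) {
    r <- raw_pair_cor(coh, nm)
    expect_lt(abs(atanh(r)), half + 1e-12)
  }
})

test_that("null spousal correlations achieve nominal Fisher coverage", {
  cfg <- null_config(250)
  traits <- c("weight", "sbp", "hdl")
  reps <- 200
  covered <- matrix(FALSE, reps, length(traits),
                    dimnames = list(NULL, traits))
  half <- qnorm(0.975) / sqrt(250 - 3)
  for (i in seq_len(reps)) {
    coh <- generate_cohort(cfg, seed = 1000 + i)
    for (tr in traits)
      covered[i, tr] <- abs(atanh(raw_pair_cor(coh, tr))) <= half
  }
  rates <- colMeans(covered)
  expect_true(all(rates > 0.90))
  expect_true(all(rates <= 1.00))
  expect_true(mean(rates) < 0.995)  # not degenerate over-coverage
})

test_that("injected couple correlation shifts spousal similarity monotonically", {
  grid <- c(0, 0.15, 0.30)
  reps <- 50
  means <- sapply(seq_along(grid), function(g) {
    cfg <- null_config(300)
    cfg$traits$weight$couple_corr <- grid[g]
    mean(sapply(seq_len(reps), function(i) {
      raw_pair_cor(generate_cohort(cfg, seed = 5000 + 100 * g + i), "weight")
    }))
  })
  expect_lt(means[1], means[2])
  expect_lt(means[2], means[3])
})

test_that("medication is gated on the pre-treatment thresholds", {
  cfg <- null_config(2000, zero_slopes = FALSE)
  coh <- generate_cohort(cfg, seed = 41)
  d <- derive_all(coh)
  p <- d$participants
  # back-adjusted values of treated individuals sit above the gates
  trt <- which(p$on_antihypertensive & !is.na(p$sbp_adj) & !is.na(p$dbp_adj))
  expect_gt(length(trt), 50)
  expect_true(all(p$sbp_adj[trt] >= 140 | p$dbp_adj[trt] >= 90))
  lip <- which(p$on_lipid_lowering & !is.na(p$tc_adj))
  expect_gt(length(lip), 20)
  expect_true(all(p$tc_adj[lip] >= 240))
  glu <- which(p$on_glucose_lowering & !is.na(p$hba1c))
  expect_gt(length(glu), 20)
  expect_true(all(p$hba1c[glu] >= 6.0))
})

test_that("cohorts round-trip through the CSV schema", {
  cfg <- default_config()
  cfg$n_pairs <- 120L
  coh <- generate_cohort(cfg, seed = 51)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(file.path(dir, "participants.csv"),
                      file.path(dir, "pairs.csv"))
  expect_equal(back$participants, coh$participants, tolerance = 1e-12)
  expect_identical(back$pairs, coh$pairs)
})

test_that("configurations round-trip through YAML", {
  cfg <- default_config()
  cfg$n_pairs <- 17L
  cfg$traits$sbp$couple_corr <- 0.2
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$n_pairs, 17)
  expect_equal(back$traits$sbp$couple_corr, 0.2)
  expect_equal(back$missing_rates, cfg$missing_rates)
  expect_equal(back$age_corr, cfg$age_corr)
})
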