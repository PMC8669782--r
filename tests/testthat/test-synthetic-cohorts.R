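test_that("config validation rejects impossible parameters naming the field", {
  expect_error(sim_config(n_cohorts = 0), "n_cohorts")
  expect_error(sim_config(followup_years = 0), "followup_years")
  expect_error(sim_config(cohort_intercept_sd = -1), "cohort_intercept_sd")
  bad <- default_exposure_spec()
  bad$sd_within[2] <- -0.1
  expect_error(sim_config(exposures = bad), "sd_within")
  ms <- default_missing_spec()
  ms$p_cohort[1] <- 1.2
  expect_error(sim_config(missing_spec = ms), "missing_spec")
})

test_that("same seed gives identical datasets, different seeds differ", {
  a <- tiny_sim(seed = 5)
  b <- tiny_sim(seed = 5)
  c <- tiny_sim(seed = 6)
  expect_identical(a$participants, b$participants)
  expect_identical(a$repeats, b$repeats)
  expect_false(identical(a$participants, c$participants))
})

test_that("zero within-person SD makes repeats identical to the usual level", {
  spec <- default_exposure_spec()
  spec$sd_within <- 0
  sim <- simulate_cohorts(sim_config(
    n_cohorts = 3, n_per_cohort = 100, exposures = spec,
    repeat_measure_times = c(2, 4), missing_spec = no_missing_spec(), seed = 9
  ))
  truth <- tidyr::pivot_longer(sim$true_exposures, -participant_id,
                               names_to = "risk_factor", values_to = "true")
  joined <- dplyr::inner_join(sim$repeats, truth,
                              by = c("participant_id", "risk_factor"))
  expect_gt(nrow(joined), 0)
  expect_equal(joined$value, joined$true)
  # baseline observation equals the usual level too
  base <- tidyr::pivot_longer(sim$participants,
                              dplyr::all_of(c("bmi", "sbp", "fpg", "tc", "nonhdl")),
                              names_to = "risk_factor", values_to = "obs")
  base <- dplyr::inner_join(base, truth, by = c("participant_id", "risk_factor"))
  expect_equal(base$obs, base$true)
})

test_that("null effects reproduce the configured baseline rate (Poisson oracle)", {
  # all log RRs zero, no cohort heterogeneity, no sex effect, flat hazard:
  # events are a Poisson process at exactly `rate`, so the empirical rate
  # must fall within 3 Monte Carlo SEs at ~50,000 person-years
  rate <- 0.002
  sim0 <- simulate_cohorts(sim_config(
    n_cohorts = 5, n_per_cohort = 1500, age_range = c(40, 70),
    true_log_rr = default_true_log_rr_zero(),
    baseline_rate_by_age = tibble::tibble(age_lo = 20, rate = rate),
    sex_log_rr = 0, cohort_intercept_sd = 0, followup_years = 8,
    missing_spec = no_missing_spec(), seed = 22
  ))
  py <- sum(sim0$participants$followup_time)
  expect_gt(py, 5e4)
  events <- sum(sim0$participants$event)
  mc_se <- sqrt(rate / py)
  expect_lt(abs(events / py - rate), 3 * mc_se)
})

test_that("realised missingness matches the configured probabilities", {
  ms <- tibble::tibble(
    risk_factor = c("bmi", "sbp", "fpg", "tc", "nonhdl"),
    p_cohort = c(0, 0, 0, 0, 0), p_mcar = c(0.3, 0.1, 0, 0, 0)
  )
  sim <- simulate_cohorts(sim_config(n_cohorts = 5, n_per_cohort = 1000,
                                     missing_spec = ms, seed = 13))
  p <- sim$participants
  n <- nrow(p)
  for (rf in c("bmi", "sbp")) {
    pm <- ms$p_mcar[ms$risk_factor == rf]
    se <- sqrt(pm * (1 - pm) / n)
    expect_lt(abs(mean(is.na(p[[rf]])) - pm), 2 * se)
  }
  expect_false(anyNA(p$tc))
  # cohort-level missingness knocks out whole cohorts at a time
  ms2 <- ms
  ms2$p_cohort <- c(0.5, 0, 0, 0, 0)
  ms2$p_mcar <- 0
  sim2 <- simulate_cohorts(sim_config(n_cohorts = 40, n_per_cohort = 20,
                                      missing_spec = ms2, seed = 14))
  frac <- tapply(is.na(sim2$participants$bmi), sim2$participants$cohort, mean)
  expect_true(all(frac %in% c(0, 1)))
  se <- sqrt(0.5 * 0.5 / 40)
  expect_lt(abs(mean(frac) - 0.5), 2 * se)
})

test_that("empirical regression-dilution ratio converges to the variance ratio", {
  # sigma_b^2 / (sigma_b^2 + sigma_w^2) = 2/3 by construction
  sim <- single_band_sim(seed = 31, n_cohorts = 4, n_per_cohort = 2000,
                         true_log_rr_sbp = 0, sd_within_frac = 1 / 3)
  pairs <- repeat_pairs(sim, "sbp")
  expect_gt(nrow(pairs), 5000)
  slope <- coef(lm(repeat_value ~ baseline, data = pairs))[["baseline"]]
  expect_lt(abs(slope - 2 / 3), 0.03)
})

test_that("follow-up respects the administrative horizon and events are labelled", {
  sim <- tiny_sim(seed = 8)
  p <- sim$participants
  expect_true(all(p$followup_time <= sim$config$followup_years + 1e-12))
  expect_true(all(p$followup_time > 0))
  expect_true(all(p$event %in% 0:1))
  expect_equal(p$event, p$event_fatal + p$event_nonfatal)
  frac_fatal <- mean(p$event_fatal[p$event == 1])
  expect_gt(frac_fatal, 0.3)
  expect_lt(frac_fatal, 0.8)
})

test_that("cohort sets round-trip to disk with a YAML truth sidecar", {
  sim <- tiny_sim(seed = 15, n_cohorts = 3, n_per_cohort = 50)
  dir <- withr::local_tempdir()
  write_cohorts(sim, dir)
  expect_true(file.exists(file.path(dir, "participants.csv")))
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$seed, 15)
  expect_equal(truth$n_cohorts, 3)
  back <- readr::read_csv(file.path(dir, "participants.csv"), show_col_types = FALSE)
  expect_equal(nrow(back), nrow(sim$participants))
})
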