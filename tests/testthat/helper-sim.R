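# small, fast simulation configurations shared across test files

tiny_sim <- function(seed = 42, n_cohorts = 6, n_per_cohort = 200, ...) {
  simulate_cohorts(sim_config(n_cohorts = n_cohorts, n_per_cohort = n_per_cohort,
                              seed = seed, ...))
}

# single-band generator: everyone enters at 55, one modelling band captures
# all follow-up, so band fits see the whole dataset
single_band_sim <- function(seed, n_cohorts = 20, n_per_cohort = 2000,
                            true_log_rr_sbp = log(1.02),
                            cohort_intercept_sd = 0.3,
                            rate = 0.004, sd_within_frac = NULL) {
  exp_spec <- default_exposure_spec()
  if (!is.null(sd_within_frac)) {
    tot <- sqrt(exp_spec$sd_between^2 + exp_spec$sd_within^2)
    exp_spec$sd_within <- tot * sqrt(sd_within_frac)
    exp_spec$sd_between <- tot * sqrt(1 - sd_within_frac)
  }
  tl <- default_true_log_rr_zero()
  tl["sbp"] <- true_log_rr_sbp
  simulate_cohorts(sim_config(
    n_cohorts = n_cohorts, n_per_cohort = n_per_cohort,
    age_range = c(55, 55.01), age_mean = 55, age_sd = 0.001,
    exposures = exp_spec, true_log_rr = tl,
    baseline_rate_by_age = tibble::tibble(age_lo = c(20, 55), rate = c(rate, rate)),
    cohort_intercept_sd = cohort_intercept_sd,
    followup_years = 8, repeat_measure_times = 3,
    missing_spec = no_missing_spec(), seed = seed
  ))
}

default_true_log_rr_zero <- function() {
  stats::setNames(rep(0, 5), c("bmi", "sbp", "fpg", "tc", "nonhdl"))
}

no_missing_spec <- function() {
  tibble::tibble(
    risk_factor = c("bmi", "sbp", "fpg", "tc", "nonhdl"),
    p_cohort = 0, p_mcar = 0
  )
}

# minimal hand-built participant table
mk_participants <- function(age, followup, fatal = 0, nonfatal = 0,
                            cohort = "c1", sex = "female", sbp = 130) {
  n <- max(lengths(list(age, followup, fatal, nonfatal, cohort, sex, sbp)))
  tibble::tibble(
    participant_id = paste0("p", seq_len(n)),
    cohort = rep_len(cohort, n), sex = rep_len(sex, n),
    age_baseline = rep_len(age, n), followup_time = rep_len(followup, n),
    event_fatal = rep_len(fatal, n), event_nonfatal = rep_len(nonfatal, n),
    sbp = rep_len(sbp, n)
  )
}
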