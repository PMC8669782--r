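#' Default generative exposure specification
#'
#' One row per cardio-metabolic risk factor with the population mean and the
#' split of total cross-sectional variance into between-person ("usual" level)
#' and within-person (measurement-occasion) components. Defaults use pooled
#' LAC cohort summary levels (BMI 27.2 kg/m2 SD 4.8, SBP 131 mmHg SD 22.1,
#' FPG 5.5 mmol/L SD 1.9, TC 5.3 mmol/L SD 1.3, non-HDL 4.2 mmol/L SD 1.3);
#' the between/within split is chosen so the implied regression-dilution
#' ratio reproduces the conventional correction factors (1.10 BMI, 1.50 SBP,
#' 1.53 FPG, 1.75 TC, 1.85 non-HDL): `sd_between^2 / total = 1 / factor`.
#'
#' @param correction_factors Named numeric vector of dilution correction
#'   factors used to split total SD into between/within components.
#' @return Tibble with columns `risk_factor`, `mean`, `sd_between`,
#'   `sd_within`, `units`.
#' @export
default_exposure_spec <- function(correction_factors = c(
                                    bmi = 1.10, sbp = 1.50, fpg = 1.53,
                                    tc = 1.75, nonhdl = 1.85
                                  )) {
  means <- c(bmi = 27.2, sbp = 131, fpg = 5.5, tc = 5.3, nonhdl = 4.2)
  sd_tot <- c(bmi = 4.8, sbp = 22.1, fpg = 1.9, tc = 1.3, nonhdl = 1.3)
  lambda <- 1 / correction_factors[RISK_FACTORS]
  tibble(
    risk_factor = RISK_FACTORS,
    mean = unname(means[RISK_FACTORS]),
    sd_between = unname(sd_tot[RISK_FACTORS] * sqrt(lambda)),
    sd_within = unname(sd_tot[RISK_FACTORS] * sqrt(1 - lambda)),
    units = unname(CANONICAL_UNITS[RISK_FACTORS])
  )
}

default_true_log_rr <- function() {
  # per canonical unit of usual exposure; generator knobs, not estimates
  c(bmi = 0.055, sbp = 0.022, fpg = 0.11, tc = 0.20, nonhdl = 0.24)
}

default_baseline_rates <- function() {
  # events per person-year by attained-age band (chosen once so the overall
  # simulated rate lands near ~116 per 100,000 person-years at the default mix)
  tibble(
    age_lo = c(20, 35, 45, 55, 65, 75, 85),
    rate = c(10, 26, 66, 170, 430, 1000, 2300) / 1e5
  )
}

default_missing_spec <- function() {
  # cohort-level: whole variable unmeasured in a sampled subset of cohorts;
  # then within-cohort missing-completely-at-random on the remainder
  tibble(
    risk_factor = RISK_FACTORS,
    p_cohort = c(0.05, 0.30, 0.55, 0.50, 0.60),
    p_mcar = rep(0.03, 5)
  )
}

#' Simulation configuration for synthetic pooled cohorts
#'
#' Bundles every generative parameter of the synthetic multi-cohort dataset:
#' cohort count and size, entry-age distribution, sex mix, per-risk-factor
#' exposure moments (between- and within-person SDs), true log incidence-rate
#' ratios per canonical unit of usual exposure, piecewise-constant baseline
#' hazard by attained-age band, cohort random-intercept SD, administrative
#' censoring horizon, repeat-measurement schedule, missingness mechanism and
#' the global seed from which all sub-streams are derived.
#'
#' @param n_cohorts,n_per_cohort Number of cohorts and participants per cohort.
#' @param age_range Entry-age support in years (default 20-85).
#' @param age_mean,age_sd Moments of the truncated-normal entry-age draw.
#' @param sex_fraction_female Proportion of women (default 0.837).
#' @param exposures Tibble as returned by [default_exposure_spec()].
#' @param true_log_rr Named numeric, true log-IRR per canonical unit of usual
#'   exposure (names must match `exposures$risk_factor`).
#' @param baseline_rate_by_age Tibble (`age_lo`, `rate`) of events per
#'   person-year; piecewise constant over attained age.
#' @param sex_log_rr Log rate ratio for men vs women.
#' @param cohort_intercept_sd SD of the cohort log-rate random intercepts.
#' @param followup_years Administrative censoring horizon (> 0).
#' @param repeat_measure_times Years from baseline at which exposures are
#'   re-measured.
#' @param fatal_fraction Probability an event is fatal (default 0.54).
#' @param missing_spec Tibble (`risk_factor`, `p_cohort`, `p_mcar`).
#' @param seed Integer master seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cohorts = 20, n_per_cohort = 1000,
                       age_range = c(20, 85), age_mean = 48, age_sd = 12,
                       sex_fraction_female = 0.837,
                       exposures = default_exposure_spec(),
                       true_log_rr = default_true_log_rr(),
                       baseline_rate_by_age = default_baseline_rates(),
                       sex_log_rr = 0.4,
                       cohort_intercept_sd = 0.3,
                       followup_years = 9,
                       repeat_measure_times = 4,
                       fatal_fraction = 0.54,
                       missing_spec = default_missing_spec(),
                       seed = 1L) {
  if (n_cohorts < 1 || n_per_cohort < 1) {
    abort("`n_cohorts` and `n_per_cohort` must be positive counts.")
  }
  if (followup_years <= 0) abort("`followup_years` must be > 0.")
  if (sex_fraction_female < 0 || sex_fraction_female > 1) {
    abort("`sex_fraction_female` must lie in [0, 1].")
  }
  if (fatal_fraction < 0 || fatal_fraction > 1) {
    abort("`fatal_fraction` must lie in [0, 1].")
  }
  if (any(exposures$sd_between < 0)) abort("negative variance: `sd_between` must be >= 0.")
  if (any(exposures$sd_within < 0)) abort("negative variance: `sd_within` must be >= 0.")
  if (cohort_intercept_sd < 0) abort("negative variance: `cohort_intercept_sd` must be >= 0.")
  if (any(baseline_rate_by_age$rate <= 0)) abort("`baseline_rate_by_age$rate` must be > 0.")
  if (!all(exposures$risk_factor %in% names(true_log_rr))) {
    abort("`true_log_rr` must be named for every risk factor in `exposures`.")
  }
  if (any(missing_spec$p_cohort < 0 | missing_spec$p_cohort > 1) ||
      any(missing_spec$p_mcar < 0 | missing_spec$p_mcar > 1)) {
    abort("missingness probabilities in `missing_spec` must lie in [0, 1].")
  }
  structure(
    list(
      n_cohorts = as.integer(n_cohorts), n_per_cohort = as.integer(n_per_cohort),
      age_range = age_range, age_mean = age_mean, age_sd = age_sd,
      sex_fraction_female = sex_fraction_female,
      exposures = exposures, true_log_rr = true_log_rr,
      baseline_rate_by_age = baseline_rate_by_age,
      sex_log_rr = sex_log_rr, cohort_intercept_sd = cohort_intercept_sd,
      followup_years = followup_years,
      repeat_measure_times = repeat_measure_times,
      fatal_fraction = fatal_fraction, missing_spec = missing_spec,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# normal draws truncated at a floor by resampling (keeps moments near-nominal
# provided the floor is several SDs below the mean)
rnorm_floor <- function(n, mean, sd, floor) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < floor)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < floor]
  }
  x
}

# piecewise-constant-hazard event times over attained age, vectorised.
# residence[i, j]: years participant i spends in hazard band j before the
# horizon; haz[i, j]: that band's hazard. Returns time to event (Inf if none
# before total residence runs out).
piecewise_event_time <- function(residence, haz) {
  cum_haz <- residence * haz
  if (ncol(cum_haz) > 1) cum_haz <- t(apply(cum_haz, 1, cumsum))
  target <- rexp(nrow(residence))
  j_hit <- apply(cum_haz >= target - 1e-12, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  t_event <- rep(Inf, nrow(residence))
  hit <- !is.na(j_hit)
  if (any(hit)) {
    idx <- cbind(seq_len(nrow(residence))[hit], j_hit[hit])
    prev <- ifelse(j_hit[hit] == 1, 0, cum_haz[cbind(idx[, 1], pmax(j_hit[hit] - 1, 1))])
    prev[j_hit[hit] == 1] <- 0
    time_before <- rowSums(residence[hit, , drop = FALSE] *
                             (col(residence[hit, , drop = FALSE]) < j_hit[hit]))
    t_event[hit] <- time_before + (target[hit] - prev) / haz[idx]
  }
  t_event
}

#' Generate a synthetic pooled multi-cohort dataset
#'
#' Draws a multi-cohort dataset with cohort-level baseline-rate heterogeneity,
#' between- and within-person exposure variability (so the regression-dilution
#' ratio is known by construction), log-linear exposure-hazard effects on a
#' piecewise-constant attained-age baseline hazard, administrative censoring,
#' fatal/non-fatal event labelling, and two-layer missingness (whole variables
#' unmeasured in a sampled subset of cohorts, then within-cohort MCAR).
#' Deterministic given `config$seed`; each internal stage draws from a
#' sub-stream derived from the master seed by a fixed offset.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `cohort_sim`: a list with `participants`
#'   (tibble, one row per participant with observed exposures), `repeats`
#'   (long tibble of repeat measurements), `true_exposures` (tibble of latent
#'   usual levels), `cohort_effects` (realised random intercepts) and `config`.
#' @export
simulate_cohorts <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a `sim_config` object.")
  cf <- config
  n <- cf$n_cohorts * cf$n_per_cohort
  rf <- cf$exposures$risk_factor
  K <- length(rf)

  ## sub-stream 0: population structure
  set.seed(cf$seed)
  cohort <- rep(sprintf("c%02d", seq_len(cf$n_cohorts)), each = cf$n_per_cohort)
  u <- rnorm(cf$n_cohorts, 0, cf$cohort_intercept_sd)
  names(u) <- sprintf("c%02d", seq_len(cf$n_cohorts))
  sex <- ifelse(runif(n) < cf$sex_fraction_female, "female", "male")
  age0 <- rnorm_floor(n, cf$age_mean, cf$age_sd, cf$age_range[1])
  over <- which(age0 > cf$age_range[2])
  while (length(over) > 0) {
    age0[over] <- rnorm_floor(length(over), cf$age_mean, cf$age_sd, cf$age_range[1])
    over <- over[age0[over] > cf$age_range[2]]
  }
  true_x <- matrix(NA_real_, n, K, dimnames = list(NULL, rf))
  for (k in seq_len(K)) {
    true_x[, k] <- rnorm_floor(n, cf$exposures$mean[k], cf$exposures$sd_between[k],
                               EXPOSURE_FLOORS[[rf[k]]])
  }

  ## sub-stream 1: event process
  set.seed(cf$seed + 1L)
  beta <- cf$true_log_rr[rf]
  eta <- u[cohort] + cf$sex_log_rr * (sex == "male") +
    drop(sweep(true_x, 2, cf$exposures$mean, "-") %*% beta)
  brk <- c(cf$baseline_rate_by_age$age_lo, Inf)
  J <- length(brk) - 1
  residence <- matrix(0, n, J)
  horizon_exit <- age0 + cf$followup_years
  for (j in seq_len(J)) {
    residence[, j] <- pmax(0, pmin(horizon_exit, brk[j + 1]) - pmax(age0, brk[j]))
  }
  haz <- outer(exp(eta), cf$baseline_rate_by_age$rate)
  t_event <- piecewise_event_time(residence, haz)
  event <- as.integer(t_event <= cf$followup_years)
  followup <- pmin(t_event, cf$followup_years)

  ## sub-stream 2: measurement noise (baseline + scheduled repeats)
  set.seed(cf$seed + 2L)
  obs_x <- true_x + sapply(seq_len(K), function(k) rnorm(n, 0, cf$exposures$sd_within[k]))
  colnames(obs_x) <- rf
  pid <- sprintf("%s_p%05d", cohort, rep(seq_len(cf$n_per_cohort), cf$n_cohorts))
  repeats <- tidyr::expand_grid(
    i = seq_len(n), time = cf$repeat_measure_times, risk_factor = rf
  )
  repeats$value <- true_x[cbind(repeats$i, match(repeats$risk_factor, rf))] +
    rnorm(nrow(repeats), 0, cf$exposures$sd_within[match(repeats$risk_factor, rf)])
  repeats <- repeats[repeats$time < followup[repeats$i], , drop = FALSE]

  ## sub-stream 3: missingness (cohort-level, then MCAR)
  set.seed(cf$seed + 3L)
  ms <- cf$missing_spec
  cohort_missing <- matrix(FALSE, cf$n_cohorts, K,
                           dimnames = list(names(u), rf))
  for (k in seq_len(K)) {
    p <- ms$p_cohort[match(rf[k], ms$risk_factor)]
    cohort_missing[, k] <- runif(cf$n_cohorts) < p
    miss <- cohort_missing[cohort, k] |
      (runif(n) < ms$p_mcar[match(rf[k], ms$risk_factor)])
    obs_x[miss, k] <- NA_real_
  }
  rep_k <- match(repeats$risk_factor, rf)
  rep_drop <- cohort_missing[cbind(match(cohort[repeats$i], names(u)), rep_k)] |
    (runif(nrow(repeats)) < ms$p_mcar[match(repeats$risk_factor, ms$risk_factor)])
  repeats <- repeats[!rep_drop, , drop = FALSE]

  ## sub-stream 4: fatal / non-fatal labels
  set.seed(cf$seed + 4L)
  fatal <- as.integer(event == 1 & runif(n) < cf$fatal_fraction)
  nonfatal <- as.integer(event == 1 & fatal == 0)

  participants <- tibble(
    participant_id = pid, cohort = cohort, sex = sex,
    age_baseline = age0, followup_time = followup,
    event = event, event_fatal = fatal, event_nonfatal = nonfatal
  ) %>%
    bind_cols(as_tibble(obs_x))

  structure(
    list(
      participants = participants,
      repeats = tibble(
        participant_id = pid[repeats$i], cohort = cohort[repeats$i],
        risk_factor = repeats$risk_factor, time = repeats$time,
        value = repeats$value
      ),
      true_exposures = tibble(participant_id = pid) %>% bind_cols(as_tibble(true_x)),
      cohort_effects = tibble(cohort = names(u), intercept = unname(u)),
      config = cf
    ),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim>", nrow(x$participants), "participants in",
      x$config$n_cohorts, "cohorts;",
      sum(x$participants$event), "events (",
      sum(x$participants$event_fatal), "fatal )\n")
  invisible(x)
}

#' Write a synthetic cohort set to disk
#'
#' Persists the participant table and repeat measurements as CSV and the full
#' generative configuration as a YAML truth sidecar, so downstream stages can
#' be run file-to-file and checked against ground truth.
#'
#' @param sim A `cohort_sim` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohorts <- function(sim, dir) {
  if (!inherits(sim, "cohort_sim")) abort("`sim` must be a `cohort_sim` object.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$participants, file.path(dir, "participants.csv"))
  readr::write_csv(sim$repeats, file.path(dir, "repeats.csv"))
  readr::write_csv(sim$true_exposures, file.path(dir, "true_exposures.csv"))
  cf <- sim$config
  truth <- list(
    n_cohorts = cf$n_cohorts, n_per_cohort = cf$n_per_cohort,
    age_range = cf$age_range, age_mean = cf$age_mean, age_sd = cf$age_sd,
    sex_fraction_female = cf$sex_fraction_female,
    exposures = as.list(as.data.frame(cf$exposures)),
    true_log_rr = as.list(cf$true_log_rr),
    baseline_rate_by_age = as.list(as.data.frame(cf$baseline_rate_by_age)),
    sex_log_rr = cf$sex_log_rr, cohort_intercept_sd = cf$cohort_intercept_sd,
    followup_years = cf$followup_years,
    repeat_measure_times = cf$repeat_measure_times,
    fatal_fraction = cf$fatal_fraction,
    missing_spec = as.list(as.data.frame(cf$missing_spec)),
    seed = cf$seed
  )
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
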