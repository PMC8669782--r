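one_band_segments <- function(seed = 71, n_cohorts = 8, n_per_cohort = 400,
                              ...) {
  sim <- single_band_sim(seed = seed, n_cohorts = n_cohorts,
                         n_per_cohort = n_per_cohort, ...)
  lexis_expand(sim$participants, outcome = "fatal")
}

test_that("the person-time offset behaves like a Poisson exposure term", {
  seg <- one_band_segments(seed = 71)
  f1 <- fit_band_model(seg, "sbp", nAGQ = 1)
  seg2 <- seg
  seg2$person_time <- 2 * seg2$person_time
  f2 <- fit_band_model(seg2, "sbp", nAGQ = 1)
  # doubling exposure time with events fixed: intercept drops by ln 2,
  # the exposure slope is untouched
  i1 <- f1$coefficients$estimate[f1$coefficients$term == "(Intercept)"]
  i2 <- f2$coefficients$estimate[f2$coefficients$term == "(Intercept)"]
  expect_equal(i2 - i1, -log(2), tolerance = 1e-4)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
})

test_that("with no cohort heterogeneity the mixed fit matches plain Poisson", {
  seg <- one_band_segments(seed = 72, cohort_intercept_sd = 0)
  f <- fit_band_model(seg, "sbp", nAGQ = 1, adjust_age = FALSE)
  expect_lt(f$sigma_u, 0.05)
  d <- seg[!is.na(seg$sbp), ]
  d$exposure <- d$sbp - mean(d$sbp)
  d$sex_male <- as.numeric(d$sex == "male")
  g <- glm(events ~ exposure + sex_male, family = poisson(),
           offset = log(person_time), data = d)
  expect_equal(f$beta, unname(coef(g)["exposure"]), tolerance = 1e-3)
  expect_equal(f$se, unname(sqrt(diag(vcov(g)))[2]), tolerance = 1e-2)
})

test_that("degenerate designs fail loudly", {
  seg <- one_band_segments(seed = 73, n_cohorts = 4, n_per_cohort = 150)
  seg$sbp <- 130
  expect_error(fit_band_model(seg, "sbp"), "constant")
  seg2 <- one_band_segments(seed = 73, n_cohorts = 4, n_per_cohort = 150)
  seg2$events <- 0L
  expect_error(fit_band_model(seg2, "sbp"), "no events")
  seg3 <- one_band_segments(seed = 73, n_cohorts = 4, n_per_cohort = 150)
  expect_error(fit_band_model(seg3[seg3$cohort == "c01", ], "sbp"), "2 cohorts")
})

test_that("band sweep skips empty bands and reports fitted ones", {
  sim <- tiny_sim(seed = 74, n_cohorts = 8, n_per_cohort = 400,
                  missing_spec = no_missing_spec())
  seg <- lexis_expand(sim$participants, outcome = "fatal")
  fits <- suppressMessages(fit_age_band_models(seg, "sbp", nAGQ = 1))
  expect_true(nrow(fits) >= 2)
  expect_true(all(fits$band %in% band_labels()))
  expect_true(all(fits$se > 0))
})

test_that("relative-risk assembly does the stated log-scale arithmetic", {
  # null coefficient: RR 1 with an interval symmetric around 1
  null_fit <- tibble::tibble(band = "45-54", beta = 0, se = 0.1)
  rr0 <- assemble_rrs(null_fit, correction = 1.7, increment = 10)
  expect_equal(rr0$rr, 1)
  expect_equal(rr0$ci_low * rr0$ci_high, 1, tolerance = 1e-12)
  # pooled beta 0.04, factor 1.5, increment 10: RR = exp(0.6)
  f <- tibble::tibble(band = "45-54", beta = 0.04, se = 0.01)
  rr <- assemble_rrs(f, correction = 1.5, increment = 10)
  expect_equal(rr$rr, exp(0.6))
  expect_equal(rr$log_rr, 0.06)
  expect_equal(rr$se, 0.015)
  expect_true(rr$corrected)
  # identity: factor 1, increment 1 leaves the per-unit RR untouched
  rr1 <- assemble_rrs(f, correction = 1, increment = 1)
  expect_equal(rr1$rr, exp(0.04))
  expect_false(rr1$corrected)
  # accepts a correction-factor table row
  rr2 <- assemble_rrs(f, correction = default_correction_factors()[2, ],
                      increment = 10)
  expect_equal(rr2$rr, exp(0.6))
})

test_that("assembly pools across imputations by Rubin's rules", {
  fits <- tibble::tibble(
    imputation = c(1, 2), band = "55-64", beta = c(0.3, 0.5), se = c(0.1, 0.1)
  )
  rr <- assemble_rrs(fits, correction = 1, increment = 1)
  manual <- rubin_pool(c(0.3, 0.5), c(0.01, 0.01))
  expect_equal(rr$m, 2L)
  expect_equal(rr$log_rr, manual$point)
  expect_equal(rr$se, manual$se)
  expect_equal(rr$df, manual$df)
  expect_equal(rr$ci_low, exp(manual$point - qt(0.975, manual$df) * manual$se))
  # non-converged rows are excluded
  fits$converged <- c(TRUE, FALSE)
  rr_c <- assemble_rrs(fits, correction = 1, increment = 1)
  expect_equal(rr_c$m, 1L)
  expect_equal(rr_c$log_rr, 0.3)
})

test_that("a single all-encompassing stratum reproduces the unstratified fit", {
  sim <- tiny_sim(seed = 75, n_cohorts = 6, n_per_cohort = 500,
                  missing_spec = no_missing_spec())
  seg <- lexis_expand(sim$participants, outcome = "fatal")
  strata <- setNames(rep("all", 6), sprintf("c%02d", 1:6))
  plain <- assemble_rrs(
    suppressMessages(fit_age_band_models(seg, "sbp", nAGQ = 1)),
    correction = 1.5, increment = 10, risk_factor = "sbp"
  )
  strat <- suppressMessages(
    stratified_rrs(seg, strata, "sbp", correction = 1.5, increment = 10, nAGQ = 1)
  )
  expect_equal(strat$rr, plain$rr)
  expect_equal(unique(strat$stratum), "all")
  # a stratum with a single cohort is skipped with a warning
  strata2 <- setNames(c(rep("big", 5), "lonely"), sprintf("c%02d", 1:6))
  expect_warning(
    out <- suppressMessages(
      stratified_rrs(seg, strata2, "sbp", correction = 1, nAGQ = 1)
    ),
    "lonely"
  )
  expect_setequal(unique(out$stratum), "big")
  # unmapped cohorts are a hard error
  expect_error(stratified_rrs(seg, strata2[-1], "sbp"), "c01")
})
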