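label_midpoint <- function(band) {
  plus <- grepl("\\+$", band)
  out <- numeric(length(band))
  out[plus] <- as.numeric(sub("\\+$", "", band[plus])) + 5
  out[!plus] <- (as.numeric(sub("-.*", "", band[!plus])) +
                   as.numeric(sub(".*-", "", band[!plus])) + 1) / 2
  out
}

#' Poisson random-intercept model for one attained-age band
#'
#' Fits event counts on person-time segments within a single age band as
#' Poisson with log person-time offset: log mean = log(person-time) +
#' beta * exposure + gamma1 * sex + gamma2 * (age at risk - band midpoint) +
#' cohort random intercept, the intercepts integrated out by adaptive
#' Gauss-Hermite quadrature (7 points by default; Laplace fallback). The
#' exposure coefficient is the log incidence-rate ratio per canonical unit.
#'
#' @param segments Segment tibble for one band (see [lexis_expand()]) with
#'   the exposure column present; rows with a missing exposure are dropped.
#' @param risk_factor Name of the exposure column.
#' @param nAGQ Quadrature points (1 = Laplace).
#' @param adjust_sex,adjust_age Include the sex and centred age-at-risk
#'   covariates (dropped automatically when constant).
#' @return Object of class `band_fit`: coefficient table, `beta`, `se`,
#'   `sigma_u` (cohort intercept SD), convergence flag and the underlying
#'   `glmerMod` fit.
#' @export
fit_band_model <- function(segments, risk_factor, nAGQ = 7,
                           adjust_sex = TRUE, adjust_age = TRUE) {
  stopifnot(risk_factor %in% names(segments))
  d <- segments[!is.na(segments[[risk_factor]]), , drop = FALSE]
  if (nrow(d) == 0 || sum(d$events) < 1) abort("no events in this band: nothing to fit.")
  if (length(unique(d$cohort)) < 2) abort("need >= 2 cohorts for a random-intercept fit.")
  if (sd(d[[risk_factor]]) == 0) {
    abort(paste0("degenerate design: exposure `", risk_factor, "` is constant."))
  }
  band <- unique(d$band)
  if (length(band) != 1) abort("`segments` must contain exactly one age band.")
  # centring the exposure improves conditioning and leaves its slope unchanged
  exposure_centre <- mean(d[[risk_factor]])
  d$exposure <- d[[risk_factor]] - exposure_centre
  d$sex_male <- as.numeric(d$sex == "male")
  d$age_c <- d$age_at_risk - label_midpoint(band)
  terms <- "exposure"
  if (adjust_sex && sd(d$sex_male) > 0) terms <- c(terms, "sex_male")
  if (adjust_age && sd(d$age_c) > 0) terms <- c(terms, "age_c")
  form <- as.formula(paste("events ~", paste(terms, collapse = " + "), "+ (1 | cohort)"))
  quiet_glmer <- function(q) {
    tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(form, data = d, family = poisson(),
                    offset = log(d$person_time), nAGQ = q)
      )),
      error = function(e) NULL
    )
  }
  fit <- quiet_glmer(nAGQ)
  if (is.null(fit) && nAGQ != 1) fit <- quiet_glmer(1)
  if (is.null(fit)) abort("band model failed to fit.")
  # small samples can make the finite-difference Hessian indefinite; lme4
  # then falls back to the RX approximation for the var-cov, which is fine
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0) &&
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  structure(
    list(
      band = band, risk_factor = risk_factor,
      beta = unname(co["exposure", "Estimate"]),
      se = unname(co["exposure", "Std. Error"]),
      coefficients = tibble(
        term = rownames(co), estimate = unname(co[, "Estimate"]),
        std_error = unname(co[, "Std. Error"]),
        statistic = unname(co[, "z value"]),
        p_value = unname(co[, "Pr(>|z|)"])
      ),
      sigma_u = sqrt(unname(lme4::VarCorr(fit)$cohort[1])),
      converged = converged,
      n_events = sum(d$events), n_cohorts = length(unique(d$cohort)),
      nobs = nrow(d), fit = fit
    ),
    class = "band_fit"
  )
}

#' @export
print.band_fit <- function(x, ...) {
  cat("<band_fit>", x$risk_factor, "in band", x$band, ":",
      sprintf("beta = %.5f (se %.5f), sigma_u = %.3f, %d events in %d cohorts\n",
              x$beta, x$se, x$sigma_u, x$n_events, x$n_cohorts))
  invisible(x)
}

#' Fit the age-band Poisson models across all bands
#'
#' Runs [fit_band_model()] for every age band present in the segments;
#' bands with no events (or other degeneracies) are skipped with a message
#' and reported as absent rows.
#'
#' @inheritParams fit_band_model
#' @param segments Segment tibble covering any number of bands.
#' @return Tibble, one row per fitted band: `band`, `beta`, `se`, `sigma_u`,
#'   `converged`, `n_events`, `n_cohorts`, `nobs`.
#' @export
fit_age_band_models <- function(segments, risk_factor, nAGQ = 7, ...) {
  bands <- intersect(band_labels(), unique(segments$band))
  purrr::map(bands, function(b) {
    f <- tryCatch(
      fit_band_model(segments[segments$band == b, , drop = FALSE],
                     risk_factor, nAGQ = nAGQ, ...),
      error = function(e) {
        rlang::inform(paste0("band ", b, " skipped: ", conditionMessage(e)))
        NULL
      }
    )
    if (is.null(f)) return(NULL)
    tibble(
      band = f$band, beta = f$beta, se = f$se, sigma_u = f$sigma_u,
      converged = f$converged, n_events = f$n_events,
      n_cohorts = f$n_cohorts, nobs = f$nobs
    )
  }) %>% bind_rows()
}

#' Assemble corrected age-specific relative risks
#'
#' Pools per-imputation band coefficients by Rubin's rules, applies the
#' regression-dilution correction factor on the log scale (to both point and
#' standard error), and exponentiates at the display increment. Confidence
#' intervals use the t distribution with Rubin degrees of freedom (normal
#' when a single imputation is supplied).
#'
#' @param fits Tibble of band fits with columns `band`, `beta`, `se`,
#'   optionally `imputation` and `converged` (non-converged fits are
#'   excluded from pooling).
#' @param correction Correction factor: a single number, or a tibble with
#'   `factor` (e.g. one row of [default_correction_factors()]).
#' @param increment Display increment in canonical units (RR per
#'   `increment` units); the stored `log_rr` stays per unit.
#' @param level Confidence level.
#' @param risk_factor Optional label carried into the output.
#' @return Tibble of class `rr_table`: `band`, `m`, `log_rr`, `se` (both
#'   corrected, per unit), `df`, `increment`, `rr`, `ci_low`, `ci_high`,
#'   `corrected`.
#' @export
assemble_rrs <- function(fits, correction = 1, increment = 1, level = 0.95,
                         risk_factor = NA_character_) {
  if (is.data.frame(correction)) correction <- correction$factor
  stopifnot(is.numeric(correction), length(correction) == 1)
  if (correction < 1) warn("correction factor below 1: dilution normally attenuates.")
  if ("converged" %in% names(fits)) fits <- fits[fits$converged, , drop = FALSE]
  if (nrow(fits) == 0) abort("no converged fits to assemble.")
  pooled <- fits %>%
    group_by(.data$band) %>%
    group_modify(function(g, key) {
      if (nrow(g) == 1) {
        tibble(m = 1L, point = g$beta, total_var = g$se^2, df = Inf)
      } else {
        rubin_pool(g$beta, g$se^2)[, c("m", "point", "total_var", "df")]
      }
    }) %>%
    ungroup()
  a <- (1 - level) / 2
  pooled %>%
    mutate(
      risk_factor = risk_factor,
      log_rr = .data$point * correction,
      se = sqrt(.data$total_var) * correction,
      increment = increment,
      rr = exp(.data$log_rr * increment),
      ci_low = exp((.data$log_rr - qt(1 - a, .data$df) * .data$se) * increment),
      ci_high = exp((.data$log_rr + qt(1 - a, .data$df) * .data$se) * increment),
      corrected = correction != 1
    ) %>%
    select("risk_factor", "band", "m", "log_rr", "se", "df", "increment",
           "rr", "ci_low", "ci_high", "corrected") %>%
    arrange(match(.data$band, band_labels())) %>%
    structure(class = c("rr_table", class(tibble())))
}

#' Age-specific relative risks by cohort stratum
#'
#' Partitions cohorts into strata (e.g. geographic sub-regions), refits the
#' age-band models independently within each stratum with identical
#' machinery, and assembles corrected RR tables per stratum. Strata with
#' fewer than two cohorts are skipped with a warning.
#'
#' @inheritParams fit_age_band_models
#' @param strata Named character vector or tibble (`cohort`, `stratum`)
#'   mapping every cohort to its stratum.
#' @inheritParams assemble_rrs
#' @return `rr_table` tibble with a leading `stratum` column.
#' @export
stratified_rrs <- function(segments, strata, risk_factor, correction = 1,
                           increment = 1, nAGQ = 7, ...) {
  if (is.data.frame(strata)) strata <- setNames(strata$stratum, strata$cohort)
  unmapped <- setdiff(unique(segments$cohort), names(strata))
  if (length(unmapped) > 0) {
    abort(paste0("cohort(s) not mapped to a stratum: ", paste(unmapped, collapse = ", ")))
  }
  purrr::map(unique(strata), function(s) {
    cohorts <- names(strata)[strata == s]
    seg_s <- segments[segments$cohort %in% cohorts, , drop = FALSE]
    if (length(unique(seg_s$cohort)) < 2) {
      warn(paste0("stratum `", s, "` skipped: fewer than 2 cohorts."))
      return(NULL)
    }
    fits <- fit_age_band_models(seg_s, risk_factor, nAGQ = nAGQ, ...)
    if (nrow(fits) == 0) {
      warn(paste0("stratum `", s, "` skipped: no fittable bands."))
      return(NULL)
    }
    assemble_rrs(fits, correction = correction, increment = increment,
                 risk_factor = risk_factor) %>%
      mutate(stratum = s, .before = 1)
  }) %>% bind_rows()
}
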