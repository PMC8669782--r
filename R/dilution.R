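#' Regression-dilution ratio by the MacMahon grouped-means method
#'
#' Groups baseline/repeat measurement pairs into quantile groups of the
#' baseline value (quintiles by default), computes each group's mean baseline
#' and mean repeat value, and estimates the regression-dilution ratio (RDR)
#' as the least-squares slope of the repeat group means on the baseline group
#' means. With two groups this reduces to the range ratio. The RDR estimates
#' the attenuation `sd_between^2 / (sd_between^2 + sd_within^2)` of a
#' one-off baseline measurement relative to the usual level; its reciprocal
#' is the correction factor applied to log relative risks.
#'
#' @param pairs Tibble with columns `baseline` and `repeat_value` (optionally
#'   `cohort`, `participant_id`).
#' @param n_groups Number of quantile groups (default 5).
#' @return One-row tibble: `rdr`, `factor`, `n_pairs`, `n_groups`.
#' @export
macmahon_rdr <- function(pairs, n_groups = 5) {
  stopifnot(all(c("baseline", "repeat_value") %in% names(pairs)))
  pairs <- pairs[is.finite(pairs$baseline) & is.finite(pairs$repeat_value), , drop = FALSE]
  if (nrow(pairs) < 2 * n_groups) {
    abort(paste0("need at least ", 2 * n_groups, " pairs for ", n_groups, " groups."))
  }
  if (sd(pairs$baseline) == 0) abort("all baseline values identical: slope undefined.")
  qs <- quantile(pairs$baseline, probs = seq(0, 1, length.out = n_groups + 1))
  grp <- cut(pairs$baseline, breaks = unique(qs), include.lowest = TRUE)
  gm <- pairs %>%
    mutate(.grp = grp) %>%
    group_by(.data$.grp) %>%
    summarise(mb = mean(.data$baseline), mr = mean(.data$repeat_value), .groups = "drop")
  if (nrow(gm) < 2) abort("fewer than two distinct baseline groups: slope undefined.")
  slope <- coef(lm(mr ~ mb, data = gm))[["mb"]]
  tibble(rdr = slope, factor = 1 / slope, n_pairs = nrow(pairs), n_groups = n_groups)
}

#' Extract baseline/repeat pairs from a synthetic cohort set
#'
#' Pairs each participant's observed baseline exposure with the first repeat
#' measurement taken at least `min_gap` years after baseline (short-interval
#' repeats carry correlated error and are skipped).
#'
#' @param sim A `cohort_sim` object, or a list with `participants` and
#'   `repeats` tibbles.
#' @param risk_factor Which exposure to pair.
#' @param min_gap Minimum years between baseline and repeat (default 1).
#' @return Tibble of `RepeatMeasurePair`s: `participant_id`, `cohort`,
#'   `risk_factor`, `baseline`, `repeat_value`, `gap_years`.
#' @export
repeat_pairs <- function(sim, risk_factor, min_gap = 1) {
  stopifnot(risk_factor %in% RISK_FACTORS)
  base <- sim$participants %>%
    select("participant_id", "cohort", baseline = all_of(risk_factor))
  reps <- sim$repeats %>%
    filter(.data$risk_factor == !!risk_factor, .data$time >= min_gap) %>%
    arrange(.data$participant_id, .data$time) %>%
    distinct(.data$participant_id, .keep_all = TRUE) %>%
    select("participant_id", repeat_value = "value", gap_years = "time")
  base %>%
    inner_join(reps, by = "participant_id") %>%
    filter(is.finite(.data$baseline), is.finite(.data$repeat_value)) %>%
    mutate(risk_factor = !!risk_factor, .after = "cohort")
}

#' Pool per-cohort regression-dilution ratios
#'
#' Pools cohort-specific RDR estimates as the pair-count-weighted mean and
#' reports the pooled correction factor (its reciprocal).
#'
#' @param per_cohort Tibble with columns `cohort`, `rdr`, `n_pairs`.
#' @param risk_factor Optional label carried into the output.
#' @return One-row tibble: `risk_factor`, `rdr`, `factor`, `n_pairs`,
#'   `n_cohorts`.
#' @export
pool_rdr <- function(per_cohort, risk_factor = NA_character_) {
  stopifnot(all(c("cohort", "rdr", "n_pairs") %in% names(per_cohort)))
  if (nrow(per_cohort) < 1) abort("need at least one cohort.")
  keep <- per_cohort$n_pairs > 0
  w <- per_cohort$n_pairs[keep]
  pooled <- sum(per_cohort$rdr[keep] * w) / sum(w)
  tibble(
    risk_factor = risk_factor, rdr = pooled, factor = 1 / pooled,
    n_pairs = sum(w), n_cohorts = sum(keep)
  )
}

#' Correct a log relative risk for regression dilution bias
#'
#' Multiplies the log relative risk and its standard error by the correction
#' factor (the reciprocal of the regression-dilution ratio). The factor is
#' treated as fixed, so confidence-interval widths scale proportionally on
#' the log scale.
#'
#' @param log_rr Log relative risk(s) per unit of baseline exposure.
#' @param factor Correction factor (>= 1 for attenuating noise).
#' @param se Optional standard error(s), scaled by the same factor.
#' @return Tibble with `log_rr` (corrected) and, when `se` is given, `se`.
#' @export
apply_correction <- function(log_rr, factor, se = NULL) {
  if (any(factor <= 0)) abort("`factor` must be positive.")
  out <- tibble(log_rr = log_rr * factor)
  if (!is.null(se)) out$se <- se * factor
  out
}

#' Conventional regression-dilution correction factors
#'
#' The packaged default correction-factor table for the five cardio-metabolic
#' risk factors, as estimated from LAC cohorts with repeated measurements:
#' 1.10 (BMI), 1.50 (SBP), 1.53 (FPG), 1.75 (TC), 1.85 (non-HDL). Used when
#' no repeat-measurement data are supplied.
#'
#' @return Tibble: `risk_factor`, `rdr`, `factor`.
#' @export
default_correction_factors <- function() {
  f <- c(bmi = 1.10, sbp = 1.50, fpg = 1.53, tc = 1.75, nonhdl = 1.85)
  tibble(risk_factor = names(f), rdr = unname(1 / f), factor = unname(f))
}

#' Estimate pooled correction factors from a synthetic cohort set
#'
#' Runs the MacMahon estimator within each cohort that has repeat
#' measurements and pools across cohorts by pair count, for each requested
#' risk factor.
#'
#' @inheritParams repeat_pairs
#' @param risk_factors Which exposures to process.
#' @param n_groups Quantile groups for [macmahon_rdr()].
#' @param min_pairs Cohorts contributing fewer pairs are skipped.
#' @return Tibble, one row per risk factor (see [pool_rdr()]).
#' @export
estimate_correction_factors <- function(sim, risk_factors = RISK_FACTORS,
                                        n_groups = 5, min_gap = 1,
                                        min_pairs = 10 * n_groups) {
  purrr::map(risk_factors, function(rf) {
    pairs <- repeat_pairs(sim, rf, min_gap = min_gap)
    per_cohort <- pairs %>%
      group_by(.data$cohort) %>%
      filter(n() >= min_pairs) %>%
      group_modify(~ macmahon_rdr(.x, n_groups = n_groups)) %>%
      ungroup()
    if (nrow(per_cohort) == 0) return(NULL)
    pool_rdr(per_cohort, risk_factor = rf)
  }) %>% bind_rows()
}
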