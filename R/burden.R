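#' Default optimal (counterfactual) exposure levels
#'
#' Conventional theoretical-minimum-risk exposure levels used as the
#' counterfactual population means in the comparative risk assessment:
#' BMI 21 kg/m2, SBP 115 mmHg, TC 3.8 mmol/L, non-HDL 2.6 mmol/L. FPG is
#' excluded from the burden stage (no population exposure surface is
#' available for it).
#'
#' @return Tibble: `risk_factor`, `optimal`.
#' @export
default_optimal_levels <- function() {
  tibble(
    risk_factor = c("bmi", "sbp", "tc", "nonhdl"),
    optimal = c(21, 115, 3.8, 2.6)
  )
}

#' Interpolate 10-year-band relative risks to 5-year age groups
#'
#' Anchors each 10-year band's log RR at the band midpoint (40, 50, ..., 90
#' for 85+), interpolates log RR linearly in age across the anchors,
#' evaluates at the 5-year group reference ages (20, 25, ..., 85; see
#' [age_groups_5y()]), and extrapolates flat beyond the outermost anchors
#' (so ages below 35 carry the youngest band's RR). Because the band
#' anchors lie on the evaluation grid, band estimates are reproduced
#' exactly. Standard errors are interpolated the same way.
#'
#' @param rr An `rr_table` (see [assemble_rrs()]) or any tibble with
#'   `band`, `log_rr` and `se` columns (optionally `risk_factor`).
#' @return Tibble of class `rr_5y`: `risk_factor`, `age_group`, `age_ref`,
#'   `log_rr`, `se` for every 5-year group from 20-24 to 85+.
#' @export
interpolate_rr_5y <- function(rr) {
  stopifnot(all(c("band", "log_rr", "se") %in% names(rr)))
  if (!"risk_factor" %in% names(rr)) rr$risk_factor <- NA_character_
  out <- rr %>%
    group_by(.data$risk_factor) %>%
    group_modify(function(g, key) {
      if (nrow(g) < 1) abort("need at least one band with an estimate.")
      if (nrow(g) == 1) {
        warn("single age band: relative-risk surface is constant in age.")
      }
      mids <- label_midpoint(g$band)
      grid <- age_groups_5y()
      tibble(
        age_group = grid$age_group, age_ref = grid$age_ref,
        log_rr = if (nrow(g) == 1) rep(g$log_rr, nrow(grid)) else {
          approx(mids, g$log_rr, xout = grid$age_ref, rule = 2)$y
        },
        se = if (nrow(g) == 1) rep(g$se, nrow(grid)) else {
          approx(mids, g$se, xout = grid$age_ref, rule = 2)$y
        }
      )
    }) %>%
    ungroup()
  structure(out, class = c("rr_5y", class(tibble())))
}

#' Population attributable fraction under a mean-shift counterfactual
#'
#' For a log-linear relative risk per unit of exposure and a counterfactual
#' that shifts the population mean to the optimal level (spread unchanged),
#' the PAF is `1 - exp(-log_rr * delta)` with
#' `delta = max(0, mean_current - mean_optimal)`. Under this pure mean shift
#' the exposure distribution cancels in the ratio of expected risks, so the
#' closed form equals the distributional PAF exactly (see the quadrature
#' cross-check in the package tests). Populations already at or below the
#' optimal level contribute zero.
#'
#' @param log_rr Log relative risk per canonical exposure unit (vectorised).
#' @param mean_current Current population mean exposure.
#' @param mean_optimal Optimal (counterfactual) mean exposure.
#' @return Numeric vector of attributable fractions in `[0, 1)` for
#'   non-negative `log_rr`.
#' @export
paf <- function(log_rr, mean_current, mean_optimal) {
  if (any(!is.finite(log_rr))) abort("`log_rr` must be finite.")
  delta <- pmax(0, mean_current - mean_optimal)
  1 - exp(-log_rr * delta)
}

#' Attributable deaths per stratum
#'
#' Joins per-stratum attributable fractions with per-stratum death counts
#' and multiplies; strata present in one input but not the other are a hard
#' error (naming them), because silent dropping would break conservation.
#'
#' @param pafs Tibble with stratum keys and a `paf` column.
#' @param deaths Tibble with the same stratum keys and a `deaths` column
#'   (optionally `population`).
#' @param by Join keys (default: the columns the inputs share, excluding
#'   value columns).
#' @return Tibble with `paf`, `deaths` and `attributable_deaths` per stratum.
#' @export
attributable_deaths <- function(pafs, deaths, by = NULL) {
  if (is.null(by)) {
    by <- setdiff(intersect(names(pafs), names(deaths)),
                  c("paf", "deaths", "population"))
  }
  miss1 <- anti_join(pafs, deaths, by = by)
  miss2 <- anti_join(deaths, pafs, by = by)
  if (nrow(miss1) > 0 || nrow(miss2) > 0) {
    bad <- bind_rows(miss1[by], miss2[by]) %>% distinct()
    abort(paste0("strata not aligned between `pafs` and `deaths`: ",
                 paste(apply(bad, 1, paste, collapse = "/"), collapse = "; ")))
  }
  inner_join(pafs, deaths, by = by) %>%
    mutate(attributable_deaths = .data$paf * .data$deaths)
}

#' Crude attributable death rate per 100,000
#'
#' @param attributable_deaths Attributable death count(s).
#' @param population Adult population (> 0), same length or scalar.
#' @param per Rate scale (default 100,000).
#' @return Numeric rate(s).
#' @export
crude_attrib_rate <- function(attributable_deaths, population, per = 1e5) {
  if (any(population <= 0)) abort("`population` must be > 0.")
  attributable_deaths / population * per
}

#' Premature-to-all-ages mortality ratio
#'
#' The share of attributable deaths occurring prematurely (ages 20-69)
#' among attributable deaths at all adult ages (20+), expressed as a
#' percentage. Given two totals it is `100 * premature / all_ages`; given a
#' table of age-group cells it sums deaths below age 70 and overall first.
#'
#' @param x Premature death total (numeric), or a tibble of cells with an
#'   `age_group` column (labels as in [age_groups_5y()]).
#' @param ... Method arguments.
#' @return Percentage in `[0, 100]` (NA when the all-ages total is zero).
#' @export
premature_ratio <- function(x, ...) UseMethod("premature_ratio")

#' @rdname premature_ratio
#' @param all_ages All-ages death total.
#' @export
premature_ratio.numeric <- function(x, all_ages, ...) {
  ifelse(all_ages == 0, NA_real_, 100 * x / all_ages)
}

#' @rdname premature_ratio
#' @param deaths_col Column holding the death counts (default
#'   `"attributable_deaths"`).
#' @export
premature_ratio.data.frame <- function(x, deaths_col = "attributable_deaths", ...) {
  stopifnot("age_group" %in% names(x), deaths_col %in% names(x))
  grid <- age_groups_5y()
  lo <- grid$age_lo[match(x$age_group, grid$age_group)]
  if (anyNA(lo)) abort("unrecognised `age_group` label(s).")
  total <- sum(x[[deaths_col]])
  premature_ratio(sum(x[[deaths_col]][lo < 70]), total)
}

#' Aggregate country burden cells to sub-regions
#'
#' Sums attributable deaths and populations within each sub-region and
#' recomputes the crude rate from the sums (algebraically identical to the
#' population-weighted mean of country rates). Unmapped countries are a
#' hard error.
#'
#' @param cells Tibble with `country`, `attributable_deaths`, `population`
#'   columns (further grouping columns such as `sex` or `risk_factor` are
#'   preserved).
#' @param map Tibble (`country`, `subregion`) or named character vector.
#' @param per Rate scale.
#' @return Tibble per sub-region (x preserved groups): summed deaths,
#'   population and `rate`.
#' @export
aggregate_subregion <- function(cells, map, per = 1e5) {
  if (is.data.frame(map)) map <- setNames(map$subregion, map$country)
  unmapped <- setdiff(unique(cells$country), names(map))
  if (length(unmapped) > 0) {
    abort(paste0("country(ies) not mapped to a sub-region: ",
                 paste(unmapped, collapse = ", ")))
  }
  extra <- intersect(c("sex", "risk_factor"), names(cells))
  cells %>%
    mutate(subregion = unname(map[.data$country])) %>%
    group_by(across(all_of(c("subregion", extra)))) %>%
    summarise(
      attributable_deaths = sum(.data$attributable_deaths),
      population = sum(.data$population),
      .groups = "drop"
    ) %>%
    mutate(rate = crude_attrib_rate(.data$attributable_deaths, .data$population, per))
}

#' Comparative risk assessment: the full burden chain
#'
#' Joins the 5-year relative-risk surface with country exposure means and
#' mortality, computes the mean-shift PAF per country x sex x age group x
#' risk factor, and multiplies by stratum deaths. The same age-specific RRs
#' are used for both sexes; exposures and deaths remain sex-specific.
#'
#' @param rr5 `rr_5y` tibble (see [interpolate_rr_5y()]) with `risk_factor`.
#' @param exposure Exposure surface: `country`, `sex`, `age_group`,
#'   `risk_factor`, `mean` (canonical units).
#' @param mortality Mortality table: `country`, `sex`, `age_group`,
#'   `deaths`, `population`.
#' @param optimal Optimal levels (`risk_factor`, `optimal`); default
#'   [default_optimal_levels()].
#' @return Tibble of burden cells: keys, `paf`, `deaths`, `population`,
#'   `attributable_deaths`.
#' @export
compute_burden <- function(rr5, exposure, mortality,
                           optimal = default_optimal_levels()) {
  stopifnot(all(c("risk_factor", "age_group", "log_rr") %in% names(rr5)))
  pafs <- exposure %>%
    inner_join(optimal, by = "risk_factor") %>%
    inner_join(rr5 %>% select("risk_factor", "age_group", "log_rr"),
               by = c("risk_factor", "age_group")) %>%
    mutate(paf = paf(.data$log_rr, .data$mean, .data$optimal)) %>%
    select("country", "sex", "age_group", "risk_factor", "paf")
  attributable_deaths(pafs, mortality, by = c("country", "sex", "age_group"))
}

#' Monte Carlo credible intervals for the burden estimates
#'
#' Propagates relative-risk uncertainty through the comparative risk
#' assessment: each 5-year log RR is drawn from Normal(point, se)
#' `n_draws` times, the full PAF -> attributable deaths chain is recomputed
#' per draw, and 2.5th/97.5th percentile intervals are reported for every
#' cell together with country totals (and sub-region totals and
#' premature-to-all-ages ratios when a map is supplied). Deterministic
#' given `seed`.
#'
#' @inheritParams compute_burden
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed.
#' @param level Credible level (default 0.95).
#' @param subregion_map Optional (`country`, `subregion`) tibble.
#' @return List of class `burden_ci`: `cells` (per-cell point and interval),
#'   `country` (totals by country x sex x risk factor), and, when a map is
#'   given, `subregion` (totals, rates, premature ratios with intervals).
#' @export
monte_carlo_ci <- function(rr5, exposure, mortality,
                           optimal = default_optimal_levels(),
                           n_draws = 1000, seed = 1L, level = 0.95,
                           subregion_map = NULL) {
  set.seed(seed)
  point <- compute_burden(rr5, exposure, mortality, optimal)
  key <- point %>%
    inner_join(exposure %>% inner_join(optimal, by = "risk_factor"),
               by = c("country", "sex", "age_group", "risk_factor")) %>%
    mutate(delta = pmax(0, .data$mean - .data$optimal))
  ridx <- match(
    paste(key$risk_factor, key$age_group),
    paste(rr5$risk_factor, rr5$age_group)
  )
  if (anyNA(ridx)) abort("relative-risk surface does not cover every cell.")
  draws <- matrix(rnorm(nrow(rr5) * n_draws, rr5$log_rr, rr5$se),
                  nrow = nrow(rr5), ncol = n_draws)
  # cells x draws matrix of attributable deaths
  ad <- key$deaths * (1 - exp(-draws[ridx, , drop = FALSE] * key$delta))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- t(apply(ad, 1, quantile, probs = probs))
  cells <- key %>%
    select("country", "sex", "age_group", "risk_factor", "paf", "deaths",
           "population", "attributable_deaths") %>%
    mutate(ci_low = qs[, 1], ci_high = qs[, 2])

  grp <- paste(key$country, key$sex, key$risk_factor, sep = "|")
  tot <- rowsum(ad, grp)
  tot_point <- rowsum(key$attributable_deaths, grp)
  tot_qs <- t(apply(tot, 1, quantile, probs = probs))
  ck <- do.call(rbind, strsplit(rownames(tot), "|", fixed = TRUE))
  country <- tibble(
    country = ck[, 1], sex = ck[, 2], risk_factor = ck[, 3],
    attributable_deaths = drop(tot_point),
    ci_low = tot_qs[, 1], ci_high = tot_qs[, 2]
  )
  out <- list(cells = cells, country = country, n_draws = n_draws, seed = seed)

  if (!is.null(subregion_map)) {
    if (is.data.frame(subregion_map)) {
      subregion_map <- setNames(subregion_map$subregion, subregion_map$country)
    }
    grid <- age_groups_5y()
    prem <- grid$age_lo[match(key$age_group, grid$age_group)] < 70
    sr <- unname(subregion_map[key$country])
    if (anyNA(sr)) abort("country(ies) not mapped to a sub-region.")
    sgrp <- paste(sr, key$sex, key$risk_factor, sep = "|")
    sum_ci <- function(mask) {
      m <- rowsum(ad[mask, , drop = FALSE], sgrp[mask])
      p <- rowsum(key$attributable_deaths[mask], sgrp[mask])
      list(mat = m, point = p)
    }
    all_s <- sum_ci(rep(TRUE, nrow(key)))
    prem_s <- sum_ci(prem)
    stopifnot(identical(rownames(all_s$mat), rownames(prem_s$mat)))
    ratio_mat <- 100 * prem_s$mat / all_s$mat
    sk <- do.call(rbind, strsplit(rownames(all_s$mat), "|", fixed = TRUE))
    pop <- rowsum(key$population[!duplicated(paste(key$country, key$sex,
                                                   key$age_group, key$risk_factor))],
                  sgrp[!duplicated(paste(key$country, key$sex, key$age_group,
                                         key$risk_factor))])
    qrow <- function(m) t(apply(m, 1, quantile, probs = probs))
    qa <- qrow(all_s$mat); qp <- qrow(prem_s$mat); qr <- qrow(ratio_mat)
    out$subregion <- tibble(
      subregion = sk[, 1], sex = sk[, 2], risk_factor = sk[, 3],
      attributable_deaths = drop(all_s$point),
      ci_low = qa[, 1], ci_high = qa[, 2],
      premature_deaths = drop(prem_s$point),
      premature_ci_low = qp[, 1], premature_ci_high = qp[, 2],
      premature_ratio = 100 * drop(prem_s$point) / drop(all_s$point),
      ratio_ci_low = qr[, 1], ratio_ci_high = qr[, 2],
      population = drop(pop),
      rate = crude_attrib_rate(drop(all_s$point), drop(pop))
    )
  }
  structure(out, class = "burden_ci")
}

#' @export
print.burden_ci <- function(x, ...) {
  cat("<burden_ci>", nrow(x$cells), "cells,", x$n_draws, "draws\n")
  print(x$country, n = 6)
  invisible(x)
}
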