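test_that("interpolation to 5-year groups honours its fixed points", {
  rr <- tibble::tibble(
    band = band_labels(),
    log_rr = c(0.6, 0.5, 0.4, 0.3, 0.2, 0.1),
    se = c(0.10, 0.09, 0.08, 0.07, 0.06, 0.05)
  )
  rr5 <- interpolate_rr_5y(rr)
  expect_equal(nrow(rr5), 14)
  expect_setequal(rr5$age_group, age_groups_5y()$age_group)
  # the 10-year band anchors (40, 50, ...) sit on the evaluation grid, so
  # evaluating there reproduces the band inputs exactly
  mid <- function(ag) rr5$log_rr[rr5$age_group == ag]
  expect_equal(mid("40-44"), 0.6)
  expect_equal(mid("50-54"), 0.5)
  expect_equal(mid("80-84"), 0.2)
  # bands at 40 and 50 with log RRs 0.6 and 0.4: halfway, at age 45, gives 0.5
  rr2 <- interpolate_rr_5y(tibble::tibble(
    band = c("35-44", "45-54"), log_rr = c(0.6, 0.4), se = 0.1
  ))
  expect_equal(rr2$log_rr[rr2$age_group == "45-49"], 0.5)
  # flat extrapolation outside the outermost anchors (ages below 35 use the
  # youngest band); the open-ended 85+ group is evaluated at age 85, between
  # the 80 and 90 anchors
  expect_equal(mid("20-24"), 0.6)
  expect_equal(mid("35-39"), 0.6)
  expect_equal(mid("85+"), (0.2 + 0.1) / 2)
  # constant input gives a constant surface
  rrc <- interpolate_rr_5y(tibble::tibble(band = band_labels(), log_rr = 0.25, se = 0.02))
  expect_true(all(rrc$log_rr == 0.25))
  expect_true(all(rrc$se == 0.02))
  # single band: constant with a warning
  expect_warning(rr1 <- interpolate_rr_5y(
    tibble::tibble(band = "45-54", log_rr = 0.3, se = 0.1)), "constant")
  expect_true(all(rr1$log_rr == 0.3))
})

test_that("the mean-shift PAF has its closed form and bounds", {
  expect_equal(paf(0.02, 110, 115), 0)
  # exp(log_rr * delta) = 2 forces paf = 0.5
  expect_equal(paf(log(2) / 20, 135, 115), 0.5)
  expect_equal(paf(0.02, 135, 115), 1 - exp(-0.4))
  expect_error(paf(Inf, 1, 0), "finite")
  # bounds and monotonicity on a grid
  lr <- seq(0.001, 0.1, length.out = 20)
  p <- paf(lr, 135, 115)
  expect_true(all(p >= 0 & p < 1))
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(paf(0.02, seq(116, 160, 2), 115)) > 0))
})

test_that("closed-form PAF equals the distributional integral under a mean shift", {
  # normal exposure, log-linear RR: population risk ratio from quadrature
  paf_quadrature <- function(log_rr, mu, sigma, optimal) {
    expected_rr <- function(m) {
      integrate(function(x) exp(log_rr * x) * dnorm(x, m, sigma),
                lower = m - 12 * sigma, upper = m + 12 * sigma,
                rel.tol = 1e-12)$value
    }
    1 - expected_rr(min(optimal, mu)) / expected_rr(mu)
  }
  closed <- paf(0.02, 135, 115)
  expect_lt(abs(closed - paf_quadrature(0.02, 135, 15, 115)), 1e-6)
  # invariant to the (unchanged) spread
  expect_lt(abs(closed - paf_quadrature(0.02, 135, 25, 115)), 1e-6)
})

test_that("attributable deaths multiply and conserve over aggregation", {
  strata <- tidyr::expand_grid(country = c("A", "B"), sex = c("f", "m"),
                               age_group = c("50-54", "70-74"))
  pafs <- strata %>% dplyr::mutate(paf = c(0.5, 0.2, 0.4, 0.1, 0.3, 0.25, 0, 0.6))
  deaths <- strata %>% dplyr::mutate(deaths = c(1000, 500, 800, 200, 600, 300, 100, 900),
                                     population = 1e6)
  cells <- attributable_deaths(pafs, deaths)
  expect_equal(cells$attributable_deaths, cells$paf * cells$deaths)
  expect_equal(cells$attributable_deaths[1], 500)
  # conservation: stratum sum equals deaths-weighted aggregate paf
  total <- sum(cells$attributable_deaths)
  agg_paf <- sum(pafs$paf * deaths$deaths) / sum(deaths$deaths)
  expect_equal(total, agg_paf * sum(deaths$deaths))
  # misaligned strata are a hard error naming the stratum
  expect_error(attributable_deaths(pafs[-1, ], deaths), "A/f/50-54")
})

test_that("crude attributable rates scale as stated", {
  expect_equal(crude_attrib_rate(500, 1e6), 50)
  expect_equal(crude_attrib_rate(0, 1e6), 0)
  expect_equal(crude_attrib_rate(700, 2e6), crude_attrib_rate(7, 2e4))
  expect_error(crude_attrib_rate(10, 0), "population")
})

test_that("premature ratios reproduce published sub-regional arithmetic", {
  expect_equal(premature_ratio(2659, 3299), 80.60, tolerance = 0.005)
  expect_equal(premature_ratio(6072, 13590), 44.68, tolerance = 0.005)
  expect_equal(premature_ratio(5, 5), 100)
  expect_true(is.na(premature_ratio(0, 0)))
  # data-frame method sums below age 70 first
  cells <- tibble::tibble(
    age_group = c("40-44", "65-69", "70-74", "85+"),
    attributable_deaths = c(10, 20, 30, 40)
  )
  expect_equal(premature_ratio(cells), 100 * 30 / 100)
  expect_error(premature_ratio(dplyr::mutate(cells, age_group = "bogus")),
               "age_group")
})

test_that("sub-regional aggregation equals the population-weighted mean rate", {
  cells <- tibble::tibble(
    country = c("A", "B", "C"), sex = "m", risk_factor = "sbp",
    attributable_deaths = c(30, 30, 10), population = c(3e5, 1e5, 1e5)
  )
  map <- tibble::tibble(country = c("A", "B", "C"),
                        subregion = c("r1", "r1", "r2"))
  agg <- aggregate_subregion(cells, map)
  # one-country sub-region: identical to the country rate
  expect_equal(agg$rate[agg$subregion == "r2"], 10 / 1e5 * 1e5)
  # rates 10 and 30 with population 3:1 pool to 15
  expect_equal(agg$rate[agg$subregion == "r1"], 15)
  # rate-from-sums identical to the weighted mean of rates
  w <- cells$population[1:2]
  r <- crude_attrib_rate(cells$attributable_deaths[1:2], w)
  expect_equal(agg$rate[agg$subregion == "r1"], sum(r * w) / sum(w))
  expect_error(aggregate_subregion(cells, map[-3, ]), "C")
})

test_that("the full burden chain conserves totals from cells to sub-regions", {
  set.seed(10)
  surf <- simulate_surfaces(countries = paste0("ct", 1:5), seed = 3)
  rr5 <- interpolate_rr_5y(tibble::tibble(
    risk_factor = "sbp", band = band_labels(),
    log_rr = c(0.04, 0.035, 0.03, 0.02, 0.012, 0.008), se = 0.005
  ))
  cells <- compute_burden(rr5, dplyr::filter(surf$exposure, risk_factor == "sbp"),
                          surf$mortality)
  expect_true(all(cells$paf >= 0 & cells$paf < 1))
  expect_true(all(cells$attributable_deaths <= cells$deaths))
  by_country <- cells %>%
    dplyr::group_by(country) %>%
    dplyr::summarise(d = sum(attributable_deaths))
  expect_equal(sum(by_country$d), sum(cells$attributable_deaths))
  agg <- aggregate_subregion(cells, surf$subregion_map)
  expect_equal(sum(agg$attributable_deaths), sum(cells$attributable_deaths))
})

test_that("Monte Carlo intervals behave: determinism, collapse, widening, coverage", {
  surf <- simulate_surfaces(countries = paste0("ct", 1:4), seed = 5)
  mk_rr5 <- function(se) interpolate_rr_5y(tibble::tibble(
    risk_factor = "sbp", band = band_labels(),
    log_rr = c(0.04, 0.035, 0.03, 0.02, 0.012, 0.008), se = se
  ))
  expo <- dplyr::filter(surf$exposure, risk_factor == "sbp")
  ci1 <- monte_carlo_ci(mk_rr5(0.01), expo, surf$mortality, n_draws = 300,
                        seed = 9, subregion_map = surf$subregion_map)
  ci2 <- monte_carlo_ci(mk_rr5(0.01), expo, surf$mortality, n_draws = 300,
                        seed = 9, subregion_map = surf$subregion_map)
  expect_identical(ci1$cells, ci2$cells)
  expect_identical(ci1$subregion, ci2$subregion)
  # zero SE collapses the interval onto the point estimate
  ci0 <- monte_carlo_ci(mk_rr5(0), expo, surf$mortality, n_draws = 100, seed = 1)
  expect_equal(ci0$cells$ci_low, ci0$cells$attributable_deaths)
  expect_equal(ci0$cells$ci_high, ci0$cells$attributable_deaths)
  # interval width grows with the log-RR SE
  widths <- sapply(c(0.005, 0.01, 0.02), function(s) {
    ci <- monte_carlo_ci(mk_rr5(s), expo, surf$mortality, n_draws = 300, seed = 2)
    mean(ci$country$ci_high - ci$country$ci_low)
  })
  expect_true(all(diff(widths) > 0))
  # every point estimate lies inside its own interval
  expect_true(all(ci1$cells$attributable_deaths >= ci1$cells$ci_low - 1e-9 &
                    ci1$cells$attributable_deaths <= ci1$cells$ci_high + 1e-9))
  expect_true(all(ci1$subregion$premature_ratio >= ci1$subregion$ratio_ci_low - 1e-9 &
                    ci1$subregion$premature_ratio <= ci1$subregion$ratio_ci_high + 1e-9))
})
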