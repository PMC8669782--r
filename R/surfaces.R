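#' Published sub-regional attributable cardiovascular deaths (LAC, 2019)
#'
#' Packaged reference table of cardiovascular deaths attributable to
#' non-optimal BMI, SBP, total cholesterol and non-HDL cholesterol in Latin
#' America and the Caribbean in 2019, by sub-region and sex: the all-ages
#' (20+) and premature (20-69) estimates with 95% credible bounds, and the
#' printed premature-to-all-ages percentage. Used to exercise the reporting
#' arithmetic without access to the underlying cohort or country data.
#'
#' @return Tibble: `region`, `sex`, `risk_factor`, `bound`
#'   (estimate/lower/upper), `deaths_all_ages`, `deaths_premature`,
#'   `printed_ratio_pct`.
#' @export
lac_attributable_deaths_2019 <- function() {
  path <- system.file("extdata", "lac_attributable_cvd_deaths_2019.csv",
                      package = "cmburden", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Simulate a country exposure surface and mortality table
#'
#' Generates a synthetic country x sex x 5-year-age-group exposure surface
#' (mean levels rising modestly with age around realistic adult levels) and
#' a matching mortality/population table with death rates increasing
#' steeply with age, for exercising the comparative risk assessment without
#' external data. Deterministic given `seed`.
#'
#' @param countries Character vector of country names.
#' @param seed Integer seed.
#' @param risk_factors Risk factors to include (default: the four with
#'   burden-stage exposure surfaces; FPG is excluded).
#' @return List with `exposure` (`country`, `sex`, `age_group`,
#'   `risk_factor`, `mean`), `mortality` (`country`, `sex`, `age_group`,
#'   `deaths`, `population`) and a default `subregion_map`.
#' @export
simulate_surfaces <- function(countries = paste0("country_", LETTERS[1:6]),
                              seed = 1L,
                              risk_factors = c("bmi", "sbp", "tc", "nonhdl")) {
  set.seed(seed)
  grid <- age_groups_5y()
  base_mean <- c(bmi = 27, sbp = 128, tc = 5.2, nonhdl = 4.1)
  age_slope <- c(bmi = 0.03, sbp = 0.45, tc = 0.012, nonhdl = 0.010) # per year from age 50
  country_sd <- c(bmi = 1.2, sbp = 5, tc = 0.3, nonhdl = 0.3)
  frame <- tidyr::expand_grid(
    country = countries, sex = c("female", "male"),
    age_group = grid$age_group
  ) %>%
    left_join(grid, by = "age_group")
  exposure <- purrr::map(risk_factors, function(rf) {
    shift <- rnorm(length(countries), 0, country_sd[[rf]])
    names(shift) <- countries
    frame %>%
      mutate(
        risk_factor = rf,
        mean = base_mean[[rf]] + age_slope[[rf]] * (.data$age_ref + 2.5 - 50) +
          shift[.data$country] + ifelse(.data$sex == "male" & rf == "sbp", 3, 0)
      )
  }) %>%
    bind_rows() %>%
    select("country", "sex", "age_group", "risk_factor", "mean")
  mortality <- frame %>%
    distinct(.data$country, .data$sex, .data$age_group, .data$age_ref) %>%
    mutate(
      population = round(runif(n(), 5e4, 5e5)),
      # CVD death rate roughly doubling every 7 years of age
      deaths = round(.data$population * 2e-4 * 2^((.data$age_ref + 2.5 - 40) / 7) *
                       ifelse(.data$sex == "male", 1.3, 1))
    ) %>%
    select("country", "sex", "age_group", "deaths", "population")
  n_half <- ceiling(length(countries) / 2)
  list(
    exposure = exposure,
    mortality = mortality,
    subregion_map = tibble(
      country = countries,
      subregion = rep(c("subregion_1", "subregion_2"),
                      c(n_half, length(countries) - n_half))
    )
  )
}
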