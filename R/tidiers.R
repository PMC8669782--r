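#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a band-level Poisson random-intercept fit
#'
#' @param x A `band_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per fixed-effect term: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`.
#' @method tidy band_fit
#' @export
tidy.band_fit <- function(x, ...) x$coefficients

#' One-row summary of a band-level fit
#'
#' @param x A `band_fit` object.
#' @param ... Unused.
#' @return Tibble: band, events, cohorts, observations, cohort-intercept SD,
#'   log-likelihood, AIC, convergence flag.
#' @method glance band_fit
#' @export
glance.band_fit <- function(x, ...) {
  tibble(
    band = x$band, risk_factor = x$risk_factor,
    n_events = x$n_events, n_cohorts = x$n_cohorts, nobs = x$nobs,
    sigma_u = x$sigma_u,
    logLik = as.numeric(logLik(x$fit)), AIC = AIC(x$fit),
    converged = x$converged
  )
}

#' Forest-style plot of age-specific relative risks
#'
#' @param object An `rr_table` (see [assemble_rrs()]).
#' @param ... Unused.
#' @return A ggplot: RR with confidence interval by age band, faceted by
#'   risk factor (and stratum when present), log-scaled y axis with a
#'   reference line at RR = 1.
#' @method autoplot rr_table
#' @export
autoplot.rr_table <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$band, y = .data$rr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Attained-age band (years)",
                  y = paste0("Relative risk per ", unique(object$increment),
                             " unit(s)")) +
    ggplot2::theme_minimal()
  facets <- intersect(c("risk_factor", "stratum"), names(object))
  facets <- facets[vapply(facets, function(f) any(!is.na(object[[f]])), logical(1))]
  if (length(facets) > 0) {
    p <- p + ggplot2::facet_wrap(stats::reformulate(facets), scales = "free_y")
  }
  p
}

#' Interpolated 5-year relative-risk surface plot
#'
#' @param object An `rr_5y` tibble (see [interpolate_rr_5y()]).
#' @param ... Unused.
#' @return A ggplot of log RR (with +-1.96 se ribbon) against age-group
#'   reference age, faceted by risk factor.
#' @method autoplot rr_5y
#' @export
autoplot.rr_5y <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age_ref, y = .data$log_rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$log_rr - 1.96 * .data$se,
                                      ymax = .data$log_rr + 1.96 * .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~risk_factor, scales = "free_y") +
    ggplot2::labs(x = "Age (5-year group reference age)",
                  y = "log relative risk per unit") +
    ggplot2::theme_minimal()
}

#' Bar chart of crude attributable death rates
#'
#' @param data Tibble with `rate` and a `country` or `subregion` column
#'   (e.g. from [aggregate_subregion()]), optionally `sex` / `risk_factor`.
#' @return A ggplot of rates per 100,000 by geography, dodged by sex when
#'   present and faceted by risk factor when present.
#' @export
plot_attrib_rates <- function(data) {
  geo <- if ("subregion" %in% names(data)) "subregion" else "country"
  aes <- ggplot2::aes(x = .data[[geo]], y = .data$rate)
  if ("sex" %in% names(data)) aes$fill <- rlang::quo(.data$sex)
  p <- ggplot2::ggplot(data, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Attributable deaths per 100,000") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("risk_factor" %in% names(data)) p <- p + ggplot2::facet_wrap(~risk_factor)
  p
}
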