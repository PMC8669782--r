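# unit conversions to canonical units, keyed by (risk_factor, unit).
# cholesterol mg/dL -> mmol/L divides by 38.67; glucose by 18.016.
unit_conversion <- function(risk_factor, unit) {
  key <- paste(risk_factor, unit, sep = "|")
  table <- c(
    "bmi|kg/m2" = 1,
    "sbp|mmHg" = 1,
    "fpg|mmol/L" = 1, "fpg|mg/dL" = 1 / 18.016,
    "tc|mmol/L" = 1, "tc|mg/dL" = 1 / 38.67,
    "nonhdl|mmol/L" = 1, "nonhdl|mg/dL" = 1 / 38.67
  )
  out <- table[key]
  if (anyNA(out)) {
    bad <- key[is.na(out)]
    abort(paste0("unknown unit for column(s): ", paste(bad, collapse = ", ")))
  }
  unname(out)
}

#' Pool participant tables from several cohort sources
#'
#' Harmonises a collection of participant tables into one pooled dataset:
#' exposures are converted to canonical units (kg/m2, mmHg, mmol/L), cohort
#' and participant identifiers are made globally unique by prefixing the
#' source name, and rows violating basic eligibility invariants (baseline age
#' below 20, non-positive follow-up) are dropped and counted.
#'
#' @param tables A named list of participant data frames (or a single data
#'   frame). Expected columns: `participant_id`, `cohort`, `sex`,
#'   `age_baseline`, `followup_time`, `event_fatal`, `event_nonfatal`, plus
#'   any of the exposure columns `bmi`, `sbp`, `fpg`, `tc`, `nonhdl`.
#' @param units Optional named list: for each table, a named character vector
#'   mapping exposure column names to their unit labels. Columns not listed
#'   are assumed canonical.
#' @return Pooled tibble; attributes `n_dropped` (rows failing invariants)
#'   and `dropped` (a per-reason count tibble).
#' @export
pool_cohorts <- function(tables, units = NULL) {
  if (is.data.frame(tables)) tables <- list(pooled = tables)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("src", seq_along(tables))
  }
  pooled <- purrr::imap(tables, function(tab, nm) {
    tab <- as_tibble(tab)
    u <- units[[nm]]
    if (!is.null(u)) {
      for (col in names(u)) {
        if (!col %in% names(tab)) abort(paste0("unit declared for absent column `", col, "`"))
        tab[[col]] <- tab[[col]] * unit_conversion(col, u[[col]])
      }
    }
    tab$cohort <- paste(nm, tab$cohort, sep = ".")
    tab$participant_id <- paste(nm, tab$participant_id, sep = ".")
    tab
  }) %>%
    bind_rows()
  bad_age <- !is.na(pooled$age_baseline) & pooled$age_baseline < 20
  bad_fu <- is.na(pooled$followup_time) | pooled$followup_time <= 0
  drop <- bad_age | bad_fu | is.na(pooled$age_baseline)
  if (any(drop)) {
    rlang::inform(paste0("pool_cohorts: dropped ", sum(drop),
                         " row(s) failing eligibility invariants."))
  }
  out <- pooled[!drop, , drop = FALSE]
  attr(out, "n_dropped") <- sum(drop)
  attr(out, "dropped") <- tibble(
    reason = c("age_baseline < 20", "followup_time <= 0"),
    n = c(sum(bad_age, na.rm = TRUE), sum(bad_fu, na.rm = TRUE))
  )
  out
}

#' Lexis expansion of follow-up into attained-age bands
#'
#' Splits each participant's follow-up into person-time segments by the
#' attained-age bands used for age-specific modelling. Person-time before age
#' 35 is discarded; each band crossed during follow-up yields one segment
#' carrying its exact (fractional-year) person-time; the event, if any, is
#' attributed to the segment containing the exit age (the last segment with
#' positive person-time when the exit falls exactly on a band edge).
#' `age_at_risk` is the midpoint of the occupied sub-interval of the band.
#' Exposure and identifier columns are carried onto the segments.
#'
#' @param data Participant tibble (see [pool_cohorts()] for the schema).
#' @param bands Lower band edges in years (default [age_bands()]).
#' @param outcome `"fatal"` (fatal events only; full follow-up) or
#'   `"combined"` (fatal or non-fatal, follow-up as recorded, which is
#'   truncated at the first event by construction upstream).
#' @return Segment tibble: identifiers, sex, `band`, `entry_age`, `exit_age`,
#'   `person_time`, `events`, `age_at_risk`, plus any exposure columns.
#' @export
lexis_expand <- function(data, bands = age_bands(), outcome = c("fatal", "combined")) {
  outcome <- match.arg(outcome)
  if (any(data$followup_time <= 0, na.rm = TRUE)) abort("`followup_time` must be > 0.")
  ev <- if (outcome == "fatal") data$event_fatal else {
    pmax(data$event_fatal, data$event_nonfatal)
  }
  brk <- c(bands, Inf)
  J <- length(bands)
  entry <- data$age_baseline
  exit <- data$age_baseline + data$followup_time
  keep_cols <- intersect(
    c("participant_id", "cohort", "sex", RISK_FACTORS), names(data)
  )
  segs <- purrr::map(seq_len(J), function(j) {
    lo <- pmax(entry, brk[j])
    hi <- pmin(exit, brk[j + 1])
    pt <- hi - lo
    sel <- which(pt > 0)
    if (length(sel) == 0) return(NULL)
    tibble(
      row = sel, band = band_labels(bands)[j],
      entry_age = lo[sel], exit_age = hi[sel], person_time = pt[sel]
    )
  }) %>% bind_rows()
  if (nrow(segs) == 0) {
    return(tibble(
      participant_id = character(), cohort = character(), sex = character(),
      band = character(), entry_age = double(), exit_age = double(),
      person_time = double(), events = integer(), age_at_risk = double()
    ))
  }
  # event goes to the band containing the exit age; if the exit falls exactly
  # on a band edge the occupied interval there is empty, so step one band down
  j_ev <- findInterval(exit, brk)
  on_edge <- exit == brk[pmax(j_ev, 1)]
  j_ev[on_edge] <- j_ev[on_edge] - 1L
  segs$events <- as.integer(
    ev[segs$row] == 1 & segs$band == band_labels(bands)[pmin(pmax(j_ev[segs$row], 1L), J)]
  )
  segs$events[is.na(segs$events)] <- 0L
  segs$age_at_risk <- (segs$entry_age + segs$exit_age) / 2
  out <- bind_cols(data[segs$row, keep_cols, drop = FALSE],
                   segs[setdiff(names(segs), "row")])
  out %>% arrange(.data$participant_id, .data$entry_age)
}

#' Crude event rate per 100,000 person-years with exact Poisson CI
#'
#' Rate = events / person-years x 100,000, with the exact (Garwood)
#' chi-square interval on the Poisson count scaled by person-years.
#'
#' @param events Event count (non-negative integer).
#' @param person_years Person-years at risk (> 0).
#' @param level Confidence level (default 0.95).
#' @param per Scale of the reported rate (default 100,000).
#' @return One-row tibble: `events`, `person_years`, `rate`, `ci_low`,
#'   `ci_high`.
#' @export
crude_rate <- function(events, person_years, level = 0.95, per = 1e5) {
  if (person_years <= 0) abort("`person_years` must be > 0.")
  if (events < 0) abort("`events` must be non-negative.")
  a <- (1 - level) / 2
  lo <- if (events == 0) 0 else qchisq(a, 2 * events) / 2
  hi <- qchisq(1 - a, 2 * events + 2) / 2
  tibble(
    events = events, person_years = person_years,
    rate = events / person_years * per,
    ci_low = lo / person_years * per,
    ci_high = hi / person_years * per
  )
}
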