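PIPELINE_STAGES <- c("simulate", "pool", "impute", "dilute", "fit", "burden", "report")

#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end run: the synthetic-cohort
#' configuration, imputation settings, dilution grouping, modelling options,
#' display increments, burden-stage inputs and the master seed (every
#' stochastic stage derives its stream from it by a fixed offset).
#'
#' @param out_dir Output directory for persisted stage artifacts.
#' @param seed Master integer seed.
#' @param sim A [sim_config()]; defaults to one derived from `seed`.
#' @param risk_factors Risk factors to model.
#' @param outcome `"fatal"` or `"combined"` (see [lexis_expand()]).
#' @param m Number of imputations.
#' @param maxit Chained-equation cycles.
#' @param complete_case Use the complete-case sensitivity mode instead of
#'   multiple imputation.
#' @param n_groups Quantile groups for the MacMahon estimator.
#' @param increments Named display increments per risk factor (canonical
#'   units; default 1 unit each).
#' @param optimal_levels Counterfactual means (see
#'   [default_optimal_levels()]).
#' @param n_draws Monte Carlo draws for credible intervals.
#' @param nAGQ Quadrature points for the band models.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = NULL,
                            risk_factors = c("bmi", "sbp"),
                            outcome = c("fatal", "combined"),
                            m = 5, maxit = 5, complete_case = FALSE,
                            n_groups = 5,
                            increments = NULL,
                            optimal_levels = default_optimal_levels(),
                            n_draws = 200, nAGQ = 1) {
  outcome <- match.arg(outcome)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  if (is.null(increments)) increments <- setNames(rep(1, length(risk_factors)), risk_factors)
  if (!all(risk_factors %in% names(increments))) {
    abort("`increments` must be named for every modelled risk factor.")
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
         risk_factors = risk_factors, outcome = outcome, m = m, maxit = maxit,
         complete_case = complete_case, n_groups = n_groups,
         increments = increments, optimal_levels = optimal_levels,
         n_draws = n_draws, nAGQ = nAGQ),
    class = "pipeline_config"
  )
}

read_stage_csv <- function(path, stage) {
  if (!file.exists(path)) {
    abort(paste0("stage `", stage, "` needs `", path,
                 "`; run the earlier stages first."))
  }
  readr::read_csv(path, show_col_types = FALSE)
}

#' Run the pooled-cohort burden pipeline
#'
#' Executes the stage chain simulate -> pool -> impute -> dilute -> fit ->
#' burden -> report. Each stage persists its outputs under
#' `config$out_dir/<stage>/` and later stages can be re-run from those
#' intermediates by passing a subset of `stages`. A machine-readable run
#' manifest (seed, package version, per-file MD5 hashes) is written at the
#' end; re-running with an unchanged configuration reproduces byte-identical
#' outputs. A stage failure halts the run with the failing stage named;
#' completed stage outputs are retained.
#'
#' @param config A [pipeline_config()].
#' @param stages Which stages to run (in pipeline order).
#' @return Invisibly, a list with the in-memory artifacts of the stages run.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  out <- list()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(config$out_dir, ...)
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)))
    })
    message(sprintf("stage %-8s done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  if ("simulate" %in% stages) {
    out$sim <- run_stage("simulate", function() {
      sim <- simulate_cohorts(config$sim)
      write_cohorts(sim, pth("simulate"))
      sim
    })
  }

  if ("pool" %in% stages) {
    out$pooled <- run_stage("pool", function() {
      participants <- if (!is.null(out$sim)) out$sim$participants else {
        read_stage_csv(pth("simulate", "participants.csv"), "pool")
      }
      pooled <- pool_cohorts(list(sim = participants))
      dir.create(pth("pool"), showWarnings = FALSE)
      readr::write_csv(pooled, pth("pool", "pooled.csv"))
      pooled
    })
  }

  if ("impute" %in% stages) {
    out$stack <- run_stage("impute", function() {
      pooled <- if (!is.null(out$pooled)) out$pooled else {
        read_stage_csv(pth("pool", "pooled.csv"), "impute")
      }
      dir.create(pth("impute"), showWarnings = FALSE)
      if (config$complete_case) {
        cc <- complete_cases(pooled, intersect(config$risk_factors, names(pooled)))
        readr::write_csv(cc, pth("impute", "complete_case.csv"))
        structure(list(data = list(cc), m = 1L, seed = config$seed,
                       imputed_vars = character()),
                  class = "imputation_stack")
      } else {
        stack <- mi_impute(pooled, m = config$m, seed = config$seed + 10L,
                           maxit = config$maxit)
        purrr::iwalk(stack$data, function(d, i) {
          readr::write_csv(d, pth("impute", sprintf("imputed_%02d.csv", i)))
        })
        yaml::write_yaml(list(m = stack$m, seed = stack$seed,
                              imputed_vars = stack$imputed_vars),
                         pth("impute", "manifest.yaml"))
        stack
      }
    })
  }

  if ("dilute" %in% stages) {
    out$correction <- run_stage("dilute", function() {
      cf <- if (!is.null(out$sim)) {
        est <- estimate_correction_factors(out$sim, config$risk_factors,
                                           n_groups = config$n_groups)
        missing_rf <- setdiff(config$risk_factors, est$risk_factor)
        if (length(missing_rf) > 0) {
          est <- bind_rows(est, default_correction_factors() %>%
                             filter(.data$risk_factor %in% missing_rf))
        }
        est
      } else {
        default_correction_factors() %>%
          filter(.data$risk_factor %in% config$risk_factors)
      }
      dir.create(pth("dilute"), showWarnings = FALSE)
      readr::write_csv(cf, pth("dilute", "correction_factors.csv"))
      cf
    })
  }

  if ("fit" %in% stages) {
    out$rr <- run_stage("fit", function() {
      stack <- out$stack
      if (is.null(stack)) abort("run the `impute` stage in the same call before `fit`.")
      correction <- if (!is.null(out$correction)) out$correction else {
        read_stage_csv(pth("dilute", "correction_factors.csv"), "fit")
      }
      rr <- purrr::map(config$risk_factors, function(rf) {
        fits <- purrr::imap(stack$data, function(d, i) {
          seg <- lexis_expand(d, outcome = config$outcome)
          fit_age_band_models(seg, rf, nAGQ = config$nAGQ) %>%
            mutate(imputation = i)
        }) %>% bind_rows()
        fac <- correction$factor[match(rf, correction$risk_factor)]
        assemble_rrs(fits, correction = fac,
                     increment = config$increments[[rf]], risk_factor = rf)
      }) %>% bind_rows() %>%
        structure(class = c("rr_table", class(tibble())))
      dir.create(pth("fit"), showWarnings = FALSE)
      readr::write_csv(rr, pth("fit", "rr_table.csv"))
      rr
    })
  }

  if ("burden" %in% stages) {
    out$burden <- run_stage("burden", function() {
      rr <- if (!is.null(out$rr)) out$rr else {
        read_stage_csv(pth("fit", "rr_table.csv"), "burden")
      }
      surf <- simulate_surfaces(seed = config$seed + 20L)
      rf_avail <- intersect(unique(rr$risk_factor),
                            config$optimal_levels$risk_factor)
      rr5 <- interpolate_rr_5y(rr %>% filter(.data$risk_factor %in% rf_avail))
      exposure <- surf$exposure %>% filter(.data$risk_factor %in% rf_avail)
      ci <- monte_carlo_ci(rr5, exposure, surf$mortality,
                           optimal = config$optimal_levels,
                           n_draws = config$n_draws, seed = config$seed + 30L,
                           subregion_map = surf$subregion_map)
      dir.create(pth("burden"), showWarnings = FALSE)
      readr::write_csv(rr5, pth("burden", "rr_5y.csv"))
      readr::write_csv(ci$cells, pth("burden", "burden_cells.csv"))
      readr::write_csv(ci$country, pth("burden", "country_totals.csv"))
      readr::write_csv(ci$subregion, pth("burden", "subregion_summary.csv"))
      ci
    })
  }

  if ("report" %in% stages) {
    out$manifest <- run_stage("report", function() {
      files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
      files <- files[basename(files) != "manifest.json"]
      manifest <- list(
        package_version = as.character(utils::packageVersion("cmburden")),
        seed = config$seed,
        risk_factors = config$risk_factors,
        outcome = config$outcome,
        m = if (config$complete_case) 1L else config$m,
        complete_case = config$complete_case,
        files = as.list(setNames(unname(tools::md5sum(files)),
                                 sub(paste0("^", config$out_dir, "/?"), "", files)))
      )
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      manifest
    })
  }

  invisible(out)
}
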