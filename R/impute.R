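# Bayesian linear-model draw for one chained-equation step: posterior draws of
# (sigma^2, beta) under the standard noninformative prior, plus least-squares
# predictions for predictive mean matching. Rank-deficient designs are reduced
# to their pivoted full-rank column set.
bayes_lm_draw <- function(X, y) {
  qrx <- qr(X)
  piv <- qrx$pivot[seq_len(qrx$rank)]
  Xr <- X[, piv, drop = FALSE]
  xtx <- crossprod(Xr)
  Rc <- tryCatch(chol(xtx), error = function(e) chol(xtx + diag(1e-8, ncol(xtx))))
  betahat <- backsolve(Rc, forwardsolve(t(Rc), crossprod(Xr, y)))
  res <- y - Xr %*% betahat
  df <- max(nrow(Xr) - length(piv), 1)
  sigma2_star <- sum(res^2) / rchisq(1, df)
  beta_star <- betahat + backsolve(Rc, rnorm(length(piv))) * sqrt(sigma2_star)
  list(piv = piv, betahat = betahat, beta_star = beta_star)
}

# predictive mean matching: for each missing prediction, pick one of the k
# observed donors whose least-squares prediction is nearest, and impute the
# donor's observed value
match_pmm <- function(yhat_mis, yhat_obs, y_obs, k = 5) {
  o <- order(yhat_obs)
  ys <- yhat_obs[o]
  yo <- y_obs[o]
  n <- length(ys)
  k <- min(k, n)
  pos <- findInterval(yhat_mis, ys)
  offs <- seq(-k, k - 1L)
  cand <- pmin(pmax(outer(pos, offs, "+") + 1L, 1L), n)
  d <- abs(matrix(ys[cand], nrow = length(yhat_mis)) - yhat_mis)
  pick <- vapply(seq_len(nrow(d)), function(i) {
    nearest <- order(d[i, ])[seq_len(k)]
    cand[i, nearest[sample.int(k, 1)]]
  }, integer(1))
  yo[pick]
}

# design matrix of fully-observed predictors for the chained equations:
# intercept, sex, baseline age, log follow-up, event indicator, cohort dummies
base_design <- function(data) {
  ev <- pmax(data$event_fatal, data$event_nonfatal)
  X <- cbind(
    `(Intercept)` = 1,
    sex_male = as.numeric(data$sex == "male"),
    age_baseline = data$age_baseline,
    log_followup = log(data$followup_time),
    event = ev
  )
  if (length(unique(data$cohort)) > 1) {
    cm <- model.matrix(~ factor(cohort), data = data)[, -1, drop = FALSE]
    X <- cbind(X, cm)
  }
  X
}

#' Multiple imputation of missing exposures by chained equations
#'
#' Imputes missing exposure values with a fully-conditional-specification
#' (chained equations) scheme: each incomplete exposure is regressed on all
#' other exposures, sex, baseline age, cohort indicators, the event indicator
#' and log follow-up time; continuous draws use predictive mean matching
#' (default 5 donors) with Bayesian parameter draws, cycled a fixed number of
#' times per imputation. Deterministic given `seed`. Exposures missing for
#' every record cannot be imputed and are excluded with a warning.
#'
#' @param data Pooled participant tibble (see [pool_cohorts()]).
#' @param m Number of imputed datasets (default 50).
#' @param seed Integer seed.
#' @param maxit Chained-equation cycles per imputation (default 10).
#' @param k Number of predictive-mean-matching donors (default 5).
#' @param vars Exposure columns to impute (default: canonical risk factors
#'   present in `data`).
#' @return An object of class `imputation_stack`: list with `data` (list of
#'   `m` completed tibbles), `m`, `seed`, and `imputed_vars`.
#' @export
mi_impute <- function(data, m = 50, seed = 1L, maxit = 10, k = 5,
                      vars = intersect(RISK_FACTORS, names(data))) {
  if (m < 1) abort("`m` must be >= 1.")
  stopifnot(all(c("sex", "age_baseline", "followup_time",
                  "event_fatal", "event_nonfatal", "cohort") %in% names(data)))
  data <- as_tibble(data)
  all_missing <- vars[vapply(vars, function(v) all(is.na(data[[v]])), logical(1))]
  if (length(all_missing) > 0) {
    warn(paste0("mi_impute: variable(s) entirely unobserved, excluded from imputation: ",
                paste(all_missing, collapse = ", ")))
    vars <- setdiff(vars, all_missing)
  }
  incomplete <- vars[vapply(vars, function(v) anyNA(data[[v]]), logical(1))]
  miss_idx <- lapply(incomplete, function(v) which(is.na(data[[v]])))
  names(miss_idx) <- incomplete
  set.seed(seed)
  Xbase <- base_design(data)
  completed <- vector("list", m)
  for (im in seq_len(m)) {
    d <- data
    # initial fill: random draws from each variable's observed values
    for (v in incomplete) {
      obs <- d[[v]][!is.na(d[[v]])]
      d[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]), replace = TRUE)
    }
    if (length(incomplete) > 0) {
      for (it in seq_len(maxit)) {
        for (v in incomplete) {
          others <- setdiff(vars, v)
          X <- cbind(Xbase, as.matrix(d[others]))
          mis <- miss_idx[[v]]
          obs <- setdiff(seq_len(nrow(d)), mis)
          y_obs <- data[[v]][obs]
          draw <- bayes_lm_draw(X[obs, , drop = FALSE], y_obs)
          yhat_obs <- drop(X[obs, draw$piv, drop = FALSE] %*% draw$betahat)
          yhat_mis <- drop(X[mis, draw$piv, drop = FALSE] %*% draw$beta_star)
          d[[v]][mis] <- match_pmm(yhat_mis, yhat_obs, y_obs, k)
        }
      }
    }
    completed[[im]] <- d
  }
  structure(
    list(data = completed, m = m, seed = seed, imputed_vars = incomplete,
         excluded_vars = all_missing),
    class = "imputation_stack"
  )
}

#' @export
print.imputation_stack <- function(x, ...) {
  cat("<imputation_stack> m =", x$m, "| imputed:",
      if (length(x$imputed_vars)) paste(x$imputed_vars, collapse = ", ") else "(nothing)",
      "\n")
  invisible(x)
}

#' Apply a function to every imputed dataset
#'
#' @param stack An `imputation_stack`.
#' @param fn Function taking a completed tibble (first argument).
#' @param ... Passed to `fn`.
#' @return List of `m` results.
#' @export
with_imputations <- function(stack, fn, ...) {
  if (!inherits(stack, "imputation_stack")) abort("`stack` must be an `imputation_stack`.")
  purrr::map(stack$data, fn, ...)
}

#' Restrict to complete cases (sensitivity mode)
#'
#' Drops rows with any missing value among the given exposures; the
#' complete-case counterpart of multiple imputation.
#'
#' @param data Participant tibble.
#' @param vars Exposure columns (default: canonical risk factors present).
#' @return Filtered tibble.
#' @export
complete_cases <- function(data, vars = intersect(RISK_FACTORS, names(data))) {
  keep <- !Reduce(`|`, lapply(vars, function(v) is.na(data[[v]])))
  data[keep, , drop = FALSE]
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines `m` per-imputation point estimates and squared standard errors:
#' the pooled point is the mean estimate; total variance is the mean
#' within-imputation variance plus `(1 + 1/m)` times the between-imputation
#' variance; degrees of freedom follow the standard formula
#' `(m - 1) * (1 + within / ((1 + 1/m) * between))^2` (infinite when the
#' between-imputation variance is zero).
#'
#' @param estimates Numeric vector of `m` point estimates (`m >= 2`).
#' @param variances Numeric vector of `m` squared standard errors.
#' @return One-row tibble: `m`, `point`, `within_var`, `between_var`,
#'   `total_var`, `se`, `df`.
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) abort("Rubin's rules need m >= 2 estimates.")
  if (length(variances) != m) abort("`estimates` and `variances` must have equal length.")
  point <- mean(estimates)
  within <- mean(variances)
  between <- var(estimates)
  total <- within + (1 + 1 / m) * between
  df <- if (between == 0) Inf else (m - 1) * (1 + within / ((1 + 1 / m) * between))^2
  tibble(
    m = m, point = point, within_var = within, between_var = between,
    total_var = total, se = sqrt(total), df = df
  )
}
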