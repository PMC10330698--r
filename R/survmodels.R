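#' Read survival records from CSV
#'
#' Expected columns: `subject_id`, `time` (positive, months), `event`
#' (1 = event, 0 = censored), plus any covariate columns.
#'
#' @param path Path to the CSV file.
#' @return A validated survival data frame.
#' @export
read_survival <- function(path) {
  validate_survival(utils::read.csv(path, stringsAsFactors = FALSE))
}

validate_survival <- function(records) {
  miss <- setdiff(c("time", "event"), names(records))
  if (length(miss)) abort("survival table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (any(!is.finite(records$time) | records$time <= 0)) {
    abort("survival times must be positive")
  }
  if (!all(records$event %in% c(0, 1))) {
    abort("event indicator must be 0 (censored) or 1 (event)")
  }
  records
}

#' Kaplan-Meier product-limit curve
#'
#' @param records Data frame with `time` and `event` columns.
#' @return An object of class `km_curve`: data frame with `time`,
#'   `at_risk`, `events`, `survival` (non-increasing, starting below 1 only
#'   after the first event).
#' @export
km_fit <- function(records) {
  records <- validate_survival(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  structure(data.frame(time = fit$time, at_risk = fit$n.risk,
                       events = fit$n.event, survival = fit$surv),
            class = c("km_curve", "data.frame"))
}

#' Median survival time from a Kaplan-Meier curve
#'
#' First time at which the survival estimate drops to 0.5 or below; `NA`
#' when the curve never reaches 0.5.
#'
#' @param curve A `km_curve`.
#' @return A single time (or `NA`).
#' @export
km_median <- function(curve) {
  i <- which(curve$survival <= 0.5)
  if (!length(i)) return(NA_real_)
  curve$time[min(i)]
}

#' Log-rank test between survival groups
#'
#' Standard (unweighted) log-rank test: per-group observed minus expected
#' events summed over event times, chi-square with (k - 1) degrees of
#' freedom, hypergeometric variance under ties.
#'
#' @param records Data frame with `time` and `event` columns.
#' @param groups Per-record group labels (>= 2 groups).
#' @return List with `chisq`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(records, groups) {
  records <- validate_survival(records)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) abort("log-rank test needs >= 2 groups")
  if (sum(records$event) == 0) abort("log-rank test needs >= 1 event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = cbind(records, g = groups))
  df <- nlevels(groups) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n_groups = nlevels(groups))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood (Efron tie correction by default) and
#' reports per-covariate hazard ratios with Wald tests and 95% confidence
#' intervals.
#'
#' @param records Data frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` or `"breslow"`.
#' @return An object of class `cox_fit`: data frame with one row per
#'   covariate (`term`, `beta`, `hr`, `se`, `z`, `p`, `ci_low`, `ci_high`)
#'   and attributes `converged` and `n_events`.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  records <- validate_survival(records)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) abort("missing covariate column(s): %s",
                          paste(miss, collapse = ", "))
  if (sum(records$event) < 1) abort("Cox fit needs >= 1 event")
  const <- covariates[vapply(records[covariates],
                             function(x) length(unique(x)) < 2, logical(1))]
  if (length(const)) abort("constant covariate(s): %s",
                           paste(const, collapse = ", "))
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(sprintf("`%s`", covariates),
                                        collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(form, data = records, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|out of iterations", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  if (any(abs(beta) > 20)) {
    abort(paste("apparent complete separation (|beta| > 20 for %s);",
                "consider a penalized fit"),
          paste(names(beta)[abs(beta) > 20], collapse = ", "))
  }
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  out <- data.frame(term = covariates, beta = unname(beta),
                    hr = exp(unname(beta)), se = unname(se), z = unname(z),
                    p = 2 * stats::pnorm(-abs(unname(z))),
                    ci_low = exp(unname(beta) - 1.96 * unname(se)),
                    ci_high = exp(unname(beta) + 1.96 * unname(se)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("cox_fit", "data.frame"),
            converged = converged, n_events = sum(records$event),
            ties = ties)
}

#' Median split into high and low strata
#'
#' `"high"` means at or above the median; the median for even sample sizes
#' is the midpoint of the two central order statistics.
#'
#' @param values Numeric vector (>= 2 values).
#' @return Character vector of `"high"` / `"low"` labels.
#' @export
median_stratify <- function(values) {
  if (length(values) < 2) abort("median stratification needs >= 2 subjects")
  if (any(!is.finite(values))) abort("values must be finite")
  m <- stats::median(values)
  labels <- ifelse(values >= m, "high", "low")
  if (all(labels == "high")) {
    warnf("all values identical: degenerate stratification (all 'high')")
  }
  labels
}

#' Joint median stratification by two features with an interaction model
#'
#' Median-splits each feature, forms the four high/low strata, tests the
#' (non-empty) strata with the log-rank test, and fits a Cox model with the
#' two high/low indicators and their product to estimate main-effect and
#' interaction hazard ratios.
#'
#' @param records Data frame with `time` and `event` columns.
#' @param feature1,feature2 Per-record numeric features.
#' @return List with `strata` (per-record labels `"high/high"` etc.),
#'   `logrank` (over the non-empty strata), `cox` (the indicator +
#'   interaction fit, or `NULL` when an indicator is constant) and
#'   `interaction_hr`.
#' @export
joint_strata_analysis <- function(records, feature1, feature2) {
  records <- validate_survival(records)
  if (length(feature1) != nrow(records) || length(feature2) != nrow(records)) {
    abort("features must have one value per record")
  }
  s1 <- median_stratify(feature1)
  s2 <- median_stratify(feature2)
  strata <- paste(s1, s2, sep = "/")
  present <- unique(strata)
  if (length(present) < 4) {
    warnf("only %d of 4 strata are non-empty; log-rank computed over these",
          length(present))
  }
  lr <- logrank_test(records, strata)
  cox <- NULL
  interaction_hr <- NA_real_
  x1 <- as.integer(s1 == "high")
  x2 <- as.integer(s2 == "high")
  if (length(unique(x1)) < 2 || length(unique(x2)) < 2 ||
      length(unique(x1 * x2)) < 2 ||
      qr(cbind(1, x1, x2, x1 * x2))$rank < 4) {
    warnf("an indicator is constant or collinear; interaction fit skipped")
  } else {
    dd <- cbind(records[c("time", "event")],
                feature1_high = x1, feature2_high = x2,
                interaction = x1 * x2)
    cox <- cox_fit(dd, c("feature1_high", "feature2_high", "interaction"))
    interaction_hr <- cox$hr[cox$term == "interaction"]
  }
  list(strata = strata, logrank = lr, cox = cox,
       interaction_hr = interaction_hr)
}

#' Write a Cox fit (or any term table) to TSV
#' @param fit A `cox_fit`.
#' @param path Output path.
#' @export
write_cox_fit <- function(fit, path) {
  utils::write.table(as.data.frame(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (%s ties, %d events%s)\n", attr(x, "ties"),
              attr(x, "n_events"),
              if (attr(x, "converged")) "" else ", NOT converged"))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}
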