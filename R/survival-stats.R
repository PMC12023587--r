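## Survival layer: Kaplan-Meier estimation with Greenwood/log-log bands,
## k-group log-rank comparison and Cox proportional-hazards regression.
## Model fitting is delegated to the survival package; this module fixes the
## package's conventions (months, 120-month horizon, Efron ties, CNL
## reference) and the derived summaries reported for each group.

#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator with Greenwood variance and log-log 95% pointwise
#' confidence bands (the bands are undefined while the estimate is still 1).
#'
#' @param times follow-up times in months (>= 0).
#' @param events event indicators, 1 = event, 0 = censored.
#' @param conf_level confidence level for the pointwise bands.
#' @return an object of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `s_hat`, `ci_low`, `ci_high`, `n`.
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, s_hat = fit$surv,
                 ci_low = fit$lower, ci_high = fit$upper,
                 n = length(times)),
            class = "km_curve")
}

check_surv_input <- function(times, events) {
  if (!length(times)) ec_validation_error("no subjects supplied")
  if (length(times) != length(events)) {
    ec_validation_error("times and events differ in length")
  }
  if (any(is.na(times)) || any(times < 0)) {
    ec_validation_error("survival times must be non-negative and non-missing")
  }
  if (!all(events %in% c(0, 1))) {
    ec_validation_error("event indicators must be 0/1")
  }
  invisible(TRUE)
}

#' @export
print.km_curve <- function(x, ...) {
  events <- sum(x$n_event)
  cat(sprintf("<km_curve> n = %d, events = %d, last follow-up = %g months\n",
              x$n, events, max(x$time)))
  invisible(x)
}

#' Survival rate at a horizon and median survival
#'
#' The rate at the horizon is the estimate at the last event time at or
#' before the horizon (1 when no event has occurred by then). The median is
#' the smallest time at which the estimate drops to 0.5 or below; when the
#' curve never reaches 0.5 the median is not reached.
#'
#' @param curve a [km_estimate()] result.
#' @param horizon_months horizon in months (default 120 = 10 years).
#' @return list: `rate_at_horizon` (fraction), `rate_pct` (half-up, 2 dp),
#'   `median_months` (NA when not reached), `not_reached`.
#' @export
curve_summary <- function(curve, horizon_months = 120) {
  if (horizon_months < 0) ec_validation_error("horizon must be >= 0")
  ev <- curve$n_event > 0
  idx <- which(ev & curve$time <= horizon_months)
  rate <- if (length(idx)) curve$s_hat[max(idx)] else 1
  med_idx <- which(curve$s_hat <= 0.5)
  median_months <- if (length(med_idx)) curve$time[min(med_idx)] else NA_real_
  list(rate_at_horizon = rate,
       rate_pct = round_half_up(100 * rate, 2),
       median_months = median_months,
       not_reached = !length(med_idx))
}

#' k-group log-rank test
#'
#' @param times follow-up times in months.
#' @param events event indicators (1 = event).
#' @param groups group labels (>= 2 groups, each with at least one subject).
#' @return an object of class `logrank_result`: `chi2`, `df`, `p_value`,
#'   `n_per_group`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv_input(times, events)
  g <- factor(groups)
  g <- droplevels(g)
  if (nlevels(g) < 2) ec_validation_error("log-rank test requires at least two groups")
  if (length(g) != length(times)) {
    ec_validation_error("group labels and times differ in length")
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  chi2 <- unname(sd$chisq)
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 n_per_group = as.integer(table(g))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: chi2 = %.3f on %d df, p = %.4g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood maximization via [survival::coxph()] with Efron tie
#' handling by default (Breslow available); Wald confidence intervals and
#' p-values per covariate. Rows with missing covariates are dropped
#' (complete-case) before fitting.
#'
#' @param covariates numeric matrix or data frame of covariates with column
#'   names; no column may be constant among the analyzed subjects.
#' @param times follow-up times in months.
#' @param events event indicators (1 = event).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level confidence level of the hazard-ratio intervals.
#' @return an object of class `cox_result` with `table` (one row per
#'   covariate: `covariate`, `log_hr`, `hr`, `ci95_low`, `ci95_high`,
#'   `p_value`), `n`, `events`, `converged`, `ties`.
#' @export
cox_ph <- function(covariates, times, events, ties = c("efron", "breslow"),
                   conf_level = 0.95) {
  ties <- match.arg(ties)
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  check_surv_input(times, events)
  if (nrow(x) != length(times)) {
    ec_validation_error("covariate rows and times differ in length")
  }
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  times <- times[keep]
  events <- events[keep]
  if (nrow(x) <= ncol(x)) {
    ec_degenerate_error("fewer usable subjects than covariates")
  }
  const <- apply(x, 2, function(col) length(unique(col)) < 2)
  if (any(const)) {
    ec_degenerate_error(sprintf("constant covariate(s): %s",
                                paste(colnames(x)[const], collapse = ", ")))
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ x, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w),
                ignore.case = TRUE)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  if (any(is.na(stats::coef(fit)))) converged <- FALSE
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    covariate = colnames(x),
    log_hr = unname(beta),
    hr = exp(unname(beta)),
    ci95_low = exp(unname(beta) - z * se),
    ci95_high = exp(unname(beta) + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / se)),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, n = fit$n, events = fit$nevent,
                 converged = converged, ties = ties),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH (%s ties): n = %d, events = %d%s\n", x$ties, x$n,
              x$events, if (x$converged) "" else "  [DID NOT CONVERGE]"))
  tab <- x$table
  tab$hr <- sprintf("%.3f", tab$hr)
  tab$ci <- sprintf("%.3f-%.3f", x$table$ci95_low, x$table$ci95_high)
  tab$p <- format.pval(x$table$p_value, digits = 3)
  print(tab[, c("covariate", "hr", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Covariate codings for the multivariate overall-survival model
#'
#' Builds the covariate matrix used when relating subtype and
#' clinicopathological factors to overall survival: age dichotomized at 55
#' years, stage binarized I-II vs III-IV, LVSI yes/no, and subtype indicator
#' columns against the CNL reference (the largest group). Unknown stage/LVSI
#' become NA and are dropped by [cox_ph()]'s complete-case rule.
#'
#' @param clinical clinical data frame (cohort `$clinical`).
#' @param subtype_labels subtype per sample, aligned or named by sample id.
#' @param age_cut dichotomization age (default 55).
#' @param reference reference subtype (default `"CNL"`).
#' @return numeric matrix, one row per sample.
#' @export
encode_cox_covariates <- function(clinical, subtype_labels, age_cut = 55,
                                  reference = "CNL") {
  labels <- align_labels(subtype_labels, clinical$sample_id)
  stage_late <- ifelse(clinical$stage %in% c("III", "IV"), 1,
                       ifelse(clinical$stage %in% c("I", "II"), 0, NA))
  lvsi <- ifelse(clinical$lvsi == "yes", 1,
                 ifelse(clinical$lvsi == "no", 0, NA))
  out <- cbind(age_ge_55 = as.numeric(clinical$age >= age_cut),
               stage_III_IV = stage_late,
               lvsi_yes = lvsi)
  for (s in setdiff(SUBTYPE_LEVELS, reference)) {
    col <- as.numeric(labels == s)
    col[labels == UNCLASSIFIABLE] <- NA
    out <- cbind(out, col)
    colnames(out)[ncol(out)] <- paste0("subtype_", gsub("-", "", s))
  }
  rownames(out) <- clinical$sample_id
  out
}

#' Per-group survival report
#'
#' For each level of `groups`: subjects, events, survival rate at the
#' horizon and median survival, plus the k-group log-rank comparison.
#'
#' @param times,events follow-up and event indicators.
#' @param groups group labels.
#' @param horizon_months reporting horizon (default 120).
#' @return list with `by_group` (data frame) and `logrank`.
#' @export
survival_report <- function(times, events, groups, horizon_months = 120) {
  g <- droplevels(factor(groups))
  rows <- lapply(levels(g), function(lv) {
    sel <- g == lv
    cs <- curve_summary(km_estimate(times[sel], events[sel]), horizon_months)
    data.frame(group = lv, n = sum(sel), events = sum(events[sel]),
               rate_at_horizon_pct = cs$rate_pct,
               median_months = cs$median_months,
               stringsAsFactors = FALSE)
  })
  list(by_group = do.call(rbind, rows),
       logrank = if (nlevels(g) >= 2) logrank_test(times, events, g) else NULL)
}
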