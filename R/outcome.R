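#' Dichotomize a cohort at a score quantile
#'
#' Splits samples into `high` (score strictly above the empirical type-7
#' quantile) and `low` (at or below it, so ties at the cutoff go to low).
#' The default 0.75 reproduces the common 75th-percentile convention for
#' prognostic signature scores.
#'
#' @param cohort data.frame with at least `time_months`, `event`, `score`.
#' @param q cutoff quantile in (0, 1).
#' @return the cohort with added `group` factor (`low`/`high`) and attributes
#'   `cutoff` and `quantile`.
#' @export
dichotomize_at_quantile <- function(cohort, q = 0.75) {
  if (q <= 0 || q >= 1) stop("q must lie strictly between 0 and 1")
  if (nrow(cohort) < 8) stop("cohort must have at least 8 samples")
  if (length(unique(cohort$score)) == 1) {
    stop("all scores equal; cannot dichotomize")
  }
  cutoff <- stats::quantile(cohort$score, q, type = 7, names = FALSE)
  cohort$group <- factor(ifelse(cohort$score > cutoff, "high", "low"),
                         levels = c("low", "high"))
  attr(cohort, "cutoff") <- cutoff
  attr(cohort, "quantile") <- q
  cohort
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group plus the two-group log-rank
#' chi-squared statistic (1 df). A group with zero events leaves the curves
#' valid but flags the test as unstable; a cohort with zero events has no
#' defined log-rank test and raises an error.
#'
#' @param strat dichotomized cohort from [dichotomize_at_quantile()] (or any
#'   data.frame with `time_months`, `event`, `group`).
#' @return list with `fit` (a [survival::survfit] object), `chisq`, `p`,
#'   `unstable` flag.
#' @export
km_logrank <- function(strat) {
  stopifnot(all(c("time_months", "event", "group") %in% names(strat)))
  if (any(table(strat$group) == 0)) stop("both groups must be non-empty")
  if (sum(strat$event) == 0) {
    stop("no events in cohort; log-rank test undefined")
  }
  s <- survival::Surv(strat$time_months, strat$event)
  fit <- survival::survfit(s ~ group, data = strat)
  sd <- survival::survdiff(s ~ group, data = strat, rho = 0)
  unstable <- any(tapply(strat$event, strat$group, sum) == 0)
  if (unstable) warning("a group has zero events; log-rank test unstable")
  list(fit = fit, chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       unstable = unstable)
}

#' Cox proportional-hazards ratio for the high-score group
#'
#' Fits event ~ group (plus optional covariates for the multivariable mode)
#' with Efron tie handling and reports the high-vs-low hazard ratio with its
#' Wald 95% confidence interval and p-value.
#'
#' @param strat dichotomized cohort (see [km_logrank()]).
#' @param covariates optional character vector of covariate column names.
#' @return list with `hr`, `ci` (length-2), `p` (Wald), `n_events`, `fit`.
#'   Fewer than 10 events triggers a warning (small-sample instability);
#'   non-convergence raises an error with diagnostics.
#' @export
cox_hr <- function(strat, covariates = NULL) {
  stopifnot(all(c("time_months", "event", "group") %in% names(strat)))
  n_events <- sum(strat$event)
  if (n_events < 10) {
    warning("only ", n_events, " events; hazard ratio may be unstable")
  }
  rhs <- paste(c("group", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time_months, event) ~", rhs))
  fit <- survival::coxph(fml, data = strat, ties = "efron")
  if (!is.null(fit$info) || any(is.na(stats::coef(fit)["grouphigh"]))) {
    stop("Cox model did not converge: ",
         paste(utils::capture.output(print(fit)), collapse = "\n"))
  }
  sm <- summary(fit)
  co <- sm$coefficients["grouphigh", ]
  ci <- sm$conf.int["grouphigh", c("lower .95", "upper .95")]
  list(hr = unname(exp(co["coef"])), ci = unname(ci),
       p = unname(co["Pr(>|z|)"]), n_events = n_events, fit = fit)
}
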