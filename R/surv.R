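# Two-group log-rank chi-square via vectorized life-table arithmetic.
# Used by log_rank_test() and by the cutpoint scan, where it is evaluated
# hundreds of times; agrees with survival::survdiff (asserted in tests).
logrank_chisq <- function(times, events, group) {
  group <- as.integer(group)            # 0/1
  ut <- sort(unique(times[events == 1]))
  if (length(ut) == 0) return(NA_real_)
  # at-risk counts per distinct event time via sorted-time rank arithmetic
  # (comparisons are exact: ut is drawn from `times` itself)
  st <- sort(times)
  s1 <- sort(times[group == 1L])
  n_tot <- length(st) - findInterval(ut, st, left.open = TRUE)
  n1 <- length(s1) - findInterval(ut, s1, left.open = TRUE)
  n0 <- n_tot - n1
  # event counts per distinct event time, per group
  pos <- match(times, ut)               # NA for non-event times
  ev1 <- events == 1 & group == 1L & !is.na(pos)
  ev0 <- events == 1 & group == 0L & !is.na(pos)
  d1 <- tabulate(pos[ev1], length(ut))
  d0 <- tabulate(pos[ev0], length(ut))
  n <- n1 + n0
  d <- d1 + d0
  e1 <- d * n1 / n
  v <- ifelse(n > 1, d * (n1 / n) * (n0 / n) * (n - d) / (n - 1), 0)
  ov <- sum(v)
  if (ov <= 0) return(0)
  (sum(d1) - sum(e1))^2 / ov
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood standard errors and the median
#' survival time with a log-log 95% confidence interval. Censorings tied
#' with events at the same time are handled with the usual
#' events-before-censorings convention.
#'
#' @param times Nonnegative follow-up times (months).
#' @param events 0/1 event indicators.
#' @return An object of class `km_curve`: `time`, `surv`, `n_risk`,
#'   `n_event` at each observed time, `median` with `median_ci`, and the
#'   underlying [survival::survfit] object as `fit`.
#' @examples
#' km <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
#' km$surv  # 0.75 after t = 1, 0.375 after t = 3
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1) stop_input("no observations")
  if (any(times < 0)) stop_input("negative follow-up time")
  if (all(times == 0) && sum(events) == 0) {
    warning("all times zero with no events: degenerate curve S = 1")
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log")
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  med_ci <- c(unname(stats::quantile(fit, probs = 0.5)$lower),
              unname(stats::quantile(fit, probs = 0.5)$upper))
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, std_err = fit$std.err,
                 median = med, median_ci = med_ci, fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d subjects, %d events; median %.3g months (95%% CI %.3g-%.3g)\n",
              max(x$n_risk), sum(x$n_event), x$median,
              x$median_ci[1], x$median_ci[2]))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$fit, xlab = "Months", ylab = "Survival probability", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) two-sample log-rank statistic with a 1-df
#' chi-square p-value.
#'
#' @param times,events Pooled follow-up data.
#' @param group Two-level group labels.
#' @return List with `chi_square` and `p`.
#' @export
log_rank_test <- function(times, events, group) {
  g <- as.integer(factor(group)) - 1L
  if (length(unique(g)) != 2L) stop_input("exactly two groups required")
  if (sum(events) < 1) stop_input("no events in either group")
  chi <- logrank_chisq(times, events, g)
  list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood (Breslow tie handling by default,
#' Efron available) and reports hazard ratios with Wald 95% confidence
#' intervals and p-values, plus the Breslow baseline cumulative hazard.
#' Follows the events-per-variable guideline: a warning (not an error) is
#' raised when the number of events is below ten times the number of
#' covariates.
#'
#' @param times,events Follow-up data.
#' @param covariates Data frame or matrix of numeric covariates (no
#'   constant columns).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An object of class `radsurv_cox`: `coefficients`, `vcov`,
#'   `table` (HR, CI, p per covariate), `baseline` (time, cumulative
#'   hazard), `score_test`, `n_events`, and the [survival::coxph] fit.
#' @export
cox_fit <- function(times, events, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (sum(events) < 1) stop_input("no events: cannot fit a Cox model")
  const <- vapply(covariates, function(v) stats::var(as.numeric(v)) == 0,
                  logical(1))
  if (any(const)) {
    stop_input("constant covariate(s): ",
               paste(names(covariates)[const], collapse = ", "))
  }
  if (sum(events) < 10 * ncol(covariates)) {
    warning(sprintf("only %d events for %d covariates (< 10 per covariate)",
                    sum(events), ncol(covariates)))
  }
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 100))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  bad <- !is.finite(beta) | !is.finite(se) | se > 100
  if (any(bad)) {
    stop("Cox fit failed to converge (monotone likelihood?) for: ",
         paste(names(beta)[bad], collapse = ", "), call. = FALSE)
  }
  tab <- data.frame(
    covariate = names(beta),
    coef = unname(beta),
    hr = exp(unname(beta)),
    hr_lower = exp(unname(beta - 1.96 * se)),
    hr_upper = exp(unname(beta + 1.96 * se)),
    se = unname(se),
    p = unname(2 * stats::pnorm(-abs(beta / se))),
    row.names = NULL)
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(coefficients = beta, vcov = stats::vcov(fit), table = tab,
                 baseline = data.frame(time = bh$time, cumhaz = bh$hazard),
                 score_test = unname(fit$score), n_events = sum(events),
                 ties = ties, fit = fit),
            class = "radsurv_cox")
}

#' @export
print.radsurv_cox <- function(x, ...) {
  cat(sprintf("<radsurv_cox> %d events, %s ties\n", x$n_events, x$ties))
  tab <- x$table
  tab[, -1] <- round(tab[, -1], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.radsurv_cox <- function(object, ...) object$coefficients

#' @export
vcov.radsurv_cox <- function(object, ...) object$vcov

#' @export
summary.radsurv_cox <- function(object, ...) summary(object$fit, ...)

#' Harrell's concordance index
#'
#' Fraction of usable subject pairs (the member with the shorter follow-up
#' experienced the event) in which the higher predicted risk belongs to
#' the shorter survivor; prediction ties count 0.5.
#'
#' @param predictions Risk scores; higher values must mean higher risk.
#' @param times,events Follow-up data.
#' @return Concordance index in `[0, 1]`.
#' @examples
#' c_index(c(0.5, 0.9, 0.1), c(1, 2, 3), c(1, 1, 1))  # 2/3
#' @export
c_index <- function(predictions, times, events) {
  if (length(predictions) != length(times) ||
      length(times) != length(events)) {
    stop_input("'predictions', 'times' and 'events' must have equal length")
  }
  cc <- survival::concordance(survival::Surv(times, events) ~ predictions,
                              reverse = TRUE)
  npairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (npairs == 0) stop_input("no usable pairs for concordance")
  unname(cc$concordance)
}

#' Univariate-then-multivariate Cox screening
#'
#' Fits a univariate Cox model per covariate, then a multivariate model on
#' the covariates whose univariate Wald p-value is below `entry_p`
#' (mirroring the usual two-stage table: univariate screen, multivariate
#' adjustment).
#'
#' @param times,events Follow-up data.
#' @param covariates Data frame of candidate covariates.
#' @param entry_p Univariate p-value threshold for entry (default 0.05).
#' @param ties Passed to [cox_fit()].
#' @return List with `univariate` (one table row per covariate),
#'   `multivariate` (a [cox_fit()] or `NULL` when nothing enters) and
#'   `entered` (covariate names).
#' @export
cox_screen <- function(times, events, covariates, entry_p = 0.05,
                       ties = "breslow") {
  covariates <- as.data.frame(covariates)
  uni <- do.call(rbind, lapply(names(covariates), function(nm) {
    cox_fit(times, events, covariates[, nm, drop = FALSE], ties = ties)$table
  }))
  entered <- uni$covariate[uni$p < entry_p]
  multi <- NULL
  if (length(entered) >= 1) {
    multi <- cox_fit(times, events, covariates[, entered, drop = FALSE],
                     ties = ties)
  }
  list(univariate = uni, multivariate = multi, entered = entered)
}
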