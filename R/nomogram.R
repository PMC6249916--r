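#' Build a point-scaled nomogram from a Cox fit
#'
#' Re-expresses the Cox linear predictor on a 0-100 point scale: each
#' covariate's points are its risk contribution `beta_j * x_j` shifted so
#' the lowest-risk end of its observed range scores 0, scaled so the
#' variable with the widest risk contribution spans exactly 0-100. Total
#' points are therefore a strictly increasing affine transform of the
#' linear predictor, and the total-points axis maps to predicted survival
#' at the requested horizons through the Breslow baseline.
#'
#' @param fit A [cox_fit()] result.
#' @param variable_ranges Named list of `c(min, max)` observed ranges, one
#'   per model covariate (binary variables: `c(0, 1)`).
#' @param horizons_months Horizons for the total-points-to-survival
#'   lookup (default 36 and 60 months).
#' @return An object of class `nomogram_spec`: `points` (per-variable
#'   slope/reference giving `points(v) = slope * (v - ref)`), `max_points`
#'   per variable, `lp_at_zero` and `lp_per_point` (the affine map back to
#'   the linear predictor), and `lookup` (total points vs predicted
#'   survival per horizon).
#' @export
build_nomogram <- function(fit, variable_ranges,
                           horizons_months = c(36, 60)) {
  stopifnot(inherits(fit, "radsurv_cox"))
  beta <- fit$coefficients
  vars <- names(beta)
  missing <- setdiff(vars, names(variable_ranges))
  if (length(missing)) {
    stop_input("no range supplied for: ", paste(missing, collapse = ", "))
  }
  rng <- lapply(variable_ranges[vars], range)
  width <- vapply(seq_along(vars), function(j) {
    w <- abs(beta[j]) * (rng[[j]][2] - rng[[j]][1])
    if (w == 0) stop_input("zero-range variable: ", vars[j])
    w
  }, numeric(1))
  scale_max <- max(width)
  pts <- lapply(seq_along(vars), function(j) {
    b <- beta[j]
    ref <- if (b >= 0) rng[[j]][1] else rng[[j]][2]  # lowest-risk endpoint
    list(slope = 100 * b / scale_max, ref = ref)
  })
  names(pts) <- vars
  lp_at_zero <- sum(vapply(seq_along(vars), function(j) {
    beta[j] * pts[[j]]$ref
  }, numeric(1)))
  lp_per_point <- scale_max / 100
  total_max <- sum(100 * width / scale_max)
  grid <- seq(0, total_max, length.out = 101)
  lookup <- data.frame(total_points = grid)
  for (h in horizons_months) {
    s0 <- baseline_survival(fit, h)
    lookup[[paste0("surv_", h, "m")]] <-
      s0^exp(lp_at_zero + lp_per_point * grid)
  }
  structure(list(points = pts, max_points = stats::setNames(
    100 * width / scale_max, vars),
    lp_at_zero = lp_at_zero, lp_per_point = lp_per_point,
    horizons_months = horizons_months, lookup = lookup, fit = fit),
    class = "nomogram_spec")
}

#' @export
print.nomogram_spec <- function(x, ...) {
  cat("<nomogram_spec> per-variable maximum points:\n")
  print(round(x$max_points, 1))
  cat(sprintf("  horizons: %s months\n",
              paste(x$horizons_months, collapse = ", ")))
  invisible(x)
}

#' Total nomogram points for covariate profiles
#'
#' @param nomogram A [build_nomogram()] spec.
#' @param covariates Data frame (or named vector) with the model
#'   covariates.
#' @return Numeric vector of total points.
#' @export
nomogram_points <- function(nomogram, covariates) {
  stopifnot(inherits(nomogram, "nomogram_spec"))
  if (is.null(dim(covariates))) {
    covariates <- as.data.frame(as.list(covariates))
  }
  tot <- numeric(nrow(covariates))
  for (v in names(nomogram$points)) {
    p <- nomogram$points[[v]]
    tot <- tot + p$slope * (covariates[[v]] - p$ref)
  }
  tot
}

# Baseline survival S0(t) at a horizon from the Breslow cumulative hazard
# (step function; carried forward beyond the last event with a warning).
baseline_survival <- function(fit, horizon) {
  bh <- fit$baseline
  if (horizon > max(bh$time)) {
    warning(sprintf("horizon %g beyond last observed time %g: using last baseline value",
                    horizon, max(bh$time)))
  }
  idx <- findInterval(horizon, bh$time)
  if (idx == 0) return(1)
  exp(-bh$cumhaz[idx])
}

#' Predicted survival probability under a Cox fit
#'
#' `S(t | x) = S0(t) ^ exp(lp(x))` with the Breslow baseline `S0` and the
#' uncentered linear predictor `lp(x) = sum(beta_j x_j)`.
#'
#' @param fit A [cox_fit()] result.
#' @param covariates Data frame (or named vector) of covariate profiles.
#' @param horizon_months Prediction horizon.
#' @return Numeric vector of survival probabilities.
#' @export
predict_survival <- function(fit, covariates, horizon_months) {
  stopifnot(inherits(fit, "radsurv_cox"))
  if (is.null(dim(covariates))) {
    covariates <- as.data.frame(as.list(covariates))
  }
  x <- as.matrix(covariates[, names(fit$coefficients), drop = FALSE])
  lp <- drop(x %*% fit$coefficients)
  unname(baseline_survival(fit, horizon_months)^exp(lp))
}

#' Bootstrap-averaged calibration of horizon survival predictions
#'
#' Refits the Cox model on `B` bootstrap resamples and averages the
#' resample models' predictions on the original cohort (a simple
#' bootstrap smoothing of apparent predictions). Patients are grouped by
#' predicted-survival quantiles; each group's mean prediction is paired
#' with its Kaplan-Meier observed survival (with standard error) at the
#' horizon, and a Hosmer-Lemeshow-style grouped chi-square on observed
#' versus expected events (with `groups - 2` degrees of freedom) tests
#' the agreement. A group with no subjects at risk at the horizon is
#' merged with its neighbor.
#'
#' @param times,events Follow-up data.
#' @param covariates Data frame of model covariates.
#' @param horizon_months Calibration horizon.
#' @param B Bootstrap replicates (default 50).
#' @param n_groups Risk groups (default 4, quartiles).
#' @param resample Set `FALSE` to skip resampling (apparent calibration;
#'   with `B = 1` this reproduces the no-bootstrap curve exactly).
#' @param seed Seed for the resampling.
#' @param ties Passed to [cox_fit()].
#' @return An object of class `calibration_report`: `groups` (per-group
#'   `n`, `mean_predicted`, `observed`, `observed_se`), `hl_statistic`,
#'   `hl_df`, `hl_p`, `B`, `horizon_months`, `merged` (whether groups
#'   were merged).
#' @export
bootstrap_calibration <- function(times, events, covariates, horizon_months,
                                  B = 50L, n_groups = 4L, resample = TRUE,
                                  seed = 1L, ties = "breslow") {
  if (B < 1) stop_input("'B' must be at least 1")
  if (n_groups < 2) stop_input("'n_groups' must be at least 2")
  covariates <- as.data.frame(covariates)
  n <- length(times)
  pred_mat <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
      fb <- cox_fit(times[idx], events[idx],
                    covariates[idx, , drop = FALSE], ties = ties)
      predict_survival(fb, covariates, horizon_months)
    }, numeric(n))
  })
  pred <- rowMeans(pred_mat)

  qs <- stats::quantile(pred, probs = seq(0, 1, length.out = n_groups + 1))
  grp <- cut(pred, breaks = unique(qs), include.lowest = TRUE)
  grp <- as.integer(grp)
  merged <- FALSE
  repeat {
    at_risk <- vapply(sort(unique(grp)), function(g) {
      sum(times[grp == g] >= horizon_months | events[grp == g] == 1)
    }, numeric(1))
    if (all(at_risk > 0) || length(unique(grp)) <= 2) break
    bad <- sort(unique(grp))[which(at_risk == 0)[1]]
    grp[grp == bad] <- if (bad == max(grp)) bad - 1L else bad + 1L
    grp <- as.integer(factor(grp))
    merged <- TRUE
  }
  gl <- sort(unique(grp))
  rows <- lapply(gl, function(g) {
    sel <- grp == g
    km <- km_estimate(times[sel], events[sel])
    idx <- findInterval(horizon_months, km$time)
    obs <- if (idx == 0) 1 else km$surv[idx]
    se <- if (idx == 0) 0 else km$surv[idx] * km$std_err[idx]
    data.frame(group = g, n = sum(sel), mean_predicted = mean(pred[sel]),
               observed = obs, observed_se = se)
  })
  groups <- do.call(rbind, rows)
  # grouped observed vs expected events by the horizon
  O <- groups$n * (1 - groups$observed)
  E <- groups$n * (1 - groups$mean_predicted)
  denom <- pmax(E * (1 - E / groups$n), 1e-8)
  hl <- sum((O - E)^2 / denom)
  df <- max(1L, length(gl) - 2L)
  structure(list(groups = groups, predicted = pred, hl_statistic = hl,
                 hl_df = df,
                 hl_p = stats::pchisq(hl, df, lower.tail = FALSE),
                 B = B, horizon_months = horizon_months, merged = merged),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %d-month horizon, B = %d%s\n",
              x$horizon_months, x$B,
              if (x$merged) " (groups merged)" else ""))
  print(round(x$groups, 3), row.names = FALSE)
  cat(sprintf("  Hosmer-Lemeshow-style chi-square %.3f on %d df, p = %.3g\n",
              x$hl_statistic, x$hl_df, x$hl_p))
  invisible(x)
}

#' @export
plot.calibration_report <- function(x, ...) {
  plot(x$groups$mean_predicted, x$groups$observed, xlim = c(0, 1),
       ylim = c(0, 1), xlab = "Predicted survival",
       ylab = "Observed (KM) survival", pch = 19, ...)
  graphics::arrows(x$groups$mean_predicted,
                   x$groups$observed - 1.96 * x$groups$observed_se,
                   x$groups$mean_predicted,
                   x$groups$observed + 1.96 * x$groups$observed_se,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Compare risk models by concordance index
#'
#' Computes Harrell's C-index with a bootstrap percentile 95% confidence
#' interval for each named risk-score column (nomogram linear predictors,
#' the rad-score, ordinal staging systems, ...). Higher score must mean
#' higher risk in every column.
#'
#' @param model_predictions Named list (or data frame) of risk-score
#'   vectors.
#' @param times,events Follow-up data.
#' @param B Bootstrap replicates for the CI (default 200).
#' @param seed Seed for the resampling.
#' @return Data frame with `model`, `c_index`, `ci_lower`, `ci_upper`.
#' @export
compare_models <- function(model_predictions, times, events, B = 200L,
                           seed = 1L) {
  model_predictions <- as.data.frame(model_predictions)
  if (ncol(model_predictions) < 1) stop_input("at least one model required")
  n <- length(times)
  boot_idx <- with_seed(seed, {
    replicate(B, sample.int(n, n, replace = TRUE), simplify = FALSE)
  })
  rows <- lapply(names(model_predictions), function(nm) {
    p <- model_predictions[[nm]]
    ci <- c_index(p, times, events)
    bs <- vapply(boot_idx, function(idx) {
      tryCatch(c_index(p[idx], times[idx], events[idx]), error = function(e) NA_real_)
    }, numeric(1))
    q <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    data.frame(model = nm, c_index = ci, ci_lower = q[1], ci_upper = q[2])
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
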