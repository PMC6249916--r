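#' Dichotomize follow-up at the five-year horizon
#'
#' The logistic outcome behind the rad-score is the event status at five
#' years after surgery: 1 if the event occurred within 60 months, 0 if the
#' patient was followed event-free for at least 60 months, and `NA`
#' (excluded) if censored before 60 months, when the five-year status is
#' unknowable.
#'
#' @param time_months Nonnegative follow-up times in months.
#' @param event 0/1 event indicators.
#' @param horizon_months Horizon (default 60).
#' @return Integer vector of 0/1/NA labels.
#' @examples
#' make_five_year_label(c(72, 40, 40), c(0, 1, 0))  # 0, 1, NA
#' @export
make_five_year_label <- function(time_months, event, horizon_months = 60) {
  if (any(time_months < 0)) stop_input("negative follow-up time")
  event <- as.integer(event)
  out <- rep(NA_integer_, length(time_months))
  out[event == 1L & time_months <= horizon_months] <- 1L
  out[time_months >= horizon_months & !(event == 1L & time_months <= horizon_months)] <- 0L
  out
}

#' Fit the lasso-logistic rad-score model
#'
#' Standardizes the feature matrix (z-scores recorded in the model), fits
#' the L1-penalized logistic regression path with \pkg{glmnet}, selects
#' the penalty by stratified k-fold cross-validated AUC (the `"one_se"`
#' rule by default, or `"min"`), and returns the sparse coefficients.
#' The rad-score of a patient is `orientation * (intercept + sum of
#' standardized features times coefficients)`; with the default
#' orientation `-1`, lower scores indicate higher five-year event risk
#' (an aggressive-texture phenotype).
#'
#' @param x Numeric feature matrix (patients in rows, named columns) or
#'   data frame of numeric features.
#' @param y Binary outcome labels (both classes present); rows with `NA`
#'   labels are dropped.
#' @param lambda_grid Optional decreasing penalty sequence; defaults to
#'   the glmnet path.
#' @param lambda Optional fixed penalty: skips cross-validation and
#'   returns the path coefficients at this value.
#' @param n_folds Cross-validation folds (default 10).
#' @param rule Penalty selection rule, `"one_se"` or `"min"`.
#' @param orientation `+1` or `-1` (default `-1`; see above).
#' @param seed Seed for the fold assignment (recorded in the model).
#' @return An object of class `radscore_model`: `intercept`,
#'   `coefficients` (nonzero only, on the standardized scale), `lambda`,
#'   `standardization` (`center`/`scale` per retained feature), `rule`,
#'   `orientation`, `horizon_months`, `seed`, `n_nonzero`, `cv` (lambda
#'   grid with mean and SE of CV AUC, when cross-validated).
#' @export
fit_radscore <- function(x, y, lambda_grid = NULL, lambda = NULL,
                         n_folds = 10L, rule = c("one_se", "min"),
                         orientation = -1, seed = 1L,
                         horizon_months = 60) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- as.integer(y[keep])
  if (length(unique(y)) < 2L) {
    stop_input("outcome has a single class: cannot fit a logistic model")
  }
  if (nrow(x) < n_folds) stop_input("fewer observations than folds")
  if (!orientation %in% c(-1, 1)) stop_input("'orientation' must be +1 or -1")

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  usable <- scl > 0
  z <- sweep(sweep(x[, usable, drop = FALSE], 2, ctr[usable]), 2,
             scl[usable], "/")

  cv <- NULL
  if (is.null(lambda)) {
    foldid <- with_seed(seed, {
      f <- integer(length(y))           # stratified by outcome
      for (cl in unique(y)) {
        idx <- which(y == cl)
        f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      f
    })
    # stop the default path at lambda_max/100: with many collinear texture
    # features the tail of the path is slow and never selected by CV-AUC
    cvfit <- with_seed(seed, if (is.null(lambda_grid)) {
      glmnet::cv.glmnet(z, y, family = "binomial", type.measure = "auc",
                        foldid = foldid, standardize = FALSE,
                        lambda.min.ratio = 0.01)
    } else {
      glmnet::cv.glmnet(z, y, family = "binomial", type.measure = "auc",
                        lambda = lambda_grid, foldid = foldid,
                        standardize = FALSE)
    })
    lambda <- if (rule == "one_se") cvfit$lambda.1se else cvfit$lambda.min
    cv <- data.frame(lambda = cvfit$lambda, auc = cvfit$cvm,
                     auc_se = cvfit$cvsd)
    fit <- cvfit$glmnet.fit
  } else {
    if (lambda < 0) stop_input("'lambda' must be nonnegative")
    path <- lambda_grid
    if (is.null(path)) {
      lmax <- max(abs(crossprod(z, y - mean(y)))) / length(y)
      path <- exp(seq(log(max(lmax, lambda + 1e-4) * 1.05),
                      log(max(lambda, 1e-5)), length.out = 60))
      if (lambda < min(path)) path <- c(path, lambda)
    }
    fit <- glmnet::glmnet(z, y, family = "binomial", lambda = path,
                          standardize = FALSE, thresh = 1e-12)
  }
  cf <- as.matrix(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))[, 1]
  beta <- cf[-1]
  nz <- beta != 0
  structure(list(
    intercept = unname(cf[1]),
    coefficients = beta[nz],
    lambda = lambda,
    standardization = list(center = ctr[usable][nz], scale = scl[usable][nz]),
    rule = if (is.null(cv)) "fixed" else rule,
    orientation = orientation,
    horizon_months = horizon_months,
    seed = as.integer(seed),
    n_nonzero = sum(nz),
    n_obs = nrow(z),
    cv = cv), class = "radscore_model")
}

#' @export
print.radscore_model <- function(x, ...) {
  cat(sprintf("<radscore_model> %d nonzero of model features, lambda = %.5g (%s rule)\n",
              x$n_nonzero, x$lambda, x$rule))
  cat(sprintf("  fitted on %d patients, %d-month outcome, orientation %+d\n",
              x$n_obs, x$horizon_months, x$orientation))
  if (x$n_nonzero > 0) {
    cat("  coefficients (standardized scale):\n")
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' @export
coef.radscore_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Compute rad-scores for feature vectors
#'
#' Applies the recorded standardization and sparse coefficients:
#' `score = orientation * (intercept + sum(beta_j * (x_j - mean_j) / sd_j))`.
#' A feature sitting at its training mean contributes nothing.
#'
#' @param model A [fit_radscore()] model.
#' @param features Named numeric vector, matrix or data frame containing at
#'   least the model's features (columns matched by name).
#' @return Numeric vector of scores (one per row).
#' @export
compute_rad_score <- function(model, features) {
  stopifnot(inherits(model, "radscore_model"))
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, names(features)))
  }
  features <- as.matrix(features)
  need <- names(model$coefficients)
  missing <- setdiff(need, colnames(features))
  if (length(missing)) {
    stop_input("feature(s) missing from input: ",
               paste(missing, collapse = ", "))
  }
  if (length(need) == 0) {
    return(rep(model$orientation * model$intercept, nrow(features)))
  }
  z <- sweep(sweep(features[, need, drop = FALSE], 2,
                   model$standardization$center), 2,
             model$standardization$scale, "/")
  lp <- model$intercept + drop(z %*% model$coefficients)
  model$orientation * lp
}

#' @export
predict.radscore_model <- function(object, newdata, ...) {
  compute_rad_score(object, newdata)
}

#' Serialize a rad-score model to JSON
#'
#' @param model A [fit_radscore()] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_radscore_model <- function(model, path) {
  stopifnot(inherits(model, "radscore_model"))
  obj <- model[c("intercept", "coefficients", "lambda", "standardization",
                 "rule", "orientation", "horizon_months", "seed",
                 "n_nonzero", "n_obs")]
  obj$coefficients <- as.list(obj$coefficients)
  obj$standardization <- lapply(obj$standardization, as.list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized rad-score model
#'
#' @param path JSON file written by [write_radscore_model()].
#' @return A `radscore_model`.
#' @export
read_radscore_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$standardization <- lapply(obj$standardization, unlist)
  obj$cv <- NULL
  class(obj) <- "radscore_model"
  obj
}
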