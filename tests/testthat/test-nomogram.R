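make_cox_toy <- function(n = 400, seed = 19) {
  withr::with_seed(seed, {
    bin <- stats::rbinom(n, 1, 0.5)
    cont <- stats::runif(n, 0, 10)
    lp <- 0.5 * bin + 0.2 * cont
    t <- stats::rexp(n, 0.02 * exp(lp))
    cens <- stats::runif(n, 0, 120)
    list(times = pmin(t, cens), events = as.integer(t <= cens),
         covariates = data.frame(bin = bin, cont = cont))
  })
}

test_that("nomogram point scaling follows the coefficient-range rule", {
  d <- make_cox_toy()
  fit <- cox_fit(d$times, d$events, d$covariates)
  nom <- build_nomogram(fit, list(bin = c(0, 1), cont = c(0, 10)))
  # the wider risk contribution spans 0-100
  widths <- abs(coef(fit)) * c(1, 10)
  expect_equal(unname(nom$max_points[which.max(widths)]), 100)
  expect_equal(unname(nom$max_points["bin"]),
               100 * abs(coef(fit)["bin"]) / max(widths),
               ignore_attr = TRUE)

  # single binary covariate: levels map to 0 and 100
  fit1 <- cox_fit(d$times, d$events, d$covariates["bin"])
  nom1 <- build_nomogram(fit1, list(bin = c(0, 1)))
  expect_equal(sort(nomogram_points(nom1, data.frame(bin = c(0, 1)))),
               c(0, 100))

  expect_error(build_nomogram(fit, list(bin = c(0, 0), cont = c(0, 10))),
               "zero-range")
})

test_that("total points are an increasing affine transform of the linear predictor", {
  d <- make_cox_toy(seed = 23)
  fit <- cox_fit(d$times, d$events, d$covariates)
  nom <- build_nomogram(fit, list(bin = c(0, 1), cont = c(0, 10)))
  pts <- nomogram_points(nom, d$covariates)
  lp <- as.matrix(d$covariates) %*% coef(fit)
  ft <- stats::lm(lp ~ pts)
  expect_gt(coef(ft)[2], 0)
  expect_lt(max(abs(stats::residuals(ft))), 1e-10)
  expect_true(all(pts >= -1e-9))
  # the lookup maps larger point totals to lower survival
  expect_true(all(diff(nom$lookup$surv_60m) <= 1e-12))
})

test_that("predicted survival follows the proportional-hazards identity", {
  d <- make_cox_toy(seed = 31)
  fit <- cox_fit(d$times, d$events, d$covariates)
  s_base <- predict_survival(fit, data.frame(bin = 0, cont = 0), 36)
  s_double <- predict_survival(
    fit, data.frame(bin = log(2) / coef(fit)["bin"], cont = 0), 36)
  expect_equal(s_double, s_base^2, tolerance = 1e-10)
  expect_warning(predict_survival(fit, data.frame(bin = 0, cont = 0), 1e5),
                 "beyond")
})

test_that("predictions match the exponential closed form", {
  withr::with_seed(13, {
    n <- 2000
    g <- stats::rbinom(n, 1, 0.5)
    rate <- -log(0.70) / 36              # S(36) = 0.70 at the baseline profile
    t <- stats::rexp(n, rate * exp(0.6 * g))
    cens <- stats::runif(n, 0, 200)
    fit <- cox_fit(pmin(t, cens), as.integer(t <= cens),
                   data.frame(g = g))
    pred <- predict_survival(fit, data.frame(g = 0), 36)
    expect_lt(abs(pred - 0.70), 0.03)
    pred1 <- predict_survival(fit, data.frame(g = 1), 36)
    expect_lt(abs(pred1 - 0.70^exp(0.6)), 0.03)
  })
})

test_that("calibration is close under a correctly specified model", {
  d <- make_cox_toy(n = 2000, seed = 17)
  cal <- bootstrap_calibration(d$times, d$events, d$covariates, 36,
                               B = 20, seed = 17)
  expect_lt(max(abs(cal$groups$mean_predicted - cal$groups$observed)), 0.05)
  expect_gt(cal$hl_p, 0.01)

  # B = 1 without resampling reproduces the apparent curve
  cal1 <- bootstrap_calibration(d$times, d$events, d$covariates, 36,
                                B = 1, resample = FALSE, seed = 1)
  fit <- cox_fit(d$times, d$events, d$covariates)
  expect_equal(cal1$predicted, predict_survival(fit, d$covariates, 36),
               tolerance = 1e-10)
})

test_that("a systematic prediction shift is detected by the grouped test", {
  d <- make_cox_toy(n = 2000, seed = 41)
  cal <- bootstrap_calibration(d$times, d$events, d$covariates, 36,
                               B = 1, resample = FALSE, seed = 1)
  shifted <- cal
  shifted$groups$mean_predicted <-
    pmax(0.01, shifted$groups$mean_predicted - 0.2)
  O <- shifted$groups$n * (1 - shifted$groups$observed)
  E <- shifted$groups$n * (1 - shifted$groups$mean_predicted)
  hl <- sum((O - E)^2 / pmax(E * (1 - E / shifted$groups$n), 1e-8))
  p <- stats::pchisq(hl, max(1, nrow(shifted$groups) - 2),
                     lower.tail = FALSE)
  expect_lt(p, 0.01)
})

test_that("model comparison ranks informative scores above chance", {
  withr::with_seed(19, {
    n <- 1000
    stage <- sample(1:4, n, replace = TRUE)
    t <- stats::rexp(n, 0.02 * 1.5^(stage - 1))
    cens <- stats::runif(n, 0, 120)
    times <- pmin(t, cens)
    events <- as.integer(t <= cens)
    comp <- compare_models(list(stage = stage, stage_copy = stage,
                                noise = stats::rnorm(n)),
                           times, events, B = 100, seed = 3)
    st <- comp[comp$model == "stage", ]
    expect_gt(st$c_index, 0.5)
    expect_gt(st$ci_lower, 0.5)
    expect_equal(st$c_index, comp$c_index[comp$model == "stage_copy"])
    # anti-oriented score mirrors around 0.5
    anti <- compare_models(list(s = -stage), times, events, B = 1, seed = 1)
    expect_equal(anti$c_index, 1 - st$c_index, tolerance = 1e-12)
  })
})

test_that("adding a real marker never lowers the training apparent C-index", {
  withr::with_seed(47, {
    for (i in 1:5) {
      n <- 400
      clin <- stats::rbinom(n, 1, 0.5)
      marker <- stats::rbinom(n, 1, 0.5)
      t <- stats::rexp(n, 0.02 * exp(0.4 * clin + 0.9 * marker))
      cens <- stats::runif(n, 0, 120)
      times <- pmin(t, cens)
      events <- as.integer(t <= cens)
      base <- cox_fit(times, events, data.frame(clin = clin))
      full <- cox_fit(times, events,
                      data.frame(clin = clin, marker = marker))
      expect_true(abs(coef(full)["marker"]) > 0)
      c_base <- c_index(drop(as.matrix(data.frame(clin)) %*% coef(base)),
                        times, events)
      c_full <- c_index(drop(as.matrix(data.frame(clin, marker)) %*%
                               coef(full)), times, events)
      expect_gte(c_full, c_base)
    }
  })
})
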