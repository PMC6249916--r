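test_that("product-limit estimates match hand calculation", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km$surv, c(0.75, 0.75, 0.375, 0.375))

  km <- km_estimate(c(3, 1, 7), c(0, 0, 0))
  expect_true(all(km$surv == 1))

  km <- km_estimate(1:4, rep(1, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  expect_warning(km_estimate(c(0, 0), c(0, 0)), "degenerate")
})

test_that("log-rank statistic behaves like the classical test", {
  t1 <- c(2, 4, 6)
  e1 <- c(1, 1, 0)
  pooled_t <- c(t1, t1)
  pooled_e <- c(e1, e1)
  lr <- log_rank_test(pooled_t, pooled_e, rep(0:1, each = 3))
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p, 1)

  # 3-row life-table arithmetic: A events at 1,2,3; B censored at 10
  tt <- c(1, 2, 3, 10, 10, 10)
  ee <- c(1, 1, 1, 0, 0, 0)
  gg <- c(0, 0, 0, 1, 1, 1)
  # hand O-E: E1 at each event time = d * n1/n with n1 = 3 throughout
  e_grp1 <- 1 * 3 / 6 + 1 * 3 / 5 + 1 * 3 / 4
  v <- (3 * 3) / (6 * 6) * (5 / 5) + (3 * 2) / (5 * 5) * (4 / 4) +
    (3 * 1) / (4 * 4) * (3 / 3)
  expect_equal(log_rank_test(tt, ee, gg)$chi_square,
               (0 - e_grp1)^2 / v, tolerance = 1e-10)

  # rank invariance under time rescaling
  withr::with_seed(8, {
    n <- 80
    t <- stats::rexp(n)
    e <- stats::rbinom(n, 1, 0.7)
    g <- rep(0:1, n / 2)
    expect_equal(log_rank_test(t, e, g)$chi_square,
                 log_rank_test(2 * t, e, g)$chi_square)
  })

  expect_error(log_rank_test(c(1, 2), c(0, 0), c(0, 1)), "events")
})

test_that("log-rank agrees with survival::survdiff across random data", {
  withr::with_seed(91, {
    for (i in 1:25) {
      n <- sample(10:120, 1)
      t <- round(stats::rexp(n), 2)     # rounding forces ties
      e <- stats::rbinom(n, 1, 0.7)
      g <- stats::rbinom(n, 1, 0.5)
      if (length(unique(g)) < 2 || sum(e) == 0) next
      ref <- survival::survdiff(survival::Surv(t, e) ~ g)$chisq
      expect_equal(log_rank_test(t, e, g)$chi_square, ref,
                   tolerance = 1e-10)
    }
  })
})

test_that("Cox fits recover planted hazard ratios and respect invariances", {
  withr::with_seed(9, {
    n <- 1000
    g <- rep(0:1, n / 2)
    t <- stats::rexp(n, 0.02 * 2^g)
    fit <- cox_fit(t, rep(1, n), data.frame(g = g))
    expect_gte(fit$table$hr, 1.8)
    expect_lte(fit$table$hr, 2.2)
    expect_true(fit$table$hr_lower < fit$table$hr &
                  fit$table$hr < fit$table$hr_upper)

    # duplicating every subject leaves the estimate unchanged
    fit2 <- cox_fit(rep(t, 2), rep(1, 2 * n), data.frame(g = rep(g, 2)))
    expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
  })

  withr::with_seed(5, {
    n <- 500
    x <- stats::rnorm(n)
    t <- stats::rexp(n, 0.05)           # outcome independent of x
    fit <- cox_fit(t, stats::rbinom(n, 1, 0.8), data.frame(x = x))
    expect_lt(abs(fit$table$coef), 0.15)
    expect_true(fit$table$hr_lower < 1 && fit$table$hr_upper > 1)
  })
})

test_that("Cox score test at beta = 0 equals the log-rank statistic", {
  withr::with_seed(14, {
    # classical equivalence is exact for untied event times
    for (i in 1:5) {
      n <- 150
      g <- stats::rbinom(n, 1, 0.5)
      t <- stats::rexp(n, 0.05 * exp(0.5 * g))
      e <- stats::rbinom(n, 1, 0.8)
      if (sum(e) == 0 || length(unique(g)) < 2) next
      fit <- cox_fit(t, e, data.frame(g = g), ties = "breslow")
      expect_equal(fit$score_test, log_rank_test(t, e, g)$chi_square,
                   tolerance = 1e-6)
    }
  })
})

test_that("Cox guards fire on degenerate inputs", {
  expect_error(cox_fit(1:5, rep(0, 5), data.frame(x = stats::rnorm(5))),
               "no events")
  expect_error(cox_fit(1:5, rep(1, 5), data.frame(x = rep(2, 5))),
               "constant")
  expect_warning(
    cox_fit(stats::rexp(20) + 0.1, rep(1, 20),
            data.frame(a = stats::rnorm(20), b = stats::rnorm(20),
                       c = stats::rnorm(20))),
    "10 per covariate")
  # perfect separation: the risk factor identifies all early deaths
  t <- c(1:10 / 10, 10 + 1:10)
  x <- rep(c(1, 0), each = 10)
  expect_error(suppressWarnings(cox_fit(t, rep(1, 20), data.frame(x = x))),
               "converge")
})

test_that("concordance matches brute-force pair counting", {
  expect_equal(c_index(c(0.5, 0.9, 0.1), c(1, 2, 3), c(1, 1, 1)), 2 / 3)
  expect_equal(c_index(3:1, 1:3, rep(1, 3)), 1)       # anti-ordered = perfect
  expect_equal(c_index(rep(1, 5), 1:5, rep(1, 5)), 0.5)

  withr::with_seed(77, {
    for (i in 1:20) {
      n <- sample(10:200, 1)
      p <- sample(stats::rnorm(n))      # occasional ties via rounding
      if (i %% 2 == 0) p <- round(p, 1)
      t <- round(stats::rexp(n), 2)
      e <- stats::rbinom(n, 1, 0.7)
      if (sum(e) == 0) next
      expect_equal(c_index(p, t, e), cindex_oracle(p, t, e),
                   tolerance = 1e-12)
    }
  })

  expect_error(c_index(c(1, 2), c(5, 5), c(1, 1)), "usable")
})

test_that("hazard-ratio estimation is unbiased at scale", {
  withr::with_seed(123, {
    betas <- sapply(1:50, function(i) {
      n <- 2000
      g <- rep(0:1, n / 2)
      t <- stats::rexp(n, 0.05 * 2^g)
      cens <- stats::runif(n, 0, 40)
      cox_fit(pmin(t, cens), as.integer(t <= cens),
              data.frame(g = g))$table$coef
    })
    expect_lt(abs(mean(betas) - log(2)), 0.05)
  })
})

test_that("univariate screen feeds the multivariate model", {
  withr::with_seed(44, {
    n <- 400
    x1 <- stats::rbinom(n, 1, 0.5)
    x2 <- stats::rnorm(n)               # pure noise
    t <- stats::rexp(n, 0.03 * exp(0.8 * x1))
    scr <- cox_screen(t, rep(1, n), data.frame(x1 = x1, x2 = x2))
    expect_true("x1" %in% scr$entered)
    expect_false("x2" %in% scr$entered)
    expect_equal(nrow(scr$univariate), 2)
    expect_equal(names(coef(scr$multivariate)), "x1")
  })
})
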