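test_that("KM matches the hand product-limit calculation", {
  km <- km_estimate(c(5, 10, 15), c(0, 1, 1))
  # censored at 5; at t=10: 2 at risk, 1 event -> 1/2; at t=15: 1 at risk -> 0
  expect_equal(km$time, c(10, 15))
  expect_equal(km$n_risk, c(2, 1))
  expect_equal(km$survival, c(0.5, 0))
  expect_equal(km_survival_at(km, c(0, 9.99, 10, 14, 15, 20)),
               c(1, 1, 0.5, 0.5, 0, 0))
})

test_that("all-censored data gives a flat survival curve at 1", {
  km <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_length(km$time, 0)
  expect_equal(km_survival_at(km, c(0, 5)), c(1, 1))
})

test_that("KM curves are monotone and agree with survival::survfit", {
  withr::with_seed(9, {
    t <- rexp(200); e <- rbinom(200, 1, 0.6)
  })
  km <- km_estimate(t, e)
  expect_true(all(diff(km$survival) <= 0))
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  expect_equal(km$survival, sf$surv[sf$n.event > 0], tolerance = 1e-10)
  # and with the naive risk-set oracle
  ora <- oracle_km(t, e)
  expect_equal(km$survival, ora$survival, tolerance = 1e-12)
})

test_that("log-rank matches the brute-force risk-set tally", {
  # group A events at 1,2,3; group B at 4,5,6; all observed.
  # Hand tally for group B: E = 3/6 + 3/5 + 3/4 + 1 + 1 + 1 = 4.85,
  # O = 3, U = -1.85; V = 0.25 + 0.24 + 0.1875 = 0.6775.
  t <- 1:6; e <- rep(1, 6); g <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chi_square, 1.85^2 / 0.6775, tolerance = 1e-12)
  expect_equal(unname(lr$expected["B"]), 4.85, tolerance = 1e-12)
  expect_equal(unname(lr$observed["B"]), 3)
  # observed and expected totals agree across groups
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-12)

  ora <- oracle_logrank(t, e, g == "B")
  expect_equal(lr$chi_square, ora$chi, tolerance = 1e-12)
})

test_that("log-rank is symmetric, label-invariant, and null on mirrored data", {
  # identical survival experience in both groups -> chi = 0, p = 1
  t <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e <- c(1, 0, 1, 1, 1, 0, 1, 1)
  g <- rep(c("x", "y"), each = 4)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)

  withr::with_seed(10, {
    t2 <- rexp(120); e2 <- rbinom(120, 1, 0.7); g2 <- rbinom(120, 1, 0.4)
  })
  a <- logrank_test(t2, e2, g2)
  b <- logrank_test(t2, e2, 1 - g2)
  expect_equal(a$chi_square, b$chi_square, tolerance = 1e-12)
  # agreement with survival::survdiff
  sd_ <- survival::survdiff(survival::Surv(t2, e2) ~ g2)
  expect_equal(a$chi_square, sd_$chisq, tolerance = 1e-10)

  expect_error(logrank_test(t2, e2, rep(1, 120)), "two groups")
})

test_that("Cox wrapper reports HR, CI, logPL and the AIC identity", {
  d <- sim_small_cohort(n = 400, seed = 11)
  d$hi <- as.integer(d$cvf_percent > 32)
  f <- fit_cox(d, c("hi", "age"))
  expect_equal(f$aic, -2 * f$log_partial_likelihood + 2 * f$k)
  expect_equal(f$k, 2)
  expect_equal(f$terms$hr, exp(f$terms$coef))
  expect_equal(f$terms$ci_lo, exp(f$terms$coef - 1.96 * f$terms$se))
  expect_equal(f$terms$ci_hi, exp(f$terms$coef + 1.96 * f$terms$se))
  expect_true(all(f$terms$p > 0 & f$terms$p <= 1))
  # CIs contain the point estimate
  expect_true(all(f$terms$ci_lo <= f$terms$hr & f$terms$hr <= f$terms$ci_hi))
  # matches survival::coxph directly
  direct <- survival::coxph(
    survival::Surv(time_composite_years, event_composite) ~ hi + age, data = d
  )
  expect_equal(f$terms$coef, unname(direct$coefficients), tolerance = 1e-6)

  expect_error(fit_cox(transform(d, event_composite = 0), "hi"),
               "at least one event")
})

test_that("a null binary covariate is covered and flagged separation is not", {
  cover <- logical(20)
  for (s in 1:20) {
    d <- simulate_cohort(cohort_spec(n = 1000, beta_cvf = 0, beta_bnp = 0,
                                     frailty_sd = 0, seed = 100 + s))
    d$grp <- withr::with_seed(200 + s, rbinom(nrow(d), 1, 0.5))
    f <- fit_cox(d, "grp")
    cover[s] <- (f$terms$coef - 1.96 * f$terms$se) <= 0 &&
      0 <= (f$terms$coef + 1.96 * f$terms$se)
  }
  expect_gte(mean(cover), 0.80)
})

test_that("the two-predictor ladder prefers CVF-adjusted models when CVF drives risk", {
  hits <- logical(8)
  for (s in 1:8) {
    d <- simulate_cohort(cohort_spec(n = 800, beta_bnp = 0, seed = 300 + s))
    lad <- two_predictor_ladder(d, predictors = c("age", "bmi"))
    hits[s] <- all(lad$aic_adjusted < lad$aic_single)
  }
  expect_gte(mean(hits), 0.75)
})

test_that("ladder handles collinear and empty predictor sets explicitly", {
  d <- sim_small_cohort(n = 300, seed = 12)
  d$cvf_copy <- d$cvf_percent
  lad <- two_predictor_ladder(d, predictors = "cvf_copy")
  expect_match(lad$note, "collinear")

  empty <- two_predictor_ladder(d, predictors = character())
  expect_equal(nrow(empty), 0)
})

test_that("backward elimination keeps a strong predictor, drops noise", {
  kept <- logical(10)
  for (s in 1:10) {
    d <- simulate_cohort(cohort_spec(n = 1000, beta_cvf = 1,
                                     beta_bnp = 0, frailty_sd = 0,
                                     seed = 400 + s))
    d$strong <- as.integer(d$cvf_percent > 32)
    withr::with_seed(500 + s, {
      for (j in 1:5) d[[paste0("noise", j)]] <- rnorm(nrow(d))
    })
    be <- backward_eliminate(d, c("strong", paste0("noise", 1:5)))
    kept[s] <- "strong" %in% be$selected
  }
  expect_gte(mean(kept), 0.90)

  # removal order reproducible for a fixed dataset
  d <- sim_small_cohort(n = 400, seed = 13)
  withr::with_seed(14, for (j in 1:3) d[[paste0("n", j)]] <- rnorm(nrow(d)))
  b1 <- backward_eliminate(d, c("lvef", paste0("n", 1:3)))
  b2 <- backward_eliminate(d, c("lvef", paste0("n", 1:3)))
  expect_identical(b1$elimination_path, b2$elimination_path)
  expect_identical(b1$selected, b2$selected)

  # no candidate passing the screen -> explicit empty-model status
  d$pure <- withr::with_seed(15, rep(c(0, 1), length.out = nrow(d)))
  be0 <- backward_eliminate(d, "pure", enter_alpha = 1e-6)
  expect_null(be0$model)
  expect_equal(be0$status, "no candidate retained")
})

test_that("restricted cubic spline basis is linear beyond the boundary knots", {
  x <- seq(-10, 110, by = 0.5)
  sb <- rcs_basis(x, knots = c(10, 35, 65, 90))
  expect_equal(sb$knots, c(10, 35, 65, 90))
  # second differences of every basis column vanish outside the boundary
  for (j in seq_len(ncol(sb$basis))) {
    col <- sb$basis[, j]
    d2 <- diff(col, differences = 2)
    outside <- x[-c(1, length(x))] < 10 | x[-c(1, length(x))] > 90.5
    expect_true(all(abs(d2[outside]) < 1e-8))
  }
  expect_error(rcs_basis(rep(1, 10), n_knots = 4), "distinct knots")
})

test_that("nonlinearity test has power for curvature, calibration for lines", {
  # quadratic log-hazard: strong rejection
  rej <- logical(10)
  for (s in 1:10) {
    withr::with_seed(600 + s, {
      n <- 800
      x <- rnorm(n)
      tt <- 10 * (-log(runif(n)) * exp(-0.5 * x^2))^(1 / 1.2)
      cens <- pmin(8, rexp(n, 0.2))
    })
    d <- data.frame(x = x, time_composite_years = pmin(tt, cens),
                    event_composite = as.integer(tt <= cens))
    rej[s] <- nonlinearity_test(d, "x")$p_value < 0.05
  }
  expect_gte(mean(rej), 0.8)

  # purely linear effect: rejects rarely
  rej0 <- logical(25)
  for (s in 1:25) {
    withr::with_seed(700 + s, {
      n <- 500
      x <- rnorm(n)
      tt <- 10 * (-log(runif(n)) * exp(-0.5 * x))^(1 / 1.2)
      cens <- pmin(8, rexp(n, 0.2))
    })
    d <- data.frame(x = x, time_composite_years = pmin(tt, cens),
                    event_composite = as.integer(tt <= cens))
    rej0[s] <- nonlinearity_test(d, "x")$p_value < 0.05
  }
  expect_lte(mean(rej0), 0.25)
})

test_that("group comparison dispatches by declared type only", {
  d <- sim_small_cohort(n = 400, seed = 16)
  d$grp <- ifelse(d$cvf_percent > 32, "high", "low")
  m <- compare_groups(d, "grp", "age", type = "mean")
  expect_equal(m$test, "t-test")
  expect_match(m$descriptives$summary[1], "\\(")
  md <- compare_groups(d, "grp", "ntprobnp", type = "median")
  expect_equal(md$test, "mann-whitney")
  ct <- compare_groups(d, "grp", "diabetes", type = "categorical")
  expect_equal(ct$test, "chi-squared")
  expect_true(all(c(m$p_value, md$p_value, ct$p_value) > 0))

  # identical proportions -> p = 1 by definition
  d2 <- data.frame(g = rep(c("a", "b"), each = 50),
                   v = rep(c(0, 1), 50))
  expect_equal(compare_groups(d2, "g", "v", type = "categorical")$p_value, 1)
})

test_that("logit-scale correlation is exact, guarded, and bounded", {
  x <- c(10, 25, 40, 60, 75, 90, 15, 33, 57, 80)
  y <- qlogis(x / 100)
  lc <- logit_correlation(x, y)
  expect_equal(lc$r, 1, tolerance = 1e-12)

  expect_error(logit_correlation(c(0, 50, 80), rnorm(3)), "no logit")
  ok <- logit_correlation(c(0, 50, 80, 20, 60), rnorm(5), clamp_epsilon = 0.5)
  expect_true(abs(ok$r) <= 1)
  expect_error(logit_correlation(rep(50, 5), rnorm(5)), "zero variance")

  # independent vectors: CI covers 0 most of the time
  cover <- logical(30)
  for (s in 1:30) {
    withr::with_seed(800 + s, {
      xi <- runif(124, 1, 99); yi <- rnorm(124)
    })
    ci <- logit_correlation(xi, yi)$ci95
    cover[s] <- ci[1] <= 0 && 0 <= ci[2]
  }
  expect_gte(mean(cover), 0.85)
})

test_that("Rubin pooling reproduces the textbook arithmetic", {
  f1 <- data.frame(term = "x", coef = 0, se = 1)
  f2 <- data.frame(term = "x", coef = 2, se = 1)
  p <- pool_rubin(list(f1, f2))
  expect_equal(p$coef, 1)
  expect_equal(p$b_between, 2)           # var(c(0, 2)) = 2
  expect_equal(p$se^2, 1 + 1.5 * 2)      # W + (1 + 1/m) B = 4
  # identical fits: B = 0, pooled se = within se
  pi <- pool_rubin(list(f1, f1, f1))
  expect_equal(pi$b_between, 0)
  expect_equal(pi$se, 1)
  # pooled se never below the mean within-imputation se
  expect_true(all(p$se >= sqrt(p$w_within)))
  expect_error(pool_rubin(list(f1)), ">= 2")
  expect_error(pool_rubin(list(f1, data.frame(term = "y", coef = 1, se = 1))),
               "mismatched")
})

test_that("printed-rate helper applies half-up rounding", {
  expect_equal(proportion_percent(4, 524, 2), 0.76)
  expect_equal(proportion_percent(11, 524, 2), 2.10)
  expect_equal(proportion_percent(0, 524, 2), 0)
  expect_equal(proportion_percent(1, 8, 1), 12.5)
  expect_equal(proportion_percent(1, 16, 1), 6.3)  # 6.25 rounds half-up
  expect_error(proportion_percent(5, 4, 1), "count <= n")
  expect_error(proportion_percent(1, 0, 1), "> 0")
})
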