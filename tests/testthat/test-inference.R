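test_that("Wald statistics match their closed forms", {
  ## null point
  w0 <- wald_test(c(0, 0, 0), diag(3))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  ## beta = (1,1), V = I: W = 2, chi2_2 survival = exp(-1)
  w <- wald_test(c(1, 1), diag(2))
  expect_equal(w$statistic, 2)
  expect_equal(w$df, 2L)
  expect_equal(w$p_value, exp(-1))
  ## scalar: 0.2^2 / 0.01 = 4
  w1 <- wald_test(0.2, matrix(0.01))
  expect_equal(w1$statistic, 4)
  expect_equal(w1$p_value, pchisq(4, 1, lower.tail = FALSE))
  expect_equal(w1$p_value, 0.0455, tolerance = 1e-4)
  ## singular covariance falls back to a pseudo-inverse with a warning
  Vs <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_warning(ws <- wald_test(c(1, 1), Vs), "pseudo-inverse")
  expect_true(is.finite(ws$statistic))
})

test_that("the Wald test errors without an interaction block", {
  sim <- simulate_city(scenario_truth(base_rate = 50), n_years = 2,
                       seed = 101)
  m0 <- tvdlnm(sim$series, "all", tv_config(interaction = FALSE))
  expect_error(wald_interaction_test(m0), "no interaction")
})

test_that("weighted trends reproduce closed-form normal equations", {
  ## exact linear data: slope exact, R^2 = 1, zero residuals, any weights
  tr <- suppressWarnings(wls_trend(0:2, c(0, 1, 2), ses = c(1, 1, 10)))
  expect_equal(tr$slope, 1)
  expect_equal(tr$r_squared, 1)
  expect_lt(max(abs(tr$residuals)), 1e-12)
  tr_eq <- suppressWarnings(wls_trend(0:2, c(0, 1, 2)))
  expect_equal(tr_eq$slope, 1)

  ## non-collinear case against hand-computed weighted normal equations
  x <- c(0, 1, 2, 3, 4); y <- c(0.1, 1.2, 1.8, 3.3, 3.9)
  se <- c(0.5, 1, 0.8, 2, 0.6)
  w <- 1 / se^2
  sw <- sum(w); xw <- sum(w * x) / sw; yw <- sum(w * y) / sw
  slope_hand <- sum(w * (x - xw) * (y - yw)) / sum(w * (x - xw)^2)
  tr2 <- wls_trend(x, y, se)
  expect_equal(tr2$slope, slope_hand, tolerance = 1e-12)
  expect_equal(tr2$intercept, yw - slope_hand * xw, tolerance = 1e-12)
  resid <- y - (tr2$intercept + tr2$slope * x)
  s2 <- sum(w * resid^2) / (length(x) - 2)
  expect_equal(tr2$slope_se, sqrt(s2 / sum(w * (x - xw)^2)),
               tolerance = 1e-12)
  expect_equal(tr2$pearson_r, cor(x, y))       # unweighted, as displayed

  ## equal standard errors reduce to OLS exactly
  tr3 <- wls_trend(x, y, rep(2, 5))
  ols <- lm(y ~ x)
  expect_equal(tr3$slope, unname(coef(ols)[2]))
  expect_equal(tr3$slope_se, summary(ols)$coefficients[2, 2])
  expect_equal(tr3$r_squared, summary(ols)$r.squared)

  ## degenerate inputs
  cst <- suppressWarnings(wls_trend(x, rep(3, 5)))
  expect_equal(cst$slope, 0)
  expect_equal(cst$r_squared, 0)
  expect_error(wls_trend(rep(2000, 4), 1:4), "constant")
  expect_error(wls_trend(1:2, 1:2), "at least 3")
})

test_that("coupling regressions behave like trends with another regressor", {
  x <- c(18, 19, 20, 21, 22)
  cp <- suppressWarnings(coupling_regression(x, 2 * x))
  expect_equal(cp$slope, 2)
  expect_equal(cp$pearson_r, 1)
  ## under independence the p-value is approximately uniform
  set.seed(111)
  ps <- replicate(300, coupling_regression(rnorm(12), rnorm(12))$p_value)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  ## a generator with coupled indicators recovers the coupling slope
  set.seed(112)
  slopes <- replicate(100, {
    amt <- rnorm(19, 19.6, 0.5)
    mmt <- 10 + 0.5 * amt + rnorm(19, 0, 0.15)
    coupling_regression(amt, mmt)$slope
  })
  expect_equal(median(slopes), 0.5, tolerance = 0.05)
})

test_that("the missingness chi-square equals the textbook statistic", {
  ## perfectly proportional table
  prop <- rbind(c(10, 20), c(30, 60))
  r0 <- missingness_chisq(prop)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1)
  ## hand computation of sum (O-E)^2 / E for [[10,20],[20,10]]
  tab <- rbind(c(10, 20), c(20, 10))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - E)^2 / E)
  r1 <- missingness_chisq(tab)
  expect_equal(r1$statistic, hand, tolerance = 1e-12)
  expect_equal(r1$statistic, 20 / 3, tolerance = 1e-12)  # 6.667
  expect_equal(r1$df, 1L)
  ## df arithmetic and degenerate marginals
  expect_equal(suppressWarnings(
    missingness_chisq(cbind(c(5, 10), c(8, 4), c(3, 3))))$df, 2L)
  expect_error(missingness_chisq(rbind(c(0, 0), c(1, 2))), "marginal")
  expect_error(missingness_chisq(matrix(1:9, 3, 3)), "2 x k")
})
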