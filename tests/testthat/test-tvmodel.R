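sim2 <- simulate_city(scenario_truth(base_rate = 50), n_years = 2, seed = 61)

test_that("design columns follow the block arithmetic", {
  cfg <- tv_config()
  d <- assemble_design(sim2$series, "all", cfg)
  vxvl <- basis_dim(d$exposure_spec) * basis_dim(d$lag_spec)
  n_years <- nrow(sim2$series) / 365.25
  df_time <- round(cfg$time_df_per_year * n_years)
  expect_equal(length(d$blocks$time), df_time)
  expect_equal(df_time, 20)           # 10 df per year, two years
  expect_equal(ncol(d$X),
               1 + vxvl * 2 + 6 + 1 + 1 + cfg$rh_df + df_time)
  ## interaction block is the crossbasis scaled by centred time in years
  expect_equal(unname(d$X[, d$blocks$interaction]),
               unname(d$X[, d$blocks$crossbasis] * d$s))
  ## without the interaction the design loses exactly vx*vl columns
  d0 <- assemble_design(sim2$series, "all",
                        tv_config(interaction = FALSE))
  expect_equal(ncol(d$X) - ncol(d0$X), vxvl)
  ## leading lag-window rows are masked out
  expect_false(any(d$rows_used[1:cfg$max_lag]))
  expect_error(assemble_design(sim2$series, "nope", cfg), "stratum")
})

test_that("moving-average windows match a brute-force oracle", {
  s <- sim2$series
  for (lags in c(1L, 2L)) {
    d <- assemble_design(s, "all", tv_config(ma_lags = lags))
    pm <- d$X[, "pm10_ma"]
    n <- nrow(s)
    oracle <- sapply(seq_len(n), function(t) {
      if (t <= lags) return(NA_real_)
      mean(s$pm10[(t - lags):t])
    })
    expect_equal(unname(pm), oracle)
  }
  ## the documented toy: [70, 80, 90] on day 3
  expect_equal(tvdlnm:::lagged_mean(c(70, 80, 90), 2)[3], 80)
  expect_equal(tvdlnm:::lagged_mean(c(70, 80, 90), 1)[3], 85)
})

test_that("time-slice extraction follows the closed-form block algebra", {
  ## 1-dimensional toy: beta_main 0.1, beta_int 0.02, s = 3
  V <- matrix(c(0.01, 0.001, 0.001, 0.004), 2, 2)
  fake <- structure(list(
    fit = structure(list(coefficients = c(cb = 0.1, `cb:s` = 0.02),
                         vcov = V), class = "qpfit"),
    design = list(
      dates = as.Date("2000-01-01") + 0:9,
      s = ((1:10) - 1) / 1,            # day index minus 1, in "years"
      blocks = list(crossbasis = 1L, interaction = 2L),
      crossbasis = matrix(0, 1, 1, dimnames = list(NULL, "cb")),
      exposure_spec = NULL, lag_spec = NULL,
      config = list(max_lag = 0L))
  ), class = "tvdlnm")
  sl <- coefficients_at_time(fake, as.Date("2000-01-04"))  # s = 3
  expect_equal(unname(sl$beta), 0.1 + 3 * 0.02)
  expect_equal(unname(drop(sl$vcov)),
               0.01 + 9 * 0.004 + 2 * 3 * 0.001)
  ## s = 0: the main block verbatim
  sl0 <- coefficients_at_time(fake, as.Date("2000-01-01"))
  expect_equal(unname(sl0$beta), 0.1)
  expect_equal(unname(drop(sl0$vcov)), 0.01)
  expect_error(coefficients_at_time(fake, as.Date("1999-01-01")),
               "outside")
})

test_that("a model without interaction slices identically at every centre", {
  m0 <- tvdlnm(sim2$series, "all", tv_config(interaction = FALSE))
  s1 <- coefficients_at_time(m0, as.Date("2000-07-01"))
  s2 <- coefficients_at_time(m0, as.Date("2001-07-01"))
  expect_equal(s1$beta, s2$beta)
  expect_equal(s1$vcov, s2$vcov)
})

test_that("results are invariant to the affine time-centring choice", {
  cfg <- tv_config()
  m1 <- tvdlnm(sim2$series, "all", cfg)
  m2 <- tvdlnm(sim2$series, "all", cfg, t_ref = 100)
  ## Wald statistic on the interaction is identical
  w1 <- wald_interaction_test(m1)
  w2 <- wald_interaction_test(m2)
  expect_equal(w1$statistic, w2$statistic, tolerance = 1e-8)
  ## the fitted surface at a common centre is identical
  ctr <- as.Date("2001-03-01")
  sa <- coefficients_at_time(m1, ctr)
  sb <- coefficients_at_time(m2, ctr)
  expect_equal(sa$beta, sb$beta, tolerance = 1e-6)
  grid <- seq(10, 28, by = 0.5)
  ca <- predict_curve(sa, grid, reference = 20)
  cb <- predict_curve(sb, grid, reference = 20)
  expect_equal(ca$log_crr, cb$log_crr, tolerance = 1e-6)
  expect_equal(ca$se, cb$se, tolerance = 1e-6)
})

test_that("fitted totals and residual accessors line up with the mask", {
  m <- tvdlnm(sim2$series, "all")
  f <- fitted(m)
  expect_equal(sum(is.na(f)), sum(!m$design$rows_used))
  expect_equal(sum(f, na.rm = TRUE),
               sum(m$design$y[m$design$rows_used]), tolerance = 1e-6)
  r <- residuals(m, type = "response")
  ok <- m$design$rows_used
  expect_equal(r[ok], m$design$y[ok] - f[ok])
})
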