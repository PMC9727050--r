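test_that("the generator is bitwise deterministic in its seed", {
  a <- simulate_city(scenario_truth(base_rate = 60), n_years = 2, seed = 121)
  b <- simulate_city(scenario_truth(base_rate = 60), n_years = 2, seed = 121)
  expect_identical(a, b)
  c <- simulate_city(scenario_truth(base_rate = 60), n_years = 2, seed = 122)
  expect_false(identical(a$series$deaths_all, c$series$deaths_all))
})

test_that("a null surface with no extras gives plain Poisson counts", {
  tr <- scenario_truth(base_rate = 200, beta_cold = 0, beta_heat = 0,
                       overdispersion = 1, trend_per_year = 0,
                       mort_seasonal_amp = 0, holiday_effect = 0,
                       dow_effects = rep(0, 6), rh_effect = 0,
                       pm10_effect = 0)
  sim <- simulate_city(tr, n_years = 10, seed = 131)
  y <- sim$series$deaths_all
  expect_lt(abs(mean(y) / 200 - 1), 0.01)       # mean within 1%
  expect_lt(abs(var(y) / mean(y) - 1), 0.05)    # no overdispersion
})

test_that("the gamma frailty induces the requested variance inflation", {
  tr <- scenario_truth(base_rate = 200, beta_cold = 0, beta_heat = 0,
                       overdispersion = 1.5, trend_per_year = 0,
                       mort_seasonal_amp = 0, holiday_effect = 0,
                       dow_effects = rep(0, 6), rh_effect = 0,
                       pm10_effect = 0)
  sim <- simulate_city(tr, n_years = 10, seed = 132)
  y <- sim$series$deaths_all
  expect_equal(var(y) / mean(y), 1.5, tolerance = 0.12)
})

test_that("truth tables agree with the closed-form surface", {
  tr <- scenario_truth(mmt_drift = 0.1)
  sim <- simulate_city(tr, n_years = 5, seed = 141)
  tt <- merge(sim$truth_mmt, sim$truth_crr, by = "year")
  ## cRR at P99 recomputed independently from the quadratic definition
  for (i in seq_len(nrow(tt))) {
    m <- tr$mmt0 + tr$mmt_drift * tt$t_years[i]
    dx <- tt$p99[i] - m
    slope <- if (dx < 0) tr$beta_cold else tr$beta_heat
    expect_equal(tt$crr_true_p99[i], exp(slope * dx^2), tolerance = 1e-12)
  }
  ## the true MMT at mid-series year equals mmt0 (odd year count)
  mid <- (nrow(tt) + 1) / 2
  expect_equal(tt$mmt_true[mid], tr$mmt0, tolerance = 0.01)
  ## lag weights normalised
  expect_equal(sum(sim$lag_weights), 1)
  ## rates must stay finite
  expect_error(simulate_city(scenario_truth(beta_heat = 50,
                                            overdispersion = 1),
                             n_years = 2, seed = 1), "finite")
})

test_that("weather calibration matches the target climate", {
  sim <- simulate_city(scenario_truth(), n_years = 19, seed = 151)
  tm <- sim$series$tmean
  expect_gt(mean(tm), 19.1); expect_lt(mean(tm), 20.1)
  expect_lte(min(tm), 8); expect_gte(max(tm), 27)
  rh <- sim$series$rh
  expect_true(all(rh >= 0 & rh <= 100))
  expect_equal(mean(rh), 80, tolerance = 2)
  expect_true(all(sim$series$pm10 > 0))
  ## southern-hemisphere seasonality: January hotter than July
  mo <- format(sim$series$date, "%m")
  expect_gt(mean(tm[mo == "01"]), mean(tm[mo == "07"]) + 5)
})

test_that("individual records conserve and partition the daily totals", {
  sim <- flat_city(2, seed = 161, base_rate = 10)
  rec0 <- simulate_individual_records(sim$series, seed = 5)
  cc <- build_stratum_counts(rec0, sim$series$date)
  ## zero missingness: exact reconstruction of the daily series
  expect_equal(cc$deaths_all, unname(sim$series$deaths_all))
  expect_equal(cc$deaths_female + cc$deaths_male, cc$deaths_all)

  rec <- simulate_individual_records(sim$series, seed = 6,
                                     missing_rates = c(ethnicity = 0.1))
  cc2 <- build_stratum_counts(rec, sim$series$date)
  n <- nrow(rec)
  eth_total <- sum(cc2$deaths_white) + sum(cc2$deaths_nonwhite)
  ## binomial expectation: ~90% retained, tolerance 3 sd
  expect_lt(abs(eth_total - 0.9 * n), 3 * sqrt(n * 0.9 * 0.1) + 1)

  ## missingness unrelated to stratum: chi-square p is approximately uniform
  set.seed(7)
  ps <- replicate(200, {
    sex <- sample(c("f", "m"), 400, TRUE)
    missing <- runif(400) < 0.15
    missingness_chisq(table(missing, sex))$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(simulate_individual_records(sim$series,
                                           sex_mix = c(f = 0.6, m = 0.6)),
               "sum to 1")
})
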