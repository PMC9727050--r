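## helper: a 1-dimensional slice whose cumulative prediction vector is (x, 0)
scalar_slice <- function(beta1 = 0.05, var1 = 0) {
  structure(list(
    centre = as.Date("2000-07-01"),
    beta = c(b1 = beta1, b2 = 0),
    vcov = diag(c(var1, 0)),
    exposure_spec = basis_spec("linear", boundary_knots = c(0, 40),
                               intercept = FALSE),
    lag_spec = basis_spec("linear", boundary_knots = c(-0.5, 0.5),
                          intercept = TRUE),
    max_lag = 0L), class = "time_slice")
}

test_that("null coefficients give a flat unit RR curve", {
  sl <- scalar_slice(beta1 = 0, var1 = 0.01)
  cp <- predict_curve(sl, grid = seq(5, 35, by = 1), reference = 20)
  expect_equal(cp$crr, rep(1, nrow(cp)))
  ## se comes from the covariance alone: |x - ref| * sqrt(var)
  expect_equal(cp$se, abs(cp$grid - 20) * 0.1)
})

test_that("the scalar closed form and the reference identity hold", {
  sl <- scalar_slice(beta1 = 0.05, var1 = 4e-4)
  cp <- predict_curve(sl, grid = c(15, 20, 25), reference = 20)
  expect_equal(cp$crr[3], exp(0.25))
  expect_equal(cp$crr[2], 1)            # exactly 1 at the reference
  expect_equal(cp$se[2], 0)
  expect_true(all(cp$crr_low <= cp$crr & cp$crr <= cp$crr_high))
  expect_error(predict_curve(sl, grid = c(15, 18), reference = 20),
               "reference")
})

test_that("a symmetric quadratic curve has its MMT at the vertex", {
  espec <- basis_spec("ns", 21, c(11, 31))
  x <- seq(11, 31, by = 0.1)              # symmetric around 21
  B <- cbind(1, ns_basis(x, espec))
  co <- qr.solve(B, 0.003 * (x - 21)^2)   # projection is symmetric too
  lspec <- place_lag_knots(21, 3)
  csum <- colSums(ns_basis(0:21, lspec))
  vl <- length(csum)
  ## beta such that w(x)' beta = ns(x) gamma: spread gamma over lag column 1
  beta <- as.vector(t(outer(co[-1], c(1 / csum[1], rep(0, vl - 1)))))
  sl <- structure(list(centre = as.Date("2000-07-01"), beta = beta,
                       vcov = diag(length(beta)) * 0,
                       exposure_spec = espec, lag_spec = lspec,
                       max_lag = 21L), class = "time_slice")
  mmt <- find_mmt(sl, tmean_subset = x, tv_config(n_boot = 50L), seed = 3)
  expect_equal(mmt$mmt, 21, tolerance = 0.1 + 1e-9)
  ## degenerate bootstrap under a zero covariance
  expect_equal(mmt$eci_low, mmt$eci_high)
  expect_equal(mmt$se, 0)
  expect_false(mmt$boundary_dominated)
})

test_that("monotone curves clamp the MMT to the constraint boundary", {
  sl <- scalar_slice(beta1 = -0.05, var1 = 1e-6)   # risk falls with heat
  cfg <- tv_config(n_boot = 50L)
  mmt <- find_mmt(sl, tmean_subset = seq(5, 35, by = 0.1), cfg, seed = 5)
  p99 <- unname(quantile(seq(5, 35, by = 0.1), 0.99))
  expect_equal(mmt$mmt, p99, tolerance = 0.11)
  expect_true(mmt$at_boundary)
  expect_true(mmt$boundary_dominated)
  ## flat curve: undefined minimum
  expect_error(find_mmt(scalar_slice(0, 0.01), seq(5, 35), cfg), "undefined")
})

test_that("MMT search is reference-invariant and seed-deterministic", {
  sim <- simulate_city(scenario_truth(base_rate = 80), n_years = 2,
                       seed = 71)
  m <- tvdlnm(sim$series, "all")
  sl <- coefficients_at_time(m, as.Date("2001-07-01"))
  cfg <- tv_config(n_boot = 100L)
  tm <- sim$series$tmean
  m1 <- find_mmt(sl, tm, cfg, seed = 9)
  m2 <- find_mmt(sl, tm, cfg, seed = 9)
  expect_identical(m1, m2)                       # bitwise determinism
  m3 <- find_mmt(sl, tm, cfg, seed = 10)
  expect_false(identical(m1$se, m3$se))
  ## curves re-centred anywhere differ by a constant -> same argmin
  grid <- seq(quantile(tm, 0.01), quantile(tm, 0.99), by = 0.1)
  c1 <- predict_curve(sl, grid, reference = grid[1])
  c2 <- predict_curve(sl, grid, reference = grid[length(grid)])
  expect_equal(which.min(c1$log_crr), which.min(c2$log_crr))
  expect_equal(grid[which.min(c1$log_crr)], m1$mmt, tolerance = 0.1 + 1e-9)
  ## widening the constraint can only find an equal-or-lower minimum
  cfg_wide <- tv_config(n_boot = 100L,
                        mmt_constraint_percentiles = c(0.1, 99.9))
  m4 <- find_mmt(sl, tm, cfg_wide, seed = 9)
  at <- function(x) predict_curve(sl, c(5, x, 35), reference = 5,
                                  warn_extrapolation = FALSE)$log_crr[2]
  ## grids of the two windows are offset by a sub-step amount, so allow
  ## curve variation at that scale
  expect_lte(at(m4$mmt), at(m1$mmt) + 1e-4)
})

test_that("bootstrap eCIs reach nominal coverage when the truth is in-span", {
  ## the generating surface is built inside the model's own crossbasis space,
  ## so the estimator is correctly specified and the parametric-bootstrap
  ## interval should cover the true argmin at its nominal rate
  nrep <- 40
  cover <- logical(nrep)
  for (r in seq_len(nrep)) {
    wx <- flat_city(3, seed = 500 + r, base_rate = 100)
    s <- wx$series
    espec <- place_exposure_knots(s$tmean, 75)
    lspec <- place_lag_knots(21, 3)
    ## exposure curve: LS projection of a U-shape into the exposure span
    xs <- s$tmean
    gam <- qr.solve(cbind(1, ns_basis(xs, espec)), 0.003 * (xs - 20)^2)[-1]
    ## lag weights: projection of an exponential decay into the lag span
    C <- ns_basis(0:21, lspec)
    del <- qr.solve(C, {h <- exp(-(0:21) / 3); h / sum(h)})
    beta_true <- as.vector(t(outer(gam, del)))
    cb <- build_crossbasis(s$tmean, espec, lspec, 21L)
    eta <- log(100) + drop(unclass(cb) %*% beta_true)
    ok <- attr(cb, "complete")
    set.seed(600 + r)
    s$deaths_all[ok] <- rpois(sum(ok), exp(eta[ok]))
    m <- tvdlnm(s, "all")
    sl <- coefficients_at_time(m, as.Date("2001-07-01"))
    est <- find_mmt(sl, s$tmean, tv_config(n_boot = 200L), seed = 700 + r)
    ## true argmin of the in-span curve over the same constrained grid
    grid <- seq(est$constrained_range[1], est$constrained_range[2], by = 0.1)
    truth_curve <- drop(ns_basis(grid, espec) %*% gam)
    mmt_true <- grid[which.min(truth_curve)]
    cover[r] <- est$eci_low - 0.05 <= mmt_true &
      mmt_true <= est$eci_high + 0.05
  }
  ## binomial band for nominal 95% over 40 replicates
  expect_gte(mean(cover), 33 / 40)
})

test_that("annual indicators report ordered anchors and re-centred cRRs", {
  sim <- simulate_city(scenario_truth(base_rate = 100), n_years = 3,
                       seed = 81)
  m <- tvdlnm(sim$series, "all")
  a <- annual_indicators(m, 2001, seed = 11)
  expect_true(a$p1 <= a$p10 && a$p10 <= a$p90 && a$p90 <= a$p99)
  expect_true(a$mmt >= a$p1 && a$mmt <= a$p99)
  expect_true(all(c("crr_extreme_cold", "crr_moderate_cold",
                    "crr_moderate_heat", "crr_extreme_heat",
                    "crr_extreme_heat_low", "crr_extreme_heat_high")
                  %in% names(a)))
  expect_true(a$crr_extreme_heat_low <= a$crr_extreme_heat)
  expect_error(annual_indicators(m, 2019, seed = 1), "not inside")
  s2 <- sim$series
  s2$tmean[format(s2$date, "%Y") == "2001"] <- NA
  m2 <- list(dates = s2$date, series_tmean = s2$tmean)
  class(m2) <- "tvdlnm"
  expect_error(annual_indicators(m2, 2001, tv_config(), seed = 1),
               "missing temperatures")
})

test_that("temperature trends recover a generated warming slope", {
  set.seed(91)
  dates <- seq(as.Date("2000-01-01"), as.Date("2009-12-31"), by = "day")
  yrs <- as.integer(format(dates, "%Y"))
  drift <- 0.05 * (yrs - 2000)
  tmean <- 20 + 5 * cos(2 * pi * as.integer(format(dates, "%j")) / 365.25) +
    drift + rnorm(length(dates), 0, 1.5)
  s <- daily_series(data.frame(date = dates, tmean = tmean,
                               deaths_all = rpois(length(dates), 5)))
  tt <- suppressWarnings(temperature_trends(s))
  amt <- tt$trends[tt$trends$indicator == "amt", ]
  expect_lt(abs(amt$slope - 0.05), 0.02)
  expect_lt(amt$p, 0.01)
  ## identical repeated years (2001-2003, no leap day): exactly zero slope
  d3 <- seq(as.Date("2001-01-01"), as.Date("2003-12-31"), by = "day")
  cyc <- 20 + 5 * sin(2 * pi * (1:365) / 365)
  s3 <- daily_series(data.frame(date = d3,
                                tmean = rep(cyc, 3), deaths_all = 1L))
  tab <- suppressWarnings(temperature_trends(s3))$table
  expect_lt(diff(range(tab$amt)), 1e-12)
  tr3 <- suppressWarnings(temperature_trends(s3))$trends
  expect_equal(tr3$slope[tr3$indicator == "amt"], 0, tolerance = 1e-10)
  expect_error(temperature_trends(s[1:400, ]), "3 calendar years")
})
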