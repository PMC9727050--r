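#' Ground-truth scenario for the synthetic city generator
#'
#' Defines a complete generative law for daily mortality-weather series with
#' a known, closed-form exposure-lag-response surface, so that every pipeline
#' stage can be validated against truth.  The surface is separable,
#' `f(x, l; t) = g(x; t) * h(l)`, with
#' `g(x; t) = beta_cold * (x - m(t))^2` below and
#' `beta_heat * (x - m(t))^2` above the drifting minimum
#' `m(t) = mmt0 + mmt_drift * t` (t in years, centred mid-series), and lag
#' weights `h(l)` proportional to `exp(-l / lag_tau)` normalised to sum to 1
#' over lags 0..21.  The implied lag-cumulated log relative risk is therefore
#' simply `g(x; t)`.  Weather emulates a subtropical Southern-hemisphere
#' city: temperature peaks in early January around a 19.6 C mean with roughly
#' a 7-28 C range; counts are overdispersed via a gamma frailty.
#'
#' Default effect sizes are calibrated to published urban
#' temperature-mortality surfaces: a cumulative RR near 1.3 at the 1st
#' temperature percentile and near 1.2 at the 99th, an MMT in the low 20s
#' drifting by about +0.09 C per year, and quasi-Poisson overdispersion 1.3.
#'
#' @param base_rate expected deaths/day at the MMT mid-series (baseline
#'   scale). Default 600.
#' @param trend_per_year linear trend of the log baseline per year.
#' @param mort_seasonal_amp amplitude of the winter-peaking annual harmonic
#'   on the log baseline.
#' @param mmt0 true MMT (degrees C) at mid-series.
#' @param mmt_drift linear MMT drift, degrees C per year.
#' @param beta_cold,beta_heat quadratic slopes of the log cumulative RR per
#'   (degree C)^2 on the cold and heat side of the MMT.
#' @param lag_tau exponential decay constant (days) of the lag weights.
#' @param overdispersion variance/mean ratio `omega >= 1` of daily counts.
#' @param dow_effects length-6 log-rate offsets for Tuesday..Sunday versus
#'   Monday.
#' @param holiday_effect log-rate offset on holidays.
#' @param rh_effect,pm10_effect log-rate slopes per unit of the centred
#'   confounders.
#' @param tmean_mean,tmean_amp seasonal mean and summer amplitude of daily
#'   temperature; `tmean_winter_scale` stretches the cold half-wave
#'   (subtropical winters dip further below the mean than summers rise above
#'   it).
#' @param tmean_ar,tmean_sd AR(1) coefficient and stationary sd of the
#'   temperature noise.
#' @param rh_mean,rh_sd,rh_ar relative humidity process (clipped to
#'   \[0, 100\]); `rh_tmean_cor` couples it negatively to temperature noise.
#' @param pm10_median,pm10_sd_log,pm10_ar log-scale AR(1) PM10 process.
#' @return an object of class `scenario_truth`.
#' @export
scenario_truth <- function(base_rate = 600,
                           trend_per_year = 0.005,
                           mort_seasonal_amp = 0.05,
                           mmt0 = 19,
                           mmt_drift = 0.09,
                           beta_cold = 0.0026,
                           beta_heat = 0.0028,
                           lag_tau = 6.5,
                           overdispersion = 1.3,
                           dow_effects = c(-0.005, -0.01, -0.01, -0.005,
                                           0.005, 0.01),
                           holiday_effect = 0.02,
                           rh_effect = 5e-4,
                           pm10_effect = 8e-4,
                           tmean_mean = 19.6,
                           tmean_amp = 5.8,
                           tmean_winter_scale = 1.5,
                           tmean_ar = 0.85,
                           tmean_sd = 1.8,
                           rh_mean = 80, rh_sd = 7, rh_ar = 0.8,
                           rh_tmean_cor = -0.3,
                           pm10_median = 35, pm10_sd_log = 0.35,
                           pm10_ar = 0.8) {
  stopifnot(base_rate > 0, overdispersion >= 1, lag_tau > 0,
            length(dow_effects) == 6, tmean_sd > 0,
            abs(tmean_ar) < 1, abs(rh_ar) < 1, abs(pm10_ar) < 1)
  structure(as.list(environment()), class = "scenario_truth")
}

#' True lag-cumulated log relative risk of a scenario
#'
#' `log cRR_true(x, t) = g(x; t) - g(m(t); t) = g(x; t)` in closed form.
#'
#' @param truth a [scenario_truth()].
#' @param x temperature(s), degrees C.
#' @param t_years time in years relative to the series midpoint.
#' @return numeric vector of log cumulative relative risks.
#' @export
true_log_crr <- function(truth, x, t_years = 0) {
  m <- truth$mmt0 + truth$mmt_drift * t_years
  dx <- x - m
  ifelse(dx < 0, truth$beta_cold, truth$beta_heat) * dx^2
}

#' True MMT of a scenario at a time point
#' @inheritParams true_log_crr
#' @return degrees C.
#' @export
true_mmt <- function(truth, t_years = 0) truth$mmt0 + truth$mmt_drift * t_years

ar1 <- function(n, phi, sd_stationary, innovations = NULL) {
  e <- innovations %||% stats::rnorm(n)
  e <- e * sd_stationary * sqrt(1 - phi^2)
  x <- stats::filter(e, phi, method = "recursive",
                     init = stats::rnorm(1) * sd_stationary)
  as.double(x)
}

## Fixed synthetic holiday calendar: Brazilian national/state fixed dates
## (moveable feasts approximated by fixed days).
synthetic_holidays <- function(dates) {
  md <- format(dates, "%m-%d")
  md %in% c("01-01", "01-25", "02-24", "04-21", "05-01", "06-11",
            "07-09", "09-07", "10-12", "11-02", "11-15", "12-25")
}

#' Simulate a synthetic city's daily mortality-weather series
#'
#' Generates `n_years` calendar years (starting 2000-01-01) of daily mean
#' temperature (asymmetric seasonal cycle peaking mid-January plus AR(1)
#' noise), relative humidity and PM10 (correlated AR(1) processes), a fixed
#' synthetic holiday calendar, and overdispersed daily death counts around
#' `exp(baseline + sum_l g(tmean[t-l]; t) h(l) + confounder terms)` with a
#' gamma frailty giving variance/mean = `overdispersion`.  A 21-day weather
#' burn-in precedes day one so the first rows carry complete lag histories.
#'
#' @param truth a [scenario_truth()].
#' @param n_years number of calendar years (>= 2).
#' @param seed integer seed; identical seeds give bitwise identical output.
#' @return class `sim_city`: list with `series` (a [daily_series()] with a
#'   `deaths_all` column), `truth_mmt` (per-year true MMT at 1 July),
#'   `truth_crr` (per-year true cRR at that year's empirical
#'   P1/P10/P90/P99), `truth` (the scenario), and `lag_weights`.
#' @export
simulate_city <- function(truth = scenario_truth(), n_years = 19L,
                          seed = 1L) {
  stopifnot(inherits(truth, "scenario_truth"), n_years >= 2)
  set.seed(seed)
  max_lag <- 21L
  start <- as.Date("2000-01-01")
  end <- as.Date(sprintf("%d-12-31", 2000L + n_years - 1L))
  dates <- seq(start, end, by = "day")
  n <- length(dates)
  ## weather gets a burn-in so day 1 has a full lag history
  wdates <- seq(start - max_lag, end, by = "day")
  nw <- length(wdates)

  ## temperature: asymmetric seasonal cycle (summer peak ~15 Jan) + AR(1)
  doy <- as.integer(format(wdates, "%j"))
  cyc <- cos(2 * pi * (doy - 15) / 365.25)
  cyc <- ifelse(cyc >= 0, cyc, truth$tmean_winter_scale * cyc)
  seasonal <- truth$tmean_amp * (cyc - mean(cyc))
  tmean_w <- truth$tmean_mean + seasonal +
    ar1(nw, truth$tmean_ar, truth$tmean_sd)
  tnoise <- tmean_w - truth$tmean_mean - seasonal

  ## humidity, negatively coupled to the temperature noise; PM10 log-AR(1)
  z <- truth$rh_tmean_cor * (tnoise / truth$tmean_sd) +
    sqrt(1 - truth$rh_tmean_cor^2) * ar1(nw, truth$rh_ar, 1)
  rh_w <- pmin(100, pmax(0, truth$rh_mean + truth$rh_sd * z))
  pm10_w <- exp(log(truth$pm10_median) +
                  ar1(nw, truth$pm10_ar, truth$pm10_sd_log))

  keep <- (max_lag + 1L):nw
  t_years <- (seq_len(n) - (n + 1) / 2) / 365.25

  ## lag-weighted surface contribution: sum_l g(tmean[t-l]; t) h(l)
  h <- exp(-(0:max_lag) / truth$lag_tau)
  h <- h / sum(h)
  surf <- numeric(n)
  for (l in 0:max_lag)
    surf <- surf + h[l + 1L] * true_log_crr(truth, tmean_w[keep - l], t_years)

  holiday <- synthetic_holidays(dates)
  dow <- as.integer(format(dates, "%u"))
  dow_eff <- c(0, truth$dow_effects)[dow]
  season_mort <- truth$mort_seasonal_amp *
    cos(2 * pi * (as.integer(format(dates, "%j")) - 196) / 365.25)
  eta <- log(truth$base_rate) + truth$trend_per_year * t_years +
    season_mort + dow_eff + truth$holiday_effect * holiday +
    truth$rh_effect * (rh_w[keep] - truth$rh_mean) +
    truth$pm10_effect * (pm10_w[keep] - truth$pm10_median) + surf
  lambda <- exp(eta)
  if (any(!is.finite(lambda)))
    stop("scenario implies non-finite rates; check effect sizes")
  if (truth$overdispersion > 1) {
    shape <- lambda / (truth$overdispersion - 1)
    frailty <- stats::rgamma(n, shape = shape, rate = shape)
    deaths <- stats::rpois(n, lambda * frailty)
  } else {
    deaths <- stats::rpois(n, lambda)
  }

  series <- daily_series(data.frame(
    date = dates, tmean = tmean_w[keep], rh = rh_w[keep],
    pm10 = pm10_w[keep], holiday = holiday, deaths_all = deaths))

  yrs <- as.integer(format(dates, "%Y"))
  uy <- sort(unique(yrs))
  mid <- as.Date(sprintf("%d-07-01", uy))
  ty_mid <- (match(mid, dates) - (n + 1) / 2) / 365.25
  truth_mmt <- data.frame(year = uy, t_years = ty_mid,
                          mmt_true = true_mmt(truth, ty_mid))
  truth_crr <- do.call(rbind, lapply(seq_along(uy), function(i) {
    tm <- series$tmean[yrs == uy[i]]
    q <- stats::quantile(tm, c(0.01, 0.10, 0.90, 0.99), type = 7)
    data.frame(year = uy[i],
               p1 = q[[1]], p10 = q[[2]], p90 = q[[3]], p99 = q[[4]],
               crr_true_p1 = exp(true_log_crr(truth, q[[1]], ty_mid[i])),
               crr_true_p10 = exp(true_log_crr(truth, q[[2]], ty_mid[i])),
               crr_true_p90 = exp(true_log_crr(truth, q[[3]], ty_mid[i])),
               crr_true_p99 = exp(true_log_crr(truth, q[[4]], ty_mid[i])))
  }))
  structure(list(series = series, truth_mmt = truth_mmt,
                 truth_crr = truth_crr, truth = truth, lag_weights = h,
                 seed = seed),
            class = "sim_city")
}

#' @export
print.sim_city <- function(x, ...) {
  s <- x$series
  cat(sprintf("synthetic city: %d days (%s to %s), mean tmean %.1f C [%.1f, %.1f]\n",
              nrow(s), format(min(s$date)), format(max(s$date)),
              mean(s$tmean), min(s$tmean), max(s$tmean)))
  cat(sprintf("  deaths/day mean %.1f; true MMT %.1f C mid-series, drift %+.2f C/yr\n",
              mean(s$deaths_all), x$truth$mmt0, x$truth$mmt_drift))
  invisible(x)
}

#' Simulate individual death records consistent with a daily series
#'
#' Expands a daily death-count column into individual records with
#' demographic covariates drawn independently per record from the supplied
#' mixtures, then injects missingness completely at random at the stated
#' per-variable rates.  Reconstructing daily counts via
#' [build_stratum_counts()] with zero missingness reproduces the daily
#' totals exactly.
#'
#' @param series a [daily_series()].
#' @param stratum which `deaths_` column to expand; default `"all"`.
#' @param sex_mix,age_mix,ethnicity_mix,education_mix named probability
#'   vectors (must each sum to 1).  `age_mix` names are age-group labels
#'   mapped to uniform ages inside the group.
#' @param missing_rates named vector of per-variable missingness
#'   probabilities (names among sex, age, ethnicity, education).
#' @param seed integer seed.
#' @return data.frame of records: `date, sex, age, ethnicity, education`.
#' @export
simulate_individual_records <- function(series, stratum = "all",
                                        sex_mix = c(female = 0.464,
                                                    male = 0.536),
                                        age_mix = c(lt65 = 0.45,
                                                    a65_79 = 0.27,
                                                    a80plus = 0.28),
                                        ethnicity_mix = c(white = 0.70,
                                                          nonwhite = 0.30),
                                        education_mix = c(low = 0.4,
                                                          mid = 0.45,
                                                          high = 0.15),
                                        missing_rates = c(sex = 0,
                                                          age = 0,
                                                          ethnicity = 0,
                                                          education = 0),
                                        seed = 1L) {
  for (m in list(sex_mix, age_mix, ethnicity_mix, education_mix))
    if (abs(sum(m) - 1) > 1e-8) stop("mixture proportions must sum to 1")
  set.seed(seed)
  counts <- series[[paste0("deaths_", stratum)]]
  counts[is.na(counts)] <- 0L
  N <- sum(counts)
  rec <- data.frame(
    date = rep(series$date, counts),
    sex = sample(names(sex_mix), N, TRUE, sex_mix),
    age_group = sample(names(age_mix), N, TRUE, age_mix),
    ethnicity = sample(names(ethnicity_mix), N, TRUE, ethnicity_mix),
    education = sample(names(education_mix), N, TRUE, education_mix),
    stringsAsFactors = FALSE
  )
  rec$age <- ifelse(rec$age_group == "lt65",
                    sample(30:64, N, TRUE),
                    ifelse(rec$age_group == "a65_79",
                           sample(65:79, N, TRUE),
                           sample(80:99, N, TRUE)))
  rec$age_group <- NULL
  mr <- function(v) missing_rates[v] %||% 0
  for (v in c("sex", "age", "ethnicity", "education")) {
    r <- if (v %in% names(missing_rates)) missing_rates[[v]] else 0
    if (r > 0) rec[[v]][stats::runif(N) < r] <- NA
  }
  rec
}
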