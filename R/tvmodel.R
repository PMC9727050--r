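#' Assemble the full tv-DLNM design matrix
#'
#' Builds the labelled column blocks of the time-varying DLNM regression for
#' one stratum's death counts: intercept; temperature crossbasis; day-of-week
#' indicators (reference Monday); holiday indicator; PM10 as the moving
#' average over lags `0..ma_lags` (linear); relative humidity as a natural
#' spline (knots at terciles) of the same moving average; a long-term time
#' spline with `round(time_df_per_year * n_years)` df, interior knots equally
#' spaced over the observation period, absorbing both trend and seasonality;
#' and, when enabled, the linear interaction block `crossbasis * s_t`, where
#' `s_t = (t - t_ref) / 365.25` is calendar time in years centred at the
#' series midpoint (an affine choice the predictions are invariant to).
#' Rows with any missing regressor — including incomplete lag or
#' moving-average windows — are masked out and counted.
#'
#' @param series a [daily_series()].
#' @param stratum stratum label (the `deaths_` column suffix).
#' @param config a [tv_config()].
#' @param t_ref reference day index at which the interaction time variable is
#'   zero; default the series midpoint.
#' @param mask_first additionally drop this many leading rows.  Used when
#'   several specifications (e.g. different lag windows) must be scored on a
#'   common likelihood sample: qAIC values are only comparable across models
#'   fitted to the same rows.
#' @return an object of class `tv_design`: list with the design matrix `X`,
#'   response `y`, `blocks` (named list of column index vectors), `rows_used`
#'   mask, scaled time `s`, `t_ref`, `dates`, the basis specs and the
#'   crossbasis.
#' @export
assemble_design <- function(series, stratum, config = tv_config(),
                            t_ref = NULL, mask_first = 0L) {
  stopifnot(inherits(series, "daily_series"))
  ycol <- paste0("deaths_", stratum)
  if (!ycol %in% names(series))
    stop("no such stratum column: ", ycol)
  n <- nrow(series)
  tmean <- series$tmean

  exposure_spec <- place_exposure_knots(tmean, config$exposure_percentiles)
  lag_spec <- place_lag_knots(max(config$max_lag, 1L), config$lag_knots)
  if (config$max_lag == 0L)
    lag_spec <- basis_spec("linear", boundary_knots = c(-0.5, 0.5),
                           intercept = TRUE)
  cb <- build_crossbasis(tmean, exposure_spec, lag_spec, config$max_lag)
  ncb <- ncol(cb)

  ## confounders
  dow <- stats::model.matrix(~ factor(dow, levels = 1:7), series)[, -1,
                                                                  drop = FALSE]
  colnames(dow) <- paste0("dow", 2:7)
  holiday <- matrix(as.double(series$holiday), ncol = 1,
                    dimnames = list(NULL, "holiday"))
  pm10_ma <- lagged_mean(series$pm10, config$ma_lags)
  rh_ma <- lagged_mean(series$rh, config$ma_lags)
  rh_ok <- rh_ma[!is.na(rh_ma)]
  if (!length(rh_ok)) stop("relative humidity entirely missing")
  rh_q <- stats::quantile(rh_ok, seq_len(config$rh_df - 1) / config$rh_df,
                          type = 7)
  rh_spec <- basis_spec("ns", interior_knots = unname(rh_q),
                        boundary_knots = range(rh_ok), intercept = FALSE)
  rh_b <- ns_basis(rh_ma, rh_spec)
  colnames(rh_b) <- paste0("rh", seq_len(ncol(rh_b)))

  ## long-term time spline: round(10 df per year) over the whole period
  tindex <- seq_len(n)
  n_years <- n / 365.25
  df_time <- max(2L, as.integer(round(config$time_df_per_year * n_years)))
  tknots <- seq(1, n, length.out = df_time + 1L)[-c(1L, df_time + 1L)]
  time_spec <- basis_spec("ns", interior_knots = tknots,
                          boundary_knots = c(1, n), intercept = FALSE)
  time_b <- ns_basis(tindex, time_spec)
  colnames(time_b) <- paste0("time", seq_len(ncol(time_b)))

  if (is.null(t_ref)) t_ref <- (1 + n) / 2
  s <- (tindex - t_ref) / 365.25

  X <- cbind(`(Intercept)` = 1, unclass(cb), dow, holiday,
             pm10_lag = pm10_ma, rh_b, time_b)
  blocks <- list(
    intercept = 1L,
    crossbasis = 1L + seq_len(ncb),
    dow = 1L + ncb + 1:6,
    holiday = 1L + ncb + 7L,
    pm10 = 1L + ncb + 8L,
    rh = 1L + ncb + 8L + seq_len(ncol(rh_b)),
    time = 1L + ncb + 8L + ncol(rh_b) + seq_len(ncol(time_b))
  )
  if (config$interaction) {
    inter <- unclass(cb) * s
    colnames(inter) <- paste0(colnames(cb), ":s")
    X <- cbind(X, inter)
    blocks$interaction <- (ncol(X) - ncb + 1L):ncol(X)
  }
  colnames(X)[blocks$pm10] <- "pm10_ma"

  y <- series[[ycol]]
  rows_used <- !is.na(y) & stats::complete.cases(X)
  if (mask_first > 0) rows_used[seq_len(min(mask_first, n))] <- FALSE
  n_drop <- sum(!rows_used)
  if (n_drop > 0)
    tv_log("info", "assemble_design[%s]: %d of %d rows dropped (missing data or lag window)",
           stratum, n_drop, n)
  if (sum(rows_used) < 5 * ncol(X))
    stop("insufficient complete rows (", sum(rows_used), ") for ",
         ncol(X), " parameters (need >= 5 per parameter)")

  structure(list(
    X = X, y = y, blocks = blocks, rows_used = rows_used,
    s = s, t_ref = t_ref, dates = series$date, stratum = stratum,
    exposure_spec = exposure_spec, lag_spec = lag_spec,
    rh_spec = rh_spec, time_spec = time_spec,
    crossbasis = cb, config = config
  ), class = "tv_design")
}

#' Fit a time-varying distributed lag non-linear model
#'
#' The main fitting function: assembles the design for one stratum (see
#' [assemble_design()]) and fits the quasi-Poisson regression
#' `log E(Y_t) = a + cb_t + dow + holiday + pm10_ma + ns(rh_ma, 3df) +
#' ns(time, 10 df/year) + cb_t * s_t` by IRLS.  The interaction block lets
#' the exposure-lag-response surface drift linearly over calendar time;
#' annual surfaces are read off with [coefficients_at_time()] /
#' [predict.tvdlnm()].
#'
#' @param series a [daily_series()].
#' @param stratum death-count stratum label; default `"all"`.
#' @param config a [tv_config()] (set `interaction = FALSE` for the standard
#'   time-constant DLNM).
#' @param t_ref optional interaction time origin (day index); default the
#'   series midpoint.
#' @param mask_first additionally drop this many leading rows (see
#'   [assemble_design()]); only relevant when comparing specifications by
#'   qAIC on a common sample.
#' @return an object of class `tvdlnm`: list with elements `fit` (the
#'   [fit_quasipoisson()] result), `design` (a `tv_design`), `series_tmean`,
#'   `dates`, `config`, `stratum`.
#' @examples
#' sim <- simulate_city(scenario_truth(), n_years = 3, seed = 1)
#' m <- tvdlnm(sim$series, "all", tv_config(time_df_per_year = 7))
#' print(m)
#' @export
tvdlnm <- function(series, stratum = "all", config = tv_config(),
                   t_ref = NULL, mask_first = 0L) {
  design <- assemble_design(series, stratum, config, t_ref = t_ref,
                            mask_first = mask_first)
  ok <- design$rows_used
  fit <- fit_quasipoisson(design$y[ok], design$X[ok, , drop = FALSE])
  structure(list(fit = fit, design = design,
                 series_tmean = series$tmean, dates = series$date,
                 config = config, stratum = stratum,
                 call = match.call()),
            class = "tvdlnm")
}

#' Extract the crossbasis coefficients at a centring date
#'
#' Under the linear interaction, the crossbasis coefficients at scaled time
#' `s_c` are `beta(c) = beta_main + s_c * beta_int` with covariance
#' `V_mm + s_c^2 * V_ii + s_c * (V_mi + V_mi')`, the blocks read from the
#' joint covariance.  Taking `c` as 1 July of a year yields that year's
#' average exposure-lag-response surface.  This equals (to numerical
#' precision) a full refit with the interaction time re-centred at `c`.
#'
#' @param object a fitted [tvdlnm()] model.
#' @param centre a `Date` (or coercible) inside the series range.
#' @return an object of class `time_slice`: list with `centre`, `beta`,
#'   `vcov`, and the basis specs needed for prediction.
#' @export
coefficients_at_time <- function(object, centre) {
  stopifnot(inherits(object, "tvdlnm"))
  centre <- as.Date(centre)
  d <- object$design
  idx <- match(centre, d$dates)
  if (is.na(idx))
    stop("centre date ", format(centre), " outside the series range")
  cb_i <- d$blocks$crossbasis
  beta <- coef(object$fit)
  V <- vcov(object$fit)
  b_main <- beta[cb_i]
  V_mm <- V[cb_i, cb_i, drop = FALSE]
  if (!is.null(d$blocks$interaction)) {
    int_i <- d$blocks$interaction
    s_c <- d$s[idx]
    b_int <- beta[int_i]
    V_ii <- V[int_i, int_i, drop = FALSE]
    V_mi <- V[cb_i, int_i, drop = FALSE]
    b <- b_main + s_c * b_int
    Vc <- V_mm + s_c^2 * V_ii + s_c * (V_mi + t(V_mi))
  } else {
    b <- b_main
    Vc <- V_mm
  }
  names(b) <- colnames(d$crossbasis)
  dimnames(Vc) <- list(names(b), names(b))
  structure(list(centre = centre, beta = b, vcov = Vc,
                 exposure_spec = d$exposure_spec, lag_spec = d$lag_spec,
                 max_lag = d$config$max_lag),
            class = "time_slice")
}

## ---- S3 methods ------------------------------------------------------------

#' @export
print.tvdlnm <- function(x, ...) {
  d <- x$design
  cat("Time-varying DLNM (quasi-Poisson)\n")
  cat(sprintf("  stratum: %s; %d days (%s to %s), %d rows used\n",
              x$stratum, length(d$dates), format(min(d$dates)),
              format(max(d$dates)), sum(d$rows_used)))
  cat(sprintf("  crossbasis: %d x %d = %d columns (lag 0-%d); interaction: %s\n",
              basis_dim(d$exposure_spec), basis_dim(d$lag_spec),
              length(d$blocks$crossbasis), d$config$max_lag,
              !is.null(d$blocks$interaction)))
  cat(sprintf("  %d parameters, dispersion %.3f, qAIC %.1f\n",
              x$fit$n_params, x$fit$dispersion, qaic(x)))
  invisible(x)
}

#' @export
summary.tvdlnm <- function(object, ...) {
  w <- if (!is.null(object$design$blocks$interaction))
    wald_interaction_test(object) else NULL
  structure(list(model = object, wald = w,
                 dispersion = object$fit$dispersion,
                 qaic = qaic(object),
                 n_params = object$fit$n_params,
                 n_obs = object$fit$n_obs),
            class = "summary.tvdlnm")
}

#' @export
print.summary.tvdlnm <- function(x, ...) {
  print(x$model)
  if (!is.null(x$wald))
    cat(sprintf("  Wald test of temporal change: chi2 = %.3f, df = %d, p = %.4g\n",
                x$wald$statistic, x$wald$df, x$wald$p_value))
  invisible(x)
}

#' @export
coef.tvdlnm <- function(object, block = NULL, ...) {
  b <- coef(object$fit)
  if (is.null(block)) return(b)
  b[object$design$blocks[[block]]]
}

#' @export
vcov.tvdlnm <- function(object, block = NULL, ...) {
  V <- vcov(object$fit)
  if (is.null(block)) return(V)
  i <- object$design$blocks[[block]]
  V[i, i, drop = FALSE]
}

#' @export
fitted.tvdlnm <- function(object, ...) {
  out <- rep(NA_real_, length(object$dates))
  out[object$design$rows_used] <- object$fit$fitted
  out
}

#' @export
residuals.tvdlnm <- function(object, type = "pearson", ...) {
  out <- rep(NA_real_, length(object$dates))
  out[object$design$rows_used] <- residuals(object$fit, type = type)
  out
}

#' @export
qaic.tvdlnm <- function(fit) qaic(fit$fit)

#' Predict the lag-cumulated relative risk curve of a fitted model
#'
#' Reduces the fitted surface at a centring date to the overall cumulative
#' exposure-response: the relative risk of a day at temperature `x`
#' (sustained over the lag window) versus the reference temperature.
#'
#' @param object a fitted [tvdlnm()].
#' @param centre centring date (default the series midpoint date).
#' @param grid temperature grid; default spans the observed range at the
#'   configured step.
#' @param reference reference temperature; default the constricted MMT at
#'   `centre`.
#' @param ... unused.
#' @return a [predict_curve()] result (class `curve_prediction`).
#' @export
predict.tvdlnm <- function(object, centre = NULL, grid = NULL,
                           reference = NULL, ...) {
  d <- object$design
  if (is.null(centre)) centre <- d$dates[round(d$t_ref)]
  slice <- coefficients_at_time(object, centre)
  tm <- object$series_tmean
  if (is.null(grid))
    grid <- seq(min(tm, na.rm = TRUE), max(tm, na.rm = TRUE),
                by = object$config$mmt_grid_step)
  if (is.null(reference)) {
    mmt <- find_mmt(slice, tm, object$config,
                    seed = object$config$seed %||% 1L)
    reference <- mmt$mmt
  }
  predict_curve(slice, grid = grid, reference = reference)
}

#' Plot the cumulative exposure-response curve
#'
#' @param x a fitted [tvdlnm()].
#' @param centre centring date passed to [predict.tvdlnm()].
#' @param ... further arguments to [predict.tvdlnm()].
#' @export
plot.tvdlnm <- function(x, centre = NULL, ...) {
  cp <- predict(x, centre = centre, ...)
  plot(cp)
  invisible(cp)
}
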