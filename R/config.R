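#' Run configuration for a tv-DLNM analysis
#'
#' Collects every tunable of the modelling pipeline with the defaults of the
#' main model specification: exposure spline knot at the 75th temperature
#' percentile, 21-day lag window with three log-spaced lag knots, 10 df per
#' year for the long-term time spline, relative humidity as a 3-df natural
#' spline of its lag 0--2 moving average, PM10 as a linear term of the same
#' moving average, and a linear time x crossbasis interaction.
#'
#' @param exposure_percentiles percentiles (in (0,100)) of the observed
#'   temperature distribution at which interior knots of the exposure spline
#'   are placed. Default 75.
#' @param max_lag maximum lag of the temperature effect, in days. Default 21.
#' @param lag_knots number of interior lag knots, equally spaced on the log
#'   lag scale. Default 3.
#' @param time_df_per_year degrees of freedom per year for the natural spline
#'   of calendar time absorbing trend and seasonality. Default 10.
#' @param rh_df degrees of freedom of the relative-humidity spline. Default 3.
#' @param ma_lags moving-average span for RH and PM10, as the maximum lag of
#'   the window lag 0..`ma_lags`. Default 2 (a 3-day window, lag 0--2); set 1
#'   for a lag 0--1 window.
#' @param interaction logical; include the linear time x crossbasis
#'   interaction block. Default `TRUE`.
#' @param centre_month,centre_day calendar date within each year at which
#'   annual coefficient slices are taken. Default 1 July, the central day of
#'   the year, so slices are equidistant and represent the year's average
#'   surface.
#' @param n_boot parametric bootstrap draws for MMT empirical confidence
#'   intervals. Default 1000.
#' @param seed root random seed; `NULL` leaves the RNG state untouched.
#' @param mmt_grid_step temperature grid step (degrees C) for the MMT search.
#'   Default 0.1.
#' @param percentiles named vector of the four percentile anchors at which
#'   cumulative relative risks are reported.
#' @param mmt_constraint_percentiles lower/upper percentile bounds of the
#'   constricted MMT search window. Default `c(1, 99)`.
#' @param annual_percentile_basis `"annual"` (default) computes the percentile
#'   anchors and the MMT constraint from each calendar year's temperatures;
#'   `"period"` uses the full study period distribution.
#' @param strata character vector of death-count column names (without the
#'   `deaths_` prefix) to analyse; `NULL` means every `deaths_*` column.
#' @param min_valid_fraction minimum fraction of valid hourly values for a
#'   station to be retained when aggregating hourly data. Default 0.75.
#' @param min_valid_hours_per_day minimum hourly values present for a daily
#'   mean to be computed (else the day is missing). Default 18 of 24.
#' @return an object of class `tv_config` (a named list).
#' @seealso [read_config()] to load one from a YAML file.
#' @export
tv_config <- function(exposure_percentiles = 75,
                      max_lag = 21L,
                      lag_knots = 3L,
                      time_df_per_year = 10,
                      rh_df = 3L,
                      ma_lags = 2L,
                      interaction = TRUE,
                      centre_month = 7L,
                      centre_day = 1L,
                      n_boot = 1000L,
                      seed = NULL,
                      mmt_grid_step = 0.1,
                      percentiles = c(extreme_cold = 1, moderate_cold = 10,
                                      moderate_heat = 90, extreme_heat = 99),
                      mmt_constraint_percentiles = c(1, 99),
                      annual_percentile_basis = c("annual", "period"),
                      strata = NULL,
                      min_valid_fraction = 0.75,
                      min_valid_hours_per_day = 18L) {
  stopifnot(all(exposure_percentiles > 0), all(exposure_percentiles < 100),
            max_lag >= 0, lag_knots >= 1, time_df_per_year >= 1,
            rh_df >= 1, ma_lags >= 0, n_boot >= 1, mmt_grid_step > 0,
            all(percentiles > 0), all(percentiles < 100),
            length(mmt_constraint_percentiles) == 2,
            mmt_constraint_percentiles[1] < mmt_constraint_percentiles[2],
            min_valid_fraction > 0, min_valid_fraction <= 1)
  cfg <- list(
    exposure_percentiles = sort(as.double(exposure_percentiles)),
    max_lag = as.integer(max_lag),
    lag_knots = as.integer(lag_knots),
    time_df_per_year = as.double(time_df_per_year),
    rh_df = as.integer(rh_df),
    ma_lags = as.integer(ma_lags),
    interaction = isTRUE(interaction),
    centre_month = as.integer(centre_month),
    centre_day = as.integer(centre_day),
    n_boot = as.integer(n_boot),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    mmt_grid_step = as.double(mmt_grid_step),
    percentiles = percentiles,
    mmt_constraint_percentiles = as.double(mmt_constraint_percentiles),
    annual_percentile_basis = match.arg(annual_percentile_basis),
    strata = strata,
    min_valid_fraction = as.double(min_valid_fraction),
    min_valid_hours_per_day = as.integer(min_valid_hours_per_day)
  )
  structure(cfg, class = "tv_config")
}

#' Read a run configuration from a YAML file
#'
#' Every field is optional; absent fields keep the [tv_config()] defaults.
#' Fields supplied through `...` (e.g. from command-line flags) override the
#' file values.
#'
#' @param path path to a YAML configuration file, or `NULL` for defaults only.
#' @param ... overrides, as `tv_config()` arguments.
#' @return a `tv_config` object.
#' @export
read_config <- function(path = NULL, ...) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(tv_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(vals$percentiles)) vals$percentiles <- unlist(vals$percentiles)
  do.call(tv_config, vals)
}

#' @export
print.tv_config <- function(x, ...) {
  cat("tv-DLNM run configuration\n")
  cat(sprintf("  exposure knots at percentile(s): %s\n",
              paste(x$exposure_percentiles, collapse = ", ")))
  cat(sprintf("  lag window: 0..%d days, %d log-spaced lag knots\n",
              x$max_lag, x$lag_knots))
  cat(sprintf("  time spline: %g df/year; RH spline: %d df; MA window: lag 0-%d\n",
              x$time_df_per_year, x$rh_df, x$ma_lags))
  cat(sprintf("  interaction: %s; centring: %02d-%02d; bootstrap draws: %d\n",
              x$interaction, x$centre_month, x$centre_day, x$n_boot))
  invisible(x)
}
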