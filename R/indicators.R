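#' Lag-cumulated relative risk curve from a coefficient slice
#'
#' For the cumulative prediction vectors `w(x)` of
#' [crossbasis_prediction_vector()], the lag-cumulated log relative risk
#' versus the reference temperature is
#' `log cRR(x) = (w(x) - w(ref))' beta` with standard error
#' `sqrt((w(x) - w(ref))' V (w(x) - w(ref)))`; 95 percent normal-theory
#' bounds are `exp(log cRR +/- 1.96 se)`.  At the reference the cRR is 1
#' exactly with zero standard error.
#'
#' @param slice a `time_slice` from [coefficients_at_time()].
#' @param grid temperature grid (degrees C).
#' @param reference reference (re-centring) temperature; must lie within the
#'   grid range.
#' @param warn_extrapolation warn when the grid extends beyond the exposure
#'   boundary knots by more than 10 percent of their range.
#' @return class `curve_prediction`: data.frame `grid, log_crr, se, crr,
#'   crr_low, crr_high` with attribute `reference`.
#' @export
predict_curve <- function(slice, grid, reference, warn_extrapolation = TRUE) {
  stopifnot(inherits(slice, "time_slice"))
  if (reference < min(grid) - 1e-9 || reference > max(grid) + 1e-9)
    stop("reference temperature ", reference, " outside the grid range")
  bnd <- slice$exposure_spec$boundary_knots
  pad <- 0.1 * diff(bnd)
  if (warn_extrapolation &&
      (min(grid) < bnd[1] - pad || max(grid) > bnd[2] + pad))
    warning("grid extends well beyond the observed temperature range; ",
            "curve tails are linear extrapolations")
  W <- crossbasis_prediction_vector(grid, slice$exposure_spec,
                                    slice$lag_spec, slice$max_lag)
  wref <- crossbasis_prediction_vector(reference, slice$exposure_spec,
                                       slice$lag_spec, slice$max_lag)
  D <- W - matrix(wref, nrow(W), ncol(W), byrow = TRUE)
  log_crr <- drop(D %*% slice$beta)
  se <- sqrt(pmax(rowSums((D %*% slice$vcov) * D), 0))
  out <- data.frame(grid = grid, log_crr = log_crr, se = se,
                    crr = exp(log_crr),
                    crr_low = exp(log_crr - 1.96 * se),
                    crr_high = exp(log_crr + 1.96 * se))
  structure(out, reference = reference, centre = slice$centre,
            class = c("curve_prediction", "data.frame"))
}

#' @export
print.curve_prediction <- function(x, ...) {
  cat(sprintf("lag-cumulated RR curve: %d grid points in [%.1f, %.1f] C, reference %.2f C\n",
              nrow(x), min(x$grid), max(x$grid), attr(x, "reference")))
  invisible(x)
}

#' @export
plot.curve_prediction <- function(x, ...) {
  graphics::plot(x$grid, x$crr, type = "n",
                 ylim = range(x$crr_low, x$crr_high),
                 xlab = "temperature (°C)",
                 ylab = "cumulative relative risk", ...)
  graphics::polygon(c(x$grid, rev(x$grid)), c(x$crr_low, rev(x$crr_high)),
                    col = "grey85", border = NA)
  graphics::lines(x$grid, x$crr, lwd = 2)
  graphics::abline(h = 1, lty = 3)
  graphics::abline(v = attr(x, "reference"), lty = 2)
  invisible(x)
}

#' Percentile-constricted minimum mortality temperature
#'
#' The MMT is the argmin of the lag-cumulated log relative risk over a
#' regular temperature grid, restricted to temperatures between the 1st and
#' 99th percentile of the supplied temperature distribution (constriction
#' avoids the unstable curve tails).  The location is invariant to the
#' internal reference temperature.  Uncertainty comes from a parametric
#' bootstrap: coefficient vectors are drawn from `MVN(beta, vcov)`, the
#' constrained argmin recomputed for each, and the empirical 2.5/97.5
#' percentiles and standard deviation reported.
#'
#' @param slice a `time_slice` from [coefficients_at_time()].
#' @param tmean_subset temperatures defining the percentile constraint.
#' @param config a [tv_config()] (grid step, bootstrap draws, constraint
#'   percentiles).
#' @param seed integer seed for the bootstrap draws (bitwise reproducible).
#' @param n_boot override for `config$n_boot`.
#' @return class `mmt_estimate`: list with `mmt`, `eci_low`, `eci_high`,
#'   `se`, `n_boot`, `constrained_range`, and logical flags
#'   `boundary_dominated` (argmin on a constraint boundary in more than half
#'   the draws), `at_boundary`, `outside_eci`.
#' @export
find_mmt <- function(slice, tmean_subset, config = tv_config(), seed = 1L,
                     n_boot = NULL) {
  stopifnot(inherits(slice, "time_slice"))
  n_boot <- n_boot %||% config$n_boot
  x <- tmean_subset[!is.na(tmean_subset)]
  if (!length(x)) stop("no temperatures supplied for the constraint")
  cr <- unname(stats::quantile(x, config$mmt_constraint_percentiles / 100,
                               type = 7))
  grid <- seq(cr[1], cr[2], by = config$mmt_grid_step)
  if (utils::tail(grid, 1) < cr[2] - 1e-9) grid <- c(grid, cr[2])
  W <- crossbasis_prediction_vector(grid, slice$exposure_spec,
                                    slice$lag_spec, slice$max_lag)
  ## reference-invariant: subtract the first grid point's vector
  D <- W - matrix(W[1, ], nrow(W), ncol(W), byrow = TRUE)
  lc <- drop(D %*% slice$beta)
  if (diff(range(lc)) < 1e-12)
    stop("MMT undefined: flat cumulative risk curve over the constrained range")
  i0 <- which.min(lc)
  mmt <- grid[i0]

  set.seed(seed)
  draws <- MASS::mvrnorm(n_boot, slice$beta, slice$vcov)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n_boot)
  LC <- D %*% t(draws)                      # n_grid x n_boot
  idx <- max.col(-t(LC), ties.method = "first")
  mmts <- grid[idx]
  eci <- unname(stats::quantile(mmts, c(0.025, 0.975), type = 7))
  boundary_frac <- mean(idx == 1L | idx == length(grid))
  structure(list(
    mmt = mmt, eci_low = eci[1], eci_high = eci[2],
    se = stats::sd(mmts), n_boot = n_boot,
    constrained_range = cr,
    at_boundary = i0 == 1L || i0 == length(grid),
    boundary_dominated = boundary_frac > 0.5,
    boundary_fraction = boundary_frac,
    outside_eci = mmt < eci[1] || mmt > eci[2],
    centre = slice$centre
  ), class = "mmt_estimate")
}

#' @export
print.mmt_estimate <- function(x, ...) {
  cat(sprintf("MMT %.1f C (95%% eCI %.1f-%.1f, se %.2f; %d bootstrap draws)\n",
              x$mmt, x$eci_low, x$eci_high, x$se, x$n_boot))
  if (x$boundary_dominated)
    cat("  [flag] boundary-dominated bootstrap argmin\n")
  if (x$outside_eci)
    cat("  [flag] point estimate outside its empirical interval\n")
  invisible(x)
}

#' Annual adaptation indicators for one year
#'
#' Computes, for a calendar year: the annual mean temperature (AMT) and the
#' 1st/10th/90th/99th percentile anchors from that year's daily temperatures
#' (or the full-period distribution, per the configuration); the
#' percentile-constricted MMT at the 1 July coefficient slice with its
#' bootstrap interval; and the cumulative relative risks at the four anchors
#' with the curve re-centred at that year's MMT.
#'
#' @param object a fitted [tvdlnm()] with interaction.
#' @param year calendar year within the series.
#' @param config a [tv_config()]; defaults to the model's.
#' @param seed bootstrap seed for this year's MMT.
#' @return class `annual_indicators`: one-row data.frame with `year`, `amt`,
#'   `p1,p10,p90,p99`, `mmt, mmt_eci_low, mmt_eci_high, mmt_se`,
#'   `crr_*`/`crr_*_low`/`crr_*_high` for the four anchors, and flags.
#' @export
annual_indicators <- function(object, year, config = NULL, seed = 1L) {
  stopifnot(inherits(object, "tvdlnm"))
  config <- config %||% object$config
  yrs <- as.integer(format(object$dates, "%Y"))
  in_year <- yrs == year
  if (!any(in_year)) stop("year ", year, " not inside the series")
  tm_year <- object$series_tmean[in_year]
  if (mean(is.na(tm_year)) > 0.2)
    stop("year ", year, " has more than 20% missing temperatures")
  basis_tm <- if (config$annual_percentile_basis == "annual") tm_year
              else object$series_tmean
  anchors <- stats::quantile(basis_tm, config$percentiles / 100,
                             na.rm = TRUE, type = 7)
  amt <- mean(tm_year, na.rm = TRUE)

  centre <- as.Date(sprintf("%d-%02d-%02d", year, config$centre_month,
                            config$centre_day))
  slice <- coefficients_at_time(object, centre)
  mmt <- find_mmt(slice, basis_tm, config, seed = seed)
  grid <- sort(unique(c(unname(anchors), mmt$mmt)))
  cp <- predict_curve(slice, grid = grid, reference = mmt$mmt,
                      warn_extrapolation = FALSE)
  at <- match(unname(anchors), cp$grid)
  lab <- names(config$percentiles)
  out <- data.frame(year = year, amt = amt,
                    p1 = unname(anchors[1]), p10 = unname(anchors[2]),
                    p90 = unname(anchors[3]), p99 = unname(anchors[4]),
                    mmt = mmt$mmt, mmt_eci_low = mmt$eci_low,
                    mmt_eci_high = mmt$eci_high, mmt_se = mmt$se,
                    mmt_boundary_dominated = mmt$boundary_dominated)
  for (k in seq_along(lab)) {
    out[[paste0("crr_", lab[k])]] <- cp$crr[at[k]]
    out[[paste0("crr_", lab[k], "_low")]] <- cp$crr_low[at[k]]
    out[[paste0("crr_", lab[k], "_high")]] <- cp$crr_high[at[k]]
  }
  structure(out, mmt = mmt, curve = cp,
            class = c("annual_indicators", "data.frame"))
}

#' Annual temperature indicators and their linear trends
#'
#' Annual mean temperature and the 1st/99th percentiles of each calendar
#' year's daily means, each regressed on year by ordinary least squares
#' (slope, t statistic, p value).
#'
#' @param series a [daily_series()].
#' @param config a [tv_config()] (unused fields reserved).
#' @return list with `table` (year, amt, p1, p99) and `trends` (one row per
#'   indicator: slope, se, t, p).
#' @export
temperature_trends <- function(series, config = tv_config()) {
  yrs <- as.integer(format(series$date, "%Y"))
  uy <- sort(unique(yrs))
  if (length(uy) < 3) stop("need at least 3 calendar years")
  tab <- data.frame(
    year = uy,
    amt = vapply(uy, function(y) mean(series$tmean[yrs == y], na.rm = TRUE),
                 0),
    p1 = vapply(uy, function(y)
      unname(stats::quantile(series$tmean[yrs == y], 0.01, na.rm = TRUE,
                             type = 7)), 0),
    p99 = vapply(uy, function(y)
      unname(stats::quantile(series$tmean[yrs == y], 0.99, na.rm = TRUE,
                             type = 7)), 0)
  )
  one <- function(v) {
    f <- stats::lm(tab[[v]] ~ tab$year)
    cf <- summary(f)$coefficients
    data.frame(indicator = v, slope = cf[2, 1], se = cf[2, 2],
               t = cf[2, 3], p = cf[2, 4])
  }
  trends <- do.call(rbind, lapply(c("amt", "p1", "p99"), one))
  rownames(trends) <- NULL
  list(table = tab, trends = trends)
}
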