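#' Run the full analysis pipeline over every stratum
#'
#' For each configured death-count stratum: fits the tv-DLNM, runs the
#' multivariate Wald test of temporal change, computes per-year annual
#' indicators (MMT with bootstrap eCI, cRRs at the four percentile anchors),
#' regresses each indicator on year by inverse-variance WLS, and runs the
#' coupling regressions (MMT on AMT, extreme-heat cRR on annual P99,
#' extreme-cold cRR on annual P1).  Writes per-stratum CSVs plus a combined
#' first/last-year report and a run manifest when `out_dir` is given.  All
#' randomness derives deterministically from `seed` via [derive_seed()], so
#' identical seeds give byte-identical outputs.
#'
#' @param series a [daily_series()], or a `sim_city` (its series is used).
#' @param config a [tv_config()].
#' @param out_dir optional output directory (created if missing).
#' @param seed root seed for all bootstrap draws. Default 1.
#' @return class `tv_pipeline`: per-stratum list of `model`, `wald`,
#'   `annual` (data.frame of per-year indicators), `trends`, `coupling`;
#'   plus `report` (the combined first/last-year table) and
#'   `temperature_trends`.
#' @export
run_pipeline <- function(series, config = tv_config(), out_dir = NULL,
                         seed = 1L) {
  if (inherits(series, "sim_city")) series <- series$series
  stopifnot(inherits(series, "daily_series"))
  strata <- config$strata %||%
    sub("^deaths_", "", grep("^deaths_", names(series), value = TRUE))
  yrs <- sort(unique(as.integer(format(series$date, "%Y"))))
  temp_tr <- temperature_trends(series, config)
  results <- list()
  report <- list()
  for (si in seq_along(strata)) {
    st <- strata[si]
    tv_log("info", "pipeline: fitting stratum '%s'", st)
    res <- tryCatch({
      model <- tvdlnm(series, st, config)
      wald <- if (config$interaction) wald_interaction_test(model) else NULL
      annual <- do.call(rbind, lapply(yrs, function(y)
        as.data.frame(annual_indicators(
          model, y, config, seed = derive_seed(seed, st, y)))))
      trends <- list(
        mmt = wls_trend(annual$year, annual$mmt,
                        mmt_se_floor(annual, config)),
        crr_extreme_heat = wls_trend(
          annual$year, annual$crr_extreme_heat,
          crr_se(annual, "extreme_heat")),
        crr_extreme_cold = wls_trend(
          annual$year, annual$crr_extreme_cold,
          crr_se(annual, "extreme_cold"))
      )
      coupling <- list(
        mmt_amt = coupling_regression(annual$amt, annual$mmt,
                                      mmt_se_floor(annual, config)),
        heat_p99 = coupling_regression(annual$p99,
                                       annual$crr_extreme_heat,
                                       crr_se(annual, "extreme_heat")),
        cold_p1 = coupling_regression(annual$p1,
                                      annual$crr_extreme_cold,
                                      crr_se(annual, "extreme_cold"))
      )
      list(model = model, wald = wald, annual = annual, trends = trends,
           coupling = coupling)
    }, error = function(e) {
      tv_log("error", "pipeline: stratum '%s' failed: %s", st,
             conditionMessage(e))
      stop("stratum '", st, "': ", conditionMessage(e), call. = FALSE)
    })
    results[[st]] <- res
    fl <- res$annual[res$annual$year %in% range(yrs), , drop = FALSE]
    fl <- data.frame(stratum = st, fl[, c(
      "year", "mmt",
      "crr_extreme_cold", "crr_extreme_cold_low", "crr_extreme_cold_high",
      "crr_moderate_cold", "crr_moderate_cold_low", "crr_moderate_cold_high",
      "crr_moderate_heat", "crr_moderate_heat_low", "crr_moderate_heat_high",
      "crr_extreme_heat", "crr_extreme_heat_low", "crr_extreme_heat_high")],
      wald_p = if (is.null(res$wald)) NA_real_ else res$wald$p_value)
    report[[st]] <- fl
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  out <- structure(list(strata = results, report = report,
                        temperature_trends = temp_tr,
                        config = config, seed = seed),
                   class = "tv_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, series, out_dir)
  out
}

crr_se <- function(annual, anchor) {
  ## normal-theory se on the RR scale from the 95% bounds (delta on log
  ## scale); floored so a degenerate anchor (e.g. coinciding with the MMT,
  ## where the RR is 1 with zero width by construction) cannot acquire a
  ## near-infinite weight
  lo <- annual[[paste0("crr_", anchor, "_low")]]
  hi <- annual[[paste0("crr_", anchor, "_high")]]
  est <- annual[[paste0("crr_", anchor)]]
  se_log <- (log(hi) - log(lo)) / (2 * 1.96)
  pmax(est * se_log, 1e-3)
}

## MMT standard errors floored at half the search-grid resolution
mmt_se_floor <- function(annual, config) {
  pmax(annual$mmt_se, config$mmt_grid_step / 2)
}

write_pipeline_outputs <- function(pipe, series, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  for (st in names(pipe$strata)) {
    res <- pipe$strata[[st]]
    ann <- res$annual
    wcsv(ann[, c("year", "mmt", "mmt_eci_low", "mmt_eci_high", "mmt_se",
                 "mmt_boundary_dominated")],
         sprintf("mmt_%s.csv", st))
    wcsv(ann, sprintf("indicators_%s.csv", st))
    tr <- do.call(rbind, lapply(names(res$trends), function(k) {
      t <- res$trends[[k]]
      data.frame(indicator = k, slope = t$slope, se = t$slope_se,
                 r2 = t$r_squared, F = t$f_statistic, p = t$p_value,
                 pearson_r = t$pearson_r)
    }))
    cp <- do.call(rbind, lapply(names(res$coupling), function(k) {
      t <- res$coupling[[k]]
      data.frame(indicator = paste0("coupling_", k), slope = t$slope,
                 se = t$slope_se, r2 = t$r_squared, F = t$f_statistic,
                 p = t$p_value, pearson_r = t$pearson_r)
    }))
    wcsv(rbind(tr, cp), sprintf("trends_%s.csv", st))
    if (!is.null(res$wald))
      wcsv(data.frame(statistic = res$wald$statistic, df = res$wald$df,
                      p = res$wald$p_value), sprintf("wald_%s.csv", st))
    for (y in range(ann$year)) {
      cpred <- predict(res$model,
                       centre = as.Date(sprintf("%d-07-01", y)),
                       reference = ann$mmt[ann$year == y])
      wcsv(as.data.frame(cpred)[, c("grid", "crr", "crr_low", "crr_high")],
           sprintf("curves_%s_%d.csv", st, y))
    }
  }
  wcsv(pipe$report, "report.csv")
  wcsv(pipe$temperature_trends$table, "temperature_indicators.csv")
  manifest <- c(
    sprintf("tvdlnm pipeline run %s", format(Sys.time())),
    sprintf("seed: %d", pipe$seed),
    sprintf("strata: %s", paste(names(pipe$strata), collapse = ", ")),
    "config:",
    utils::capture.output(utils::str(unclass(pipe$config)))
  )
  writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  invisible(out_dir)
}

#' @export
print.tv_pipeline <- function(x, ...) {
  cat(sprintf("tv-DLNM pipeline: %d strata, seed %d\n",
              length(x$strata), x$seed))
  print(x$report, digits = 3)
  invisible(x)
}

#' Default sensitivity grid
#'
#' Alternative model parametrisations in the families typically explored in
#' sensitivity analyses: exposure knot placement, lag window, time-spline
#' and humidity df.
#'
#' @param config base [tv_config()] the deltas apply to.
#' @return named list of `tv_config` objects.
#' @export
default_sensitivity_grid <- function(config = tv_config()) {
  alt <- function(...) {
    args <- utils::modifyList(unclass(config), list(...))
    class(args) <- "tv_config"
    args
  }
  list(
    main = config,
    expknot50 = alt(exposure_percentiles = 50),
    expknot5090 = alt(exposure_percentiles = c(50, 90)),
    lag14 = alt(max_lag = 14L),
    lag28 = alt(max_lag = 28L),
    timedf7 = alt(time_df_per_year = 7),
    timedf8 = alt(time_df_per_year = 8),
    rhdf4 = alt(rh_df = 4L)
  )
}

#' Fit a grid of alternative model specifications and select by qAIC
#'
#' Fits every configuration in the grid to one stratum, scores each by qAIC,
#' and selects the minimum (ties broken by fewest parameters, then grid
#' order).  Two measures make the scores comparable across specifications:
#' all entries are fitted to a common likelihood sample (the leading rows
#' required by the widest lag/moving-average window in the grid are dropped
#' everywhere), and one common dispersion — that of the richest successful
#' model — scales every entry's likelihood.  A model's own Pearson
#' dispersion grows with its lack of fit, so own-dispersion qAIC can reward
#' misfit; the per-model log-likelihoods and dispersions are logged in the
#' table so alternative scalings can be recomputed.  A failing entry is
#' logged and marked failed; the rest of the grid completes.  For robustness
#' inspection, the first- and last-year MMT and extreme cRRs of each
#' successful entry are reported.
#'
#' @param series a [daily_series()] or `sim_city`.
#' @param grid named list of [tv_config()]s (>= 2 entries), e.g. from
#'   [default_sensitivity_grid()].
#' @param stratum stratum label. Default `"all"`.
#' @param out_dir optional output directory for the qAIC table.
#' @param seed root seed for bootstrap draws.
#' @param indicators logical; also compute first/last-year indicators per
#'   entry (slower). Default `TRUE`.
#' @return class `tv_sensitivity`: list with `table` (model, qaic, n_params,
#'   status, selected), `selected` (name), `fits` (the models), `indicators`.
#' @export
run_sensitivity <- function(series, grid = default_sensitivity_grid(),
                            stratum = "all", out_dir = NULL, seed = 1L,
                            indicators = TRUE) {
  if (inherits(series, "sim_city")) series <- series$series
  stopifnot(length(grid) >= 2)
  if (is.null(names(grid)) || any(names(grid) == ""))
    names(grid) <- paste0("model", seq_along(grid))
  fits <- list(); rows <- list(); ind <- list()
  yrs <- range(as.integer(format(series$date, "%Y")))
  ## score every entry on a common likelihood sample: drop the leading rows
  ## required by the widest lag / moving-average window in the grid
  common_mask <- max(vapply(grid, function(g)
    max(g$max_lag, g$ma_lags), 0))
  for (g in names(grid)) {
    f <- tryCatch(tvdlnm(series, stratum, grid[[g]],
                         mask_first = common_mask),
                  error = function(e) {
                    tv_log("warn", "sensitivity entry '%s' failed: %s", g,
                           conditionMessage(e))
                    e
                  })
    if (inherits(f, "error")) {
      rows[[g]] <- data.frame(model = g, qaic = NA_real_,
                              qaic_own_phi = NA_real_,
                              loglik = NA_real_, dispersion = NA_real_,
                              n_params = NA_integer_, status = "failed")
      next
    }
    fits[[g]] <- f
    rows[[g]] <- data.frame(model = g, qaic = NA_real_,
                            qaic_own_phi = qaic(f),
                            loglik = f$fit$poisson_loglik,
                            dispersion = f$fit$dispersion,
                            n_params = f$fit$n_params, status = "ok")
    if (indicators) {
      ind[[g]] <- do.call(rbind, lapply(yrs, function(y) {
        a <- annual_indicators(f, y, grid[[g]],
                               seed = derive_seed(seed, g, y))
        data.frame(model = g, year = y, mmt = a$mmt,
                   crr_extreme_cold = a$crr_extreme_cold,
                   crr_extreme_heat = a$crr_extreme_heat)
      }))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- tab$status == "ok"
  if (!any(ok)) stop("every grid entry failed")
  ## one dispersion across the set: the richest successful model's
  ref <- which(ok)[which.max(tab$n_params[ok])]
  phi_ref <- tab$dispersion[ref]
  tab$qaic[ok] <- -2 * tab$loglik[ok] / phi_ref + 2 * tab$n_params[ok]
  ord <- order(!ok, tab$qaic, tab$n_params, seq_len(nrow(tab)))
  selected <- tab$model[ord[1]]
  tab$selected <- tab$model == selected
  out <- structure(list(table = tab, selected = selected, fits = fits,
                        indicators = if (length(ind)) do.call(rbind, ind)),
                   class = "tv_sensitivity")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "qaic_grid.csv"),
                     row.names = FALSE)
    if (!is.null(out$indicators))
      utils::write.csv(out$indicators,
                       file.path(out_dir, "sensitivity_indicators.csv"),
                       row.names = FALSE)
  }
  out
}

#' @export
print.tv_sensitivity <- function(x, ...) {
  cat("qAIC sensitivity grid (selected: ", x$selected, ")\n", sep = "")
  print(x$table, digits = 6)
  invisible(x)
}
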