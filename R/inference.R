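#' Multivariate Wald test on the interaction coefficients
#'
#' Tests the null that every time x crossbasis interaction coefficient is
#' zero (no temporal change in the exposure-lag-response surface):
#' `W = beta_int' V_int^-1 beta_int`, compared to a chi-squared distribution
#' with `df = length(beta_int)`, assuming multivariate normality of the
#' estimates.  Near-singular covariance submatrices (condition number above
#' `1e10`) fall back to the Moore-Penrose pseudo-inverse with a warning —
#' small-count strata can produce unstable covariances.
#'
#' @param fit a fitted [tvdlnm()] (or a `qpfit` with `indices` supplied).
#' @param indices optional integer column indices of the coefficients under
#'   test (default: the model's interaction block).
#' @return class `wald_result`: list with `statistic`, `df`, `p_value`,
#'   `significant` (at 0.05).
#' @export
wald_interaction_test <- function(fit, indices = NULL) {
  if (inherits(fit, "tvdlnm")) {
    if (is.null(indices)) indices <- fit$design$blocks$interaction
    if (is.null(indices))
      stop("model has no interaction block; nothing to test")
    beta <- coef(fit$fit)[indices]
    V <- vcov(fit$fit)[indices, indices, drop = FALSE]
  } else {
    if (is.null(indices)) stop("indices required for a bare fit")
    beta <- coef(fit)[indices]
    V <- vcov(fit)[indices, indices, drop = FALSE]
  }
  wald_test(beta, V)
}

#' Wald test of a coefficient vector against zero
#'
#' @param beta coefficient vector.
#' @param V its covariance matrix.
#' @return class `wald_result`.
#' @export
wald_test <- function(beta, V) {
  beta <- as.double(beta)
  V <- as.matrix(V)
  stopifnot(length(beta) == nrow(V), nrow(V) == ncol(V))
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  cond <- max(ev) / max(min(ev), .Machine$double.xmin)
  if (!is.finite(cond) || cond > 1e10 || min(ev) <= 0) {
    warning(sprintf(
      "interaction covariance near-singular (condition number %.3g); using pseudo-inverse",
      cond))
    Vinv <- MASS::ginv(V)
    W <- drop(t(beta) %*% Vinv %*% beta)
  } else {
    W <- drop(t(beta) %*% solve(V, beta))
  }
  df <- length(beta)
  p <- stats::pchisq(W, df = df, lower.tail = FALSE)
  structure(list(statistic = W, df = df, p_value = p,
                 significant = p < 0.05),
            class = "wald_result")
}

#' @export
print.wald_result <- function(x, ...) {
  cat(sprintf("multivariate Wald test: chi2 = %.4f, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$significant) " (*)" else ""))
  invisible(x)
}

#' Inverse-variance weighted least squares trend
#'
#' Weighted linear regression of an annual indicator on year with weights
#' `1 / se^2` (equal weights when no standard errors are given, in which
#' case the fit is ordinary least squares exactly).  Reports the weighted
#' slope and intercept, the weighted R-squared and Snedecor F, the slope's
#' p-value, and the unweighted Pearson correlation as displayed alongside
#' trend panels.
#'
#' @param years numeric regressor (calendar years, or any indicator for
#'   coupling regressions).
#' @param values annual indicator values.
#' @param ses optional positive standard errors of `values`.
#' @return class `trend_result`: list with `slope`, `intercept`, `slope_se`,
#'   `r_squared`, `f_statistic`, `p_value`, `pearson_r`, `weights`,
#'   `fitted`, `residuals`, `significant`.
#' @export
wls_trend <- function(years, values, ses = NULL) {
  stopifnot(length(years) == length(values))
  ok <- !is.na(years) & !is.na(values)
  if (!is.null(ses)) ok <- ok & !is.na(ses)
  years <- years[ok]; values <- values[ok]
  if (!is.null(ses)) ses <- ses[ok]
  if (length(years) < 3) stop("need at least 3 points for a trend")
  if (diff(range(years)) == 0) stop("regressor is constant")
  w <- if (is.null(ses)) rep(1, length(years)) else {
    stopifnot(all(ses > 0))
    1 / ses^2
  }
  fit <- stats::lm(values ~ years, weights = w)
  sm <- summary(fit)
  cf <- sm$coefficients
  if (nrow(cf) < 2 || anyNA(stats::coef(fit)))
    stop("trend regressor aliased (degenerate weights or collinearity)")
  fstat <- if (is.null(sm$fstatistic)) NA_real_ else unname(sm$fstatistic[1])
  r2 <- sm$r.squared
  ## constant response: no variance to explain (guard against 0/0 noise)
  if (!is.finite(r2) || diff(range(values)) == 0) r2 <- 0
  structure(list(
    slope = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
    slope_se = unname(cf[2, 2]),
    r_squared = r2,
    f_statistic = fstat,
    p_value = unname(cf[2, 4]),
    pearson_r = stats::cor(years, values),
    weights = w,
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    significant = isTRUE(unname(cf[2, 4]) < 0.05)
  ), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("WLS trend: slope %.4f (se %.4f), R2 %.3f, F %.2f, p %.4g%s; Pearson r %.3f\n",
              x$slope, x$slope_se, x$r_squared, x$f_statistic, x$p_value,
              if (x$significant) " (*)" else "", x$pearson_r))
  invisible(x)
}

#' Coupling regression between two annual indicators
#'
#' The trend machinery of [wls_trend()] with another indicator as the
#' regressor: e.g. annual MMT on annual mean temperature, or the extreme-heat
#' cRR on the annual 99th temperature percentile.
#'
#' @param x regressor indicator values.
#' @param y response indicator values.
#' @param y_ses optional standard errors of `y` (inverse-variance weights).
#' @return a `trend_result`.
#' @export
coupling_regression <- function(x, y, y_ses = NULL) wls_trend(x, y, y_ses)

#' Pearson chi-squared check of missingness balance
#'
#' Tests whether the proportion of records with missing covariate values
#' differs across strata (a 2 x k contingency table of missing vs present
#' counts), using the uncorrected Pearson statistic with
#' `df = (2 - 1)(k - 1)`.
#'
#' @param table a 2 x k matrix (or table) of counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
missingness_chisq <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) != 2 || ncol(tab) < 2)
    stop("expected a 2 x k contingency table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the contingency table")
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts <= 0)) stop("non-positive expected counts")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
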