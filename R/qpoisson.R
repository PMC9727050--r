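#' Fit an overdispersed (quasi-)Poisson regression by IRLS
#'
#' Log-link Poisson iteratively reweighted least squares, run to convergence
#' (relative deviance change below `1e-9`, at most 100 iterations).  The
#' dispersion is estimated from the Pearson statistic,
#' `phi = sum((y - mu)^2 / mu) / (n - p)`, and the coefficient covariance is
#' `phi * (X' W X)^-1` at convergence — the quasi-Poisson covariance.
#'
#' @param y non-negative integer count vector (no missing values).
#' @param X numeric design matrix, full column rank, complete rows only.
#' @param tol relative deviance convergence tolerance. Default `1e-9`.
#' @param maxit maximum IRLS iterations. Default 100.
#' @return an object of class `qpfit`: list with `coefficients`, `vcov`
#'   (dispersion-scaled), `vcov_unscaled`, `dispersion`, `poisson_loglik`,
#'   `deviance`, `fitted`, `n_obs`, `n_params`, `iter`, `converged`.
#' @export
fit_quasipoisson <- function(y, X, tol = 1e-9, maxit = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n, n > p)
  if (anyNA(y) || anyNA(X))
    stop("missing values in y or X: drop incomplete rows before fitting")
  if (any(y < 0) || any(y != round(y)))
    stop("y must contain non-negative integer counts")
  ## cheap PD check on the cross-product; on failure, name the collinear
  ## columns via a pivoted QR of X itself
  if (is.null(tryCatch(chol(crossprod(X)), error = function(e) NULL))) {
    qrx <- qr(X)
    bad <- if (qrx$rank < p)
      colnames(X)[qrx$pivot[(qrx$rank + 1L):p]] else "(numerically singular)"
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  ## IRLS with canonical log link: W = mu, working response z = eta + (y-mu)/mu
  eta <- log(pmax(y, 0.5))
  dev_old <- Inf
  trace <- numeric(0)
  converged <- FALSE
  beta <- NULL
  for (it in seq_len(maxit)) {
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    sw <- sqrt(mu)
    Xw <- X * sw
    ch <- tryCatch(chol(crossprod(Xw)), error = function(e) NULL)
    if (is.null(ch)) {
      fit <- qr.solve(Xw, z * sw)
      beta <- fit
    } else {
      beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xw, z * sw)))
    }
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    trace <- c(trace, dev)
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged)
    stop("IRLS did not converge in ", maxit, " iterations; deviance trace: ",
         paste(signif(utils::tail(trace, 5), 8), collapse = ", "))
  mu <- exp(drop(X %*% beta))
  pearson <- sum((y - mu)^2 / mu)
  dispersion <- pearson / (n - p)
  XtWX <- crossprod(X * sqrt(mu))
  vcov_unscaled <- chol2inv(chol(XtWX))
  dimnames(vcov_unscaled) <- list(colnames(X), colnames(X))
  beta <- drop(beta)
  names(beta) <- colnames(X)
  structure(list(
    coefficients = beta,
    vcov = dispersion * vcov_unscaled,
    vcov_unscaled = vcov_unscaled,
    dispersion = dispersion,
    poisson_loglik = sum(stats::dpois(y, mu, log = TRUE)),
    deviance = 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu)),
    fitted = mu,
    y = y,
    n_obs = n, n_params = p,
    iter = it, converged = converged
  ), class = "qpfit")
}

#' Quasi-Akaike information criterion
#'
#' `qAIC = -2 * loglik / phi + 2 * p`, penalising the Poisson log-likelihood
#' at the MLE by the model's own Pearson dispersion.  Lower is better.
#'
#' @param fit a `qpfit` (or an object carrying one, e.g. a [tvdlnm()] model).
#' @return numeric qAIC value.
#' @export
qaic <- function(fit) UseMethod("qaic")

#' @export
qaic.qpfit <- function(fit) {
  if (!is.finite(fit$dispersion) || fit$dispersion <= 0)
    stop("degenerate fit: dispersion is ", fit$dispersion)
  -2 * fit$poisson_loglik / fit$dispersion + 2 * fit$n_params
}

#' @export
coef.qpfit <- function(object, ...) object$coefficients

#' @export
vcov.qpfit <- function(object, ...) object$vcov

#' @export
fitted.qpfit <- function(object, ...) object$fitted

#' @export
residuals.qpfit <- function(object,
                            type = c("pearson", "deviance", "response"),
                            ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted
  switch(type,
         pearson = (y - mu) / sqrt(mu),
         deviance = sign(y - mu) *
           sqrt(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))),
         response = y - mu)
}

#' @export
print.qpfit <- function(x, ...) {
  cat(sprintf("quasi-Poisson fit: %d obs, %d parameters, dispersion %.4f\n",
              x$n_obs, x$n_params, x$dispersion))
  cat(sprintf("  Poisson loglik %.3f, qAIC %.2f, %d IRLS iterations\n",
              x$poisson_loglik, qaic(x), x$iter))
  invisible(x)
}
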