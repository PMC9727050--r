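## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: the truncated-power natural-spline construction
## is an alternative parameterization of the same function space, and the
## Newton maximizer optimises the Poisson log-likelihood directly.

## Truncated-power basis of the natural cubic spline space with the given
## interior and boundary knots (constant function excluded, matching an
## intercept-free ns basis after adding the intercept column separately).
## Construction: N1 = x, N_{k+1} = d_k - d_{K+1} with
## d_k(x) = [(x - xi_k)_+^3 - (x - xi_M)_+^3] / (xi_M - xi_k),
## over the full knot sequence xi = (b0, interior..., b1).
tp_ns_basis <- function(x, interior, boundary) {
  xi <- c(boundary[1], interior, boundary[2])
  M <- length(xi)
  pp3 <- function(u) pmax(u, 0)^3
  d <- function(k) (pp3(x - xi[k]) - pp3(x - xi[M])) / (xi[M] - xi[k])
  cols <- list(x)
  for (k in 1:(M - 2)) cols[[k + 1]] <- d(k) - d(M - 1)
  do.call(cbind, cols)
}

## Explicit double-loop crossbasis: entry (t, (i,j)) = sum_l Rfun(x[t-l])[i] *
## Cfun(l)[j], exposure-major column order.  Rfun/Cfun map a scalar to a
## basis row.
crossbasis_double_loop <- function(tmean, Rfun, Cfun, max_lag) {
  n <- length(tmean)
  vx <- length(Rfun(tmean[!is.na(tmean)][1]))
  vl <- length(Cfun(0))
  out <- matrix(NA_real_, n, vx * vl)
  for (t in seq_len(n)) {
    if (t <= max_lag) next
    acc <- matrix(0, vx, vl)
    for (l in 0:max_lag) {
      xt <- tmean[t - l]
      if (is.na(xt)) { acc <- matrix(NA_real_, vx, vl); break }
      acc <- acc + outer(Rfun(xt), Cfun(l))
    }
    out[t, ] <- as.vector(t(acc))   # exposure-major: (i-1)*vl + j
  }
  out
}

## Independent Newton-Raphson maximizer of the Poisson log-likelihood with
## log link: explicit gradient X'(y - mu) and Hessian -X' diag(mu) X.
newton_poisson <- function(y, X, maxit = 100, tol = 1e-13) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 0.1)
  for (i in seq_len(maxit)) {
    mu <- exp(drop(X %*% beta))
    grad <- drop(crossprod(X, y - mu))
    H <- crossprod(X * mu, X)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

## Small deterministic toy dataset for GLM oracle checks.
toy_glm_data <- function(n = 50, p = 3, seed = 402) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * p), n, p))
  colnames(X) <- c("(Intercept)", paste0("x", 1:p))
  beta <- c(1.2, 0.3, -0.2, 0.1)[1:(p + 1)]
  y <- rpois(n, exp(drop(X %*% beta)))
  list(y = y, X = X)
}

## Weather-only series (flat risk surface) used where deaths must follow a
## known in-span or null law built by the test itself.
flat_city <- function(n_years, seed, base_rate = 100) {
  simulate_city(scenario_truth(base_rate = base_rate, beta_cold = 0,
                               beta_heat = 0, mmt_drift = 0),
                n_years = n_years, seed = seed)
}
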