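#' Build the bi-dimensional exposure-lag crossbasis
#'
#' The crossbasis is the tensor-product design block of a distributed lag
#' non-linear model: with exposure basis functions `R_i` and lag basis
#' functions `C_j` (evaluated at integer lags `0..max_lag`), entry
#' `(t, (i,j))` equals `sum_l R_i(tmean[t-l]) * C_j(l)`.  Columns are ordered
#' exposure-major: column `(i-1)*vl + j` pairs exposure function `i` with lag
#' function `j`.  The first `max_lag` rows (insufficient history) and any row
#' whose trailing exposure window contains a missing temperature are `NA`.
#'
#' @param tmean daily mean temperature series (degrees C).
#' @param exposure_spec exposure-dimension [basis_spec()].
#' @param lag_spec lag-dimension [basis_spec()].
#' @param max_lag maximum lag in days (>= 0).
#' @return an object of class `crossbasis`: the numeric matrix with
#'   attributes `exposure_spec`, `lag_spec`, `max_lag`, `complete` (logical
#'   row mask).
#' @export
build_crossbasis <- function(tmean, exposure_spec, lag_spec, max_lag) {
  n <- length(tmean)
  if (n < max_lag + 1L)
    stop("series of length ", n, " shorter than max_lag + 1 = ", max_lag + 1)
  R <- ns_basis(tmean, exposure_spec)            # n x vx
  C <- ns_basis(0:max_lag, lag_spec)             # (max_lag+1) x vl
  vx <- ncol(R); vl <- ncol(C)
  cb <- matrix(0, n, vx * vl)
  for (l in 0:max_lag) {
    Rl <- R[c(rep(NA_integer_, l), seq_len(n - l)), , drop = FALSE]
    if (l > 0) Rl[seq_len(l), ] <- NA_real_
    ## exposure-major: columns (i-1)*vl + j
    cb <- cb + Rl[, rep(seq_len(vx), each = vl), drop = FALSE] *
      matrix(rep(C[l + 1L, ], vx), n, vx * vl, byrow = TRUE)
  }
  colnames(cb) <- paste0("cb.x", rep(seq_len(vx), each = vl),
                         ".l", rep(seq_len(vl), vx))
  complete <- !apply(is.na(cb), 1L, any)
  structure(cb, exposure_spec = exposure_spec, lag_spec = lag_spec,
            max_lag = as.integer(max_lag), complete = complete,
            class = c("crossbasis", "matrix"))
}

#' Overall-cumulative prediction vector at a constant exposure
#'
#' For a day held at temperature `x` over the whole lag window, the
#' lag-cumulated crossbasis contribution reduces to
#' `w_(i,j)(x) = R_i(x) * sum_l C_j(l)`.  Differences `w(x) - w(ref)` against
#' the crossbasis coefficients give lag-cumulated log relative risks; every
#' MMT and cRR computation is built on this vector.
#'
#' @param x temperature(s), degrees C (vectorised).
#' @param exposure_spec,lag_spec the [basis_spec()]s of the crossbasis.
#' @param max_lag maximum lag in days.
#' @return a numeric matrix `length(x)` x `vx*vl` (a vector's worth per row),
#'   exposure-major column order matching [build_crossbasis()].
#' @export
crossbasis_prediction_vector <- function(x, exposure_spec, lag_spec,
                                         max_lag) {
  R <- ns_basis(x, exposure_spec)
  csum <- colSums(ns_basis(0:max_lag, lag_spec))
  vx <- ncol(R); vl <- length(csum)
  W <- R[, rep(seq_len(vx), each = vl), drop = FALSE] *
    matrix(rep(csum, vx), length(x), vx * vl, byrow = TRUE)
  colnames(W) <- paste0("cb.x", rep(seq_len(vx), each = vl),
                        ".l", rep(seq_len(vl), vx))
  W
}
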