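#' Specify a basis for one model dimension
#'
#' A basis specification fixes the function space used for one dimension of
#' the model: a natural cubic spline (cubic between boundary knots, linear
#' beyond them) or a plain linear basis.  The dimension of the spanned space
#' is `#interior knots + 1 + intercept` for natural cubic splines and
#' `1 + intercept` for linear bases.
#'
#' @param kind `"ns"` (natural cubic spline) or `"linear"`.
#' @param interior_knots strictly increasing values strictly inside the
#'   boundary knots (ignored for `"linear"`).
#' @param boundary_knots length-2 increasing numeric vector.
#' @param intercept logical; include the constant function in the basis.
#' @return an object of class `basis_spec`.
#' @export
basis_spec <- function(kind = c("ns", "linear"), interior_knots = numeric(),
                       boundary_knots, intercept = FALSE) {
  kind <- match.arg(kind)
  interior_knots <- as.double(interior_knots)
  boundary_knots <- as.double(boundary_knots)
  if (length(boundary_knots) != 2 || !all(is.finite(boundary_knots)))
    stop("boundary_knots must be two finite values")
  if (boundary_knots[1] >= boundary_knots[2])
    stop("degenerate boundary knots: [", boundary_knots[1], ", ",
         boundary_knots[2], "]")
  if (kind == "ns") {
    if (anyNA(interior_knots) || any(!is.finite(interior_knots)))
      stop("non-finite interior knots")
    if (is.unsorted(interior_knots, strictly = TRUE))
      stop("interior knots must be strictly increasing")
    if (length(interior_knots) &&
        (min(interior_knots) <= boundary_knots[1] ||
         max(interior_knots) >= boundary_knots[2]))
      stop("interior knots must lie strictly inside the boundary knots")
  } else {
    interior_knots <- numeric()
  }
  structure(list(kind = kind, interior_knots = interior_knots,
                 boundary_knots = boundary_knots,
                 intercept = isTRUE(intercept)),
            class = "basis_spec")
}

#' Dimension of a basis specification
#' @param spec a [basis_spec()].
#' @return integer dimension of the spanned space.
#' @export
basis_dim <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (spec$kind == "ns")
    length(spec$interior_knots) + 1L + as.integer(spec$intercept)
  else 1L + as.integer(spec$intercept)
}

#' Evaluate a basis at a vector of points
#'
#' Natural cubic spline columns span the space of cubic splines with the
#' given knots that are linear beyond the boundary knots; evaluation outside
#' the boundaries extrapolates linearly.  Missing values in `x` propagate to
#' missing rows.
#'
#' @param x numeric vector (may contain `NA`).
#' @param spec a [basis_spec()].
#' @return numeric matrix `length(x)` x `basis_dim(spec)`.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  p <- basis_dim(spec)
  out <- matrix(NA_real_, length(x), p)
  ok <- !is.na(x)
  if (!any(ok)) return(out)
  if (spec$kind == "linear") {
    out[ok, ] <- if (spec$intercept) cbind(1, x[ok]) else cbind(x[ok])
  } else {
    out[ok, ] <- splines::ns(
      x[ok],
      knots = if (length(spec$interior_knots)) spec$interior_knots,
      Boundary.knots = spec$boundary_knots,
      intercept = spec$intercept
    )
  }
  out
}

#' Place exposure-dimension knots at temperature percentiles
#'
#' Interior knots are set at empirical percentiles of the observed
#' temperatures (linear interpolation between order statistics, the usual
#' default of scientific stacks); boundary knots at the observed minimum and
#' maximum.  The exposure basis carries no intercept.
#'
#' @param tmean observed daily mean temperatures (degrees C; `NA` allowed).
#' @param percentiles percentiles in (0, 100); default 75.
#' @return a `basis_spec` of kind `"ns"`.
#' @export
place_exposure_knots <- function(tmean, percentiles = 75) {
  x <- tmean[!is.na(tmean)]
  if (!length(x)) stop("all temperatures missing")
  stopifnot(all(percentiles > 0), all(percentiles < 100))
  bnd <- range(x)
  if (bnd[1] == bnd[2])
    stop("constant temperature series: degenerate boundary knots")
  kn <- unname(stats::quantile(x, sort(percentiles) / 100, type = 7))
  basis_spec("ns", interior_knots = kn, boundary_knots = bnd,
             intercept = FALSE)
}

#' Place lag-dimension knots equally spaced on the log scale
#'
#' Interior knots sit at `exp()` of equally spaced points strictly between
#' `log(1)` and `log(max_lag)`: for the defaults (21-day lag, 3 knots) at
#' about 2.14, 4.58 and 9.81 days.  Boundary knots are (0, `max_lag`) and the
#' lag basis carries an intercept, so its dimension is `n_knots + 2`.  If the
#' geometry degenerates (a knot coincides with a boundary, or knots collide)
#' the lag basis falls back to a linear basis with intercept.
#'
#' @param max_lag maximum lag in days (>= 1).
#' @param n_knots number of interior knots (>= 1), default 3.
#' @return a `basis_spec` (kind `"ns"`, or `"linear"` fallback).
#' @export
place_lag_knots <- function(max_lag, n_knots = 3L) {
  stopifnot(max_lag >= 1, n_knots >= 1)
  kn <- exp(seq(0, log(max_lag), length.out = n_knots + 2L))
  kn <- kn[-c(1L, n_knots + 2L)]
  eps <- 1e-8
  if (any(kn <= eps) || any(kn >= max_lag - eps) ||
      any(diff(kn) <= eps)) {
    tv_log("warn",
           "lag knots degenerate for max_lag=%d, n_knots=%d; using linear lag basis",
           max_lag, n_knots)
    return(basis_spec("linear", boundary_knots = c(0, max_lag),
                      intercept = TRUE))
  }
  basis_spec("ns", interior_knots = kn, boundary_knots = c(0, max_lag),
             intercept = TRUE)
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("basis_spec: %s, dim %d%s\n", x$kind, basis_dim(x),
              if (x$intercept) " (with intercept)" else ""))
  if (length(x$interior_knots))
    cat("  interior knots:", paste(signif(x$interior_knots, 4),
                                   collapse = ", "), "\n")
  cat("  boundary knots:", paste(signif(x$boundary_knots, 4),
                                 collapse = ", "), "\n")
  invisible(x)
}
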