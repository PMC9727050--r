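#' @keywords internal
"_PACKAGE"

## Logging -------------------------------------------------------------------

.log_env <- new.env(parent = emptyenv())
.log_env$level <- "info"
.log_env$file <- NULL

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Configure package logging
#'
#' Messages are written to `stderr` as timestamped, level-tagged lines, and
#' optionally appended to a file.
#'
#' @param level minimum level to emit: `"debug"`, `"info"`, `"warn"`,
#'   `"error"`.
#' @param file optional path; when set, log lines are also appended there.
#' @return the previous settings, invisibly.
#' @export
tv_log_config <- function(level = c("info", "debug", "warn", "error"),
                          file = NULL) {
  old <- list(level = .log_env$level, file = .log_env$file)
  .log_env$level <- match.arg(level)
  .log_env$file <- file
  invisible(old)
}

tv_log <- function(level, fmt, ...) {
  if (.log_levels[[level]] < .log_levels[[.log_env$level]]) return(invisible())
  line <- sprintf("[%s] %-5s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), sprintf(fmt, ...))
  cat(line, "\n", file = stderr(), sep = "")
  if (!is.null(.log_env$file)) cat(line, "\n", file = .log_env$file,
                                   append = TRUE, sep = "")
  invisible()
}

## Seed handling -------------------------------------------------------------

#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in the package flows from one root seed, split
#' deterministically per stratum / year / purpose so that independent
#' components draw from independent, reproducible streams.
#'
#' @param root integer root seed.
#' @param ... further integers or strings identifying the sub-stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  parts <- list(...)
  h <- as.double(root) %% 2147483629
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    h <- (h * 48271 + as.double(p) * 7919 + 1) %% 2147483629
  }
  as.integer(h + 1)
}

## Small numeric helpers -----------------------------------------------------

## Trailing moving average over lags 0..lags; NA unless the full window is
## observed (missing regressor rows are dropped later at design assembly).
lagged_mean <- function(x, lags) {
  n <- length(x)
  k <- lags + 1L
  out <- rep(NA_real_, n)
  if (n < k) return(out)
  m <- matrix(NA_real_, n, k)
  for (l in 0:lags) m[(l + 1L):n, l + 1L] <- x[1:(n - l)]
  rowMeans(m)
}

lag_vector <- function(x, l) {
  n <- length(x)
  if (l == 0L) return(x)
  c(rep(NA_real_, l), x[1:(n - l)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
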