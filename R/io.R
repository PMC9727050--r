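#' Construct and validate a daily series
#'
#' A daily series is a `data.frame` holding aligned daily records of the
#' exposure (`tmean`, degrees C), confounders (`rh` in percent, `pm10` in
#' ug/m3, `holiday` indicator) and one or more stratified death-count columns
#' named `deaths_<stratum>`.  Dates must be consecutive calendar days; the
#' day of week (`dow`, 1 = Monday) is derived.  Missing values are permitted
#' inside columns and are counted and logged; they are never imputed.
#'
#' @param df a data.frame with at least columns `date`, `tmean` and one
#'   `deaths_*` column; `rh`, `pm10` and `holiday` are optional and filled
#'   with `NA`/`FALSE` when absent.
#' @return a validated `daily_series` data.frame with a derived `dow` column.
#' @export
daily_series <- function(df) {
  stopifnot(is.data.frame(df), "date" %in% names(df), "tmean" %in% names(df))
  df <- as.data.frame(df)
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable dates in 'date' column")
  dup <- df$date[duplicated(df$date)]
  if (length(dup))
    stop("duplicate date(s): ", paste(format(dup), collapse = ", "))
  d <- as.integer(diff(df$date))
  if (length(d) && any(d != 1L)) {
    bad <- df$date[which(d != 1L)[1] + 1L]
    stop("dates not consecutive at ", format(bad),
         " (strictly increasing daily dates with no gaps required)")
  }
  if (!"rh" %in% names(df)) df$rh <- NA_real_
  if (!"pm10" %in% names(df)) df$pm10 <- NA_real_
  if (!"holiday" %in% names(df)) df$holiday <- FALSE
  df$holiday <- as.logical(df$holiday)
  bad_rh <- which(!is.na(df$rh) & (df$rh < 0 | df$rh > 100))
  if (length(bad_rh))
    stop("relative humidity outside [0,100] at row ", bad_rh[1],
         " (", format(df$date[bad_rh[1]]), "): ", df$rh[bad_rh[1]])
  dcols <- grep("^deaths_", names(df), value = TRUE)
  if (!length(dcols)) stop("no 'deaths_<stratum>' column present")
  for (dc in dcols) {
    v <- df[[dc]]
    if (any(!is.na(v) & (v < 0 | v != round(v))))
      stop("column '", dc, "' contains negative or non-integer counts")
    df[[dc]] <- as.integer(v)
  }
  ## ISO weekday, 1 = Monday
  df$dow <- as.integer(format(df$date, "%u"))
  core <- c("date", "tmean", "rh", "pm10", "holiday", "dow")
  df <- df[, c(core, setdiff(names(df), core))]
  miss <- vapply(df, function(x) sum(is.na(x)), 0L)
  if (any(miss > 0))
    tv_log("info", "daily series: missing values per column: %s",
           paste(sprintf("%s=%d", names(miss)[miss > 0], miss[miss > 0]),
                 collapse = ", "))
  class(df) <- c("daily_series", "data.frame")
  df
}

#' Read a daily series from CSV
#'
#' Expects a header row with `date,tmean,rh,pm10,holiday,deaths_<stratum>...`
#' (extra columns are kept) and ISO-8601 dates.  Validation is as in
#' [daily_series()]: consecutive unique dates, non-negative integer counts,
#' humidity inside \[0,100\].
#'
#' @param path CSV file path.
#' @param config a [tv_config()]; reserved for column-name configuration.
#' @return a `daily_series`.
#' @export
read_daily_series <- function(path, config = tv_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  daily_series(df)
}

#' Write a daily series to CSV
#'
#' The writer/reader pair round-trips losslessly (dates ISO-8601, numeric
#' columns at full precision, `holiday` as 0/1).
#'
#' @param series a `daily_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(series, path) {
  out <- as.data.frame(series)
  out$date <- format(out$date, "%Y-%m-%d")
  out$holiday <- as.integer(out$holiday)
  out$dow <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Aggregate hourly station measurements to a daily mean series
#'
#' Two-stage aggregation used for PM10 (and applicable to any station
#' network): stations whose overall fraction of valid hourly values falls
#' below `min_valid_fraction` are excluded entirely; for retained stations a
#' daily mean is computed from the available hours of each day, provided at
#' least `min_valid_hours` are present; the daily network value is the
#' unweighted mean across retained stations reporting that day.
#'
#' @param hourly data.frame with columns `station`, `datetime` (parseable by
#'   [as.POSIXct()] or a `Date`/`POSIXt`), `value`.
#' @param min_valid_fraction station-retention threshold in (0,1], default
#'   0.75.
#' @param min_valid_hours minimum hours present for a station-day mean,
#'   default 18 (75 percent of 24).
#' @return a data.frame `date,value` (class `daily_aggregate`) with
#'   attributes `n_stations` (retained count) and `stations` (their labels).
#' @export
aggregate_hourly <- function(hourly, min_valid_fraction = 0.75,
                             min_valid_hours = 18L) {
  stopifnot(is.data.frame(hourly),
            all(c("station", "datetime", "value") %in% names(hourly)),
            min_valid_fraction > 0, min_valid_fraction <= 1)
  dt <- hourly$datetime
  if (!inherits(dt, c("POSIXt", "Date"))) dt <- as.POSIXct(dt, tz = "UTC")
  day <- as.Date(dt)
  valid_frac <- tapply(!is.na(hourly$value), hourly$station, mean)
  keep <- names(valid_frac)[valid_frac >= min_valid_fraction]
  if (!length(keep))
    stop("no station reaches the ", min_valid_fraction,
         " valid-data fraction threshold")
  tv_log("info", "aggregate_hourly: %d of %d stations retained",
         length(keep), length(valid_frac))
  sel <- hourly$station %in% keep
  key <- interaction(day[sel], hourly$station[sel], drop = TRUE)
  nv <- tapply(!is.na(hourly$value[sel]), key, sum)
  mu <- tapply(hourly$value[sel], key, mean, na.rm = TRUE)
  mu[nv < min_valid_hours] <- NA_real_
  parts <- strsplit(names(mu), ".", fixed = TRUE)
  sd_day <- as.Date(vapply(parts, `[[`, "", 1L))
  daily <- tapply(as.double(mu), sd_day, mean, na.rm = TRUE)
  daily[is.nan(daily)] <- NA_real_
  out <- data.frame(date = as.Date(names(daily)), value = as.double(daily))
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_stations = length(keep), stations = sort(keep),
            class = c("daily_aggregate", "data.frame"))
}

#' Default mortality stratification scheme
#'
#' The study's population strata over individual death records carrying
#' `sex` (`"female"`/`"male"`), `age` (years), `ethnicity`
#' (`"white"`/`"nonwhite"`) and `education` (years): overall, by sex, by age
#' group (65--79 and >= 80), by ethnic group, and sex x age combinations.
#' Each stratum is a predicate over the record table plus the fields it
#' requires to be non-missing.
#'
#' @return a named list of strata, each `list(requires=, predicate=)`.
#' @export
default_strata <- function() {
  list(
    all = list(requires = character(),
               predicate = function(r) rep(TRUE, nrow(r))),
    female = list(requires = "sex", predicate = function(r) r$sex == "female"),
    male = list(requires = "sex", predicate = function(r) r$sex == "male"),
    age65_79 = list(requires = "age",
                    predicate = function(r) r$age >= 65 & r$age <= 79),
    age80plus = list(requires = "age", predicate = function(r) r$age >= 80),
    white = list(requires = "ethnicity",
                 predicate = function(r) r$ethnicity == "white"),
    nonwhite = list(requires = "ethnicity",
                    predicate = function(r) r$ethnicity == "nonwhite"),
    female_80plus = list(requires = c("sex", "age"),
                         predicate = function(r)
                           r$sex == "female" & r$age >= 80),
    male_80plus = list(requires = c("sex", "age"),
                       predicate = function(r)
                         r$sex == "male" & r$age >= 80)
  )
}

#' Build daily stratified death counts from individual records
#'
#' For each stratum, records with any missing required field are excluded
#' from that stratum's column only (they still count wherever their fields
#' suffice); exclusion tallies are returned for the missing-data bias check.
#'
#' @param records data.frame of individual deaths with a `date` column plus
#'   the covariates the scheme requires.
#' @param dates `Date` vector of consecutive days defining the series range.
#' @param scheme a stratification scheme as from [default_strata()].
#' @return data.frame `date, deaths_<stratum>...` with attribute
#'   `excluded` (named integer vector of per-stratum exclusion counts).
#' @export
build_stratum_counts <- function(records, dates,
                                 scheme = default_strata()) {
  stopifnot(is.data.frame(records), "date" %in% names(records))
  rd <- as.Date(records$date)
  if (any(rd < min(dates) | rd > max(dates)))
    stop("record date(s) outside the series range: ",
         format(min(rd[rd < min(dates) | rd > max(dates)])))
  out <- data.frame(date = dates)
  excluded <- integer(length(scheme))
  names(excluded) <- names(scheme)
  fd <- factor(rd, levels = as.character(dates))
  for (s in names(scheme)) {
    req <- scheme[[s]]$requires
    ok <- if (length(req))
      !Reduce(`|`, lapply(req, function(f) is.na(records[[f]])))
    else rep(TRUE, nrow(records))
    excluded[s] <- sum(!ok)
    inb <- ok & !is.na(ok)
    hit <- rep(FALSE, nrow(records))
    hit[inb] <- scheme[[s]]$predicate(records[inb, , drop = FALSE]) %in% TRUE
    out[[paste0("deaths_", s)]] <- as.integer(table(fd[hit]))
  }
  structure(out, excluded = excluded)
}
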