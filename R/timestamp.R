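#' Create a calendar timestamp with explicit granularity
#'
#' A timestamp is a calendar position whose precision is stated explicitly:
#' fields finer than the granularity are absent, fields at or coarser than
#' it are present, and the combination must be calendar-valid (month
#' lengths, leap years) on the proleptic Gregorian calendar.
#'
#' @param year Integer year.
#' @param month Integer month 1-12, or `NULL` for year granularity.
#' @param day Integer day of month, or `NULL`.
#' @param hour Integer hour 0-23, or `NULL`.
#' @param minute Integer minute 0-59, or `NULL`.
#' @param granularity Granularity string; if `NULL`, inferred as the finest
#'   field supplied.
#' @return An object of class `cntro_timestamp`.
#' @examples
#' timestamp(2006, 5)            # May 2006, month granularity
#' timestamp(2006, 7, 14)        # day granularity
#' @export
timestamp <- function(year, month = NULL, day = NULL, hour = NULL,
                      minute = NULL, granularity = NULL) {
  fields <- list(year = year, month = month, day = day,
                 hour = hour, minute = minute)
  present <- !vapply(fields, is.null, logical(1))
  if (!present[["year"]]) {
    stop_narratime("invalid_timestamp", "timestamp requires a year")
  }
  # fields must be contiguous from year down to the finest one given
  finest <- max(which(present))
  if (!all(present[seq_len(finest)])) {
    missing <- names(fields)[seq_len(finest)][!present[seq_len(finest)]]
    stop_narratime("invalid_timestamp",
                   sprintf("field '%s' absent but finer fields present", missing[1]))
  }
  # order year..minute corresponds to granularity year..minute
  inferred <- rev(GRANULARITIES)[finest]
  if (is.null(granularity)) {
    granularity <- inferred
  } else {
    granularity <- as_granularity(granularity)
    if (granularity != inferred) {
      stop_narratime("invalid_timestamp",
                     sprintf("granularity '%s' does not match supplied fields ('%s')",
                             granularity, inferred))
    }
  }
  out <- lapply(fields, function(x) if (is.null(x)) NA_integer_ else as.integer(x))
  out$granularity <- granularity
  class(out) <- "cntro_timestamp"
  validate_timestamp(out)
  out
}

validate_timestamp <- function(ts) {
  if (!is.na(ts$month) && (ts$month < 1L || ts$month > 12L)) {
    stop_narratime("invalid_timestamp", sprintf("month %d out of range", ts$month))
  }
  if (!is.na(ts$day)) {
    dim_ <- days_in_month(ts$year, ts$month)
    if (ts$day < 1L || ts$day > dim_) {
      stop_narratime("invalid_timestamp",
                     sprintf("day %d invalid for %04d-%02d", ts$day, ts$year, ts$month))
    }
  }
  if (!is.na(ts$hour) && (ts$hour < 0L || ts$hour > 23L)) {
    stop_narratime("invalid_timestamp", sprintf("hour %d out of range", ts$hour))
  }
  if (!is.na(ts$minute) && (ts$minute < 0L || ts$minute > 59L)) {
    stop_narratime("invalid_timestamp", sprintf("minute %d out of range", ts$minute))
  }
  invisible(ts)
}

is_leap_year <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  d[month == 2L & is_leap_year(year)] <- 29L
  d
}

#' Test for a timestamp object
#' @param x Object.
#' @return Logical scalar.
#' @export
is_timestamp <- function(x) inherits(x, "cntro_timestamp")

#' Truncate a timestamp to a coarser granularity
#'
#' Removes all fields finer than `g`. Requesting a granularity finer than
#' the one the timestamp carries is an error: precision is never invented.
#'
#' @param ts A `cntro_timestamp`.
#' @param g Target granularity (coarser than or equal to `ts`).
#' @return A `cntro_timestamp` at granularity `g`.
#' @examples
#' ts_truncate(timestamp(2006, 7, 14), "month")  # 2006-07
#' @export
ts_truncate <- function(ts, g) {
  stopifnot(is_timestamp(ts))
  g <- as_granularity(g)
  if (!gran_ge(g, ts$granularity)) {
    stop_narratime("cannot_refine",
                   sprintf("cannot refine: timestamp has granularity '%s', requested finer '%s'",
                           ts$granularity, g))
  }
  if (g == ts$granularity) return(ts)
  keep <- rev(GRANULARITIES)[seq_len(6L - gran_level(g))]
  out <- ts
  for (f in setdiff(c("year", "month", "day", "hour", "minute"), keep)) {
    out[[f]] <- NA_integer_
  }
  out$granularity <- g
  out
}

# internal: Date / POSIXct bridges (UTC, proleptic Gregorian)
ts_to_date <- function(ts) {
  as.Date(sprintf("%04d-%02d-%02d", ts$year, ts$month, ts$day))
}
ts_to_posix <- function(ts) {
  ISOdatetime(ts$year, ts$month, ts$day, ts$hour,
              if (is.na(ts$minute)) 0L else ts$minute, 0, tz = "UTC")
}
date_to_ts <- function(d) {
  p <- as.POSIXlt(d)
  timestamp(p$year + 1900L, p$mon + 1L, p$mday)
}

# month index helpers (month granularity arithmetic)
ts_month_index <- function(ts) ts$year * 12L + (ts$month - 1L)

# shift a (year, month, day) triple by n months, clamping day-of-month
# (Jan 31 + 1 month = Feb 28/29); day may be NA
shift_months <- function(year, month, day, n) {
  idx <- year * 12L + (month - 1L) + as.integer(n)
  y <- idx %/% 12L
  m <- idx %% 12L + 1L
  d <- day
  if (!is.na(d)) d <- min(d, days_in_month(y, m))
  list(year = y, month = m, day = d)
}

#' Add or subtract a duration from a timestamp
#'
#' Calendar-correct arithmetic that never manufactures precision: the
#' result granularity is the coarser of the timestamp's granularity and
#' the duration's unit. The duration magnitude is first converted to that
#' granularity (30-day months, 12-month years, round half up), so a 60-day
#' offset moves a month-granularity stamp by 2 months while a 1-day offset
#' leaves it unchanged.
#'
#' @param ts A `cntro_timestamp`.
#' @param d A `cntro_duration` (not a range).
#' @param sign `+1` to add, `-1` to subtract.
#' @return A `cntro_timestamp`.
#' @examples
#' add_duration(timestamp(2006, 5, 1), duration(60, "day"), +1)  # 2006-06-30
#' add_duration(timestamp(2006, 5), duration(2, "month"), +1)    # 2006-07
#' @export
add_duration <- function(ts, d, sign = 1L) {
  stopifnot(is_timestamp(ts), is_duration(d))
  if (!sign %in% c(1L, -1L, 1, -1)) {
    stop_narratime("invalid_argument", "sign must be +1 or -1")
  }
  if (d$is_range) {
    stop_narratime("range_not_addable", "range duration not addable")
  }
  g_res <- gran_coarser(ts$granularity, d$unit)
  mag <- convert_duration(d, g_res)$magnitude
  base <- ts_truncate(ts, g_res)
  n <- as.integer(sign) * mag
  if (n == 0L) return(base)
  switch(g_res,
    year = {
      out <- base
      out$year <- base$year + n
      out
    },
    month = {
      s <- shift_months(base$year, base$month, NA_integer_, n)
      timestamp(s$year, s$month)
    },
    day = date_to_ts(ts_to_date(base) + n),
    hour = ,
    minute = {
      secs <- n * if (g_res == "hour") 3600 else 60
      p <- as.POSIXlt(ts_to_posix(base) + secs, tz = "UTC")
      timestamp(p$year + 1900L, p$mon + 1L, p$mday, p$hour,
                if (g_res == "minute") p$min else NULL)
    }
  )
}

#' Duration between two timestamps at a stated granularity
#'
#' Both timestamps are truncated to `g` before differencing, so the result
#' is exact at that granularity: calendar month/year counts for coarse
#' units, exact day/hour/minute counts for fine ones. The result is a
#' non-negative duration (symmetric in its arguments).
#'
#' @param a,b `cntro_timestamp` objects.
#' @param g Output granularity; must be at or coarser than the coarser of
#'   the two input granularities.
#' @return A `cntro_duration` in unit `g`.
#' @examples
#' timestamp_difference(timestamp(2006, 5), timestamp(2006, 7), "month")  # 2 months
#' @export
timestamp_difference <- function(a, b, g) {
  stopifnot(is_timestamp(a), is_timestamp(b))
  g <- as_granularity(g)
  coarsest_input <- gran_coarser(a$granularity, b$granularity)
  if (!gran_ge(g, coarsest_input)) {
    stop_narratime("cannot_refine",
                   sprintf("difference granularity '%s' finer than inputs allow ('%s')",
                           g, coarsest_input))
  }
  ta <- ts_truncate(a, g)
  tb <- ts_truncate(b, g)
  n <- switch(g,
    year = abs(ta$year - tb$year),
    month = abs(ts_month_index(ta) - ts_month_index(tb)),
    day = abs(as.integer(ts_to_date(ta) - ts_to_date(tb))),
    hour = abs(as.numeric(difftime(ts_to_posix(ta), ts_to_posix(tb), units = "hours"))),
    minute = abs(as.numeric(difftime(ts_to_posix(ta), ts_to_posix(tb), units = "mins")))
  )
  duration(round(n), g)
}

# -1 / 0 / +1 comparison of two timestamps at the coarser common granularity;
# returns list(cmp, granularity)
ts_compare <- function(a, b) {
  g <- gran_coarser(a$granularity, b$granularity)
  ta <- ts_truncate(a, g)
  tb <- ts_truncate(b, g)
  for (f in c("year", "month", "day", "hour", "minute")) {
    x <- ta[[f]]; y <- tb[[f]]
    if (is.na(x) || is.na(y)) break
    if (x < y) return(list(cmp = -1L, granularity = g))
    if (x > y) return(list(cmp = 1L, granularity = g))
  }
  list(cmp = 0L, granularity = g)
}

#' @export
format.cntro_timestamp <- function(x, ...) {
  switch(x$granularity,
    year = sprintf("%04d", x$year),
    month = sprintf("%04d-%02d", x$year, x$month),
    day = sprintf("%04d-%02d-%02d", x$year, x$month, x$day),
    hour = sprintf("%04d-%02d-%02dT%02d", x$year, x$month, x$day, x$hour),
    minute = sprintf("%04d-%02d-%02dT%02d:%02d",
                     x$year, x$month, x$day, x$hour, x$minute)
  )
}

#' @export
print.cntro_timestamp <- function(x, ...) {
  cat(sprintf("<timestamp %s (%s)>\n", format(x), x$granularity))
  invisible(x)
}

#' @export
`==.cntro_timestamp` <- function(e1, e2) {
  identical(unclass(e1), unclass(e2))
}

ts_equal <- function(a, b) identical(unclass(a), unclass(b))
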