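#' Create a duration
#'
#' A signed-magnitude-free duration: a non-negative integer magnitude with
#' a granularity unit. Narratives occasionally state durations as ranges
#' ("2-3 months"); these are representable (`range_high`) but excluded
#' from arithmetic, and the reasoner reports them as insufficient
#' precision rather than guessing.
#'
#' @param magnitude Non-negative integer count of `unit`s (low end when a
#'   range).
#' @param unit Granularity string.
#' @param range_high Optional integer strictly greater than `magnitude`;
#'   when supplied the duration is a range.
#' @return An object of class `cntro_duration`.
#' @examples
#' duration(2, "month")
#' duration(2, "month", range_high = 3)  # "2-3 months"
#' @export
duration <- function(magnitude, unit, range_high = NULL) {
  unit <- as_granularity(unit)
  if (length(magnitude) != 1L || is.na(magnitude) || magnitude < 0) {
    stop_narratime("invalid_duration", "magnitude must be a single non-negative number")
  }
  magnitude <- as.integer(round(magnitude))
  is_range <- !is.null(range_high)
  if (is_range) {
    range_high <- as.integer(round(range_high))
    if (range_high <= magnitude) {
      stop_narratime("invalid_duration", "range_high must exceed magnitude")
    }
  }
  structure(
    list(magnitude = magnitude, unit = unit, is_range = is_range,
         range_high = if (is_range) range_high else NA_integer_),
    class = "cntro_duration"
  )
}

#' Test for a duration object
#' @param x Object.
#' @return Logical scalar.
#' @export
is_duration <- function(x) inherits(x, "cntro_duration")

#' Convert a duration to another unit
#'
#' Deterministic conversion under the fixed conventions 1 year = 12
#' months, 1 month = 30 days, 1 day = 24 hours, 1 hour = 60 minutes.
#' Converting to a coarser unit rounds to the nearest integer with ties
#' rounding up (60 days -> 2 months, 45 days -> 2 months). Ranges must be
#' resolved before conversion.
#'
#' @param d A `cntro_duration` (not a range).
#' @param g Target unit.
#' @return A `cntro_duration` in unit `g`.
#' @examples
#' convert_duration(duration(1, "year"), "month")  # 12 months
#' convert_duration(duration(60, "day"), "month")  # 2 months
#' @export
convert_duration <- function(d, g) {
  stopifnot(is_duration(d))
  g <- as_granularity(g)
  if (d$is_range) {
    stop_narratime("range_conversion", "normalize ranges upstream")
  }
  if (g == d$unit) return(d)
  v <- d$magnitude * MINUTES_PER_UNIT[[d$unit]] / MINUTES_PER_UNIT[[g]]
  duration(round_half_up(v), g)
}

round_half_up <- function(x) floor(x + 0.5)

# exact minutes under the fixed conventions (non-range only)
duration_minutes <- function(d) d$magnitude * MINUTES_PER_UNIT[[d$unit]]

minutes_to_duration <- function(minutes, g) {
  duration(round_half_up(abs(minutes) / MINUTES_PER_UNIT[[g]]), g)
}

#' @export
format.cntro_duration <- function(x, ...) {
  unit <- if (x$is_range) {
    if (x$range_high == 1L) x$unit else paste0(x$unit, "s")
  } else if (x$magnitude == 1L) x$unit else paste0(x$unit, "s")
  if (x$is_range) {
    sprintf("%d-%d %s", x$magnitude, x$range_high, unit)
  } else {
    sprintf("%d %s", x$magnitude, unit)
  }
}

#' @export
print.cntro_duration <- function(x, ...) {
  cat(sprintf("<duration %s>\n", format(x)))
  invisible(x)
}

#' @export
`==.cntro_duration` <- function(e1, e2) {
  identical(unclass(e1), unclass(e2))
}

duration_equal <- function(a, b) identical(unclass(a), unclass(b))
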