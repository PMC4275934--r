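#' Time granularities
#'
#' The five granularity levels used throughout the package, ordered from
#' finest to coarsest: minute < hour < day < month < year. A coarser
#' granularity compares as greater.
#'
#' @format Character vector of length 5.
#' @export
GRANULARITIES <- c("minute", "hour", "day", "month", "year")

# minutes per unit under the fixed conversion conventions:
# 1 year = 12 months, 1 month = 30 days, 1 day = 24 hours, 1 hour = 60 minutes
MINUTES_PER_UNIT <- c(
  minute = 1,
  hour   = 60,
  day    = 60 * 24,
  month  = 60 * 24 * 30,
  year   = 60 * 24 * 30 * 12
)

#' Validate a granularity label
#'
#' @param g Character scalar, one of [GRANULARITIES] (case-insensitive).
#' @return The canonical lowercase granularity string.
#' @export
as_granularity <- function(g) {
  if (length(g) != 1L || is.na(g) || !is.character(g)) {
    stop_narratime("invalid_granularity", "granularity must be a single string")
  }
  g <- tolower(g)
  if (!g %in% GRANULARITIES) {
    stop_narratime(
      "invalid_granularity",
      sprintf("unknown granularity '%s' (expected one of %s)",
              g, paste(GRANULARITIES, collapse = ", "))
    )
  }
  g
}

#' Rank of a granularity (1 = minute ... 5 = year)
#' @param g Granularity string.
#' @return Integer rank; larger means coarser.
#' @export
gran_level <- function(g) match(as_granularity(g), GRANULARITIES)

#' Coarser of two granularities
#' @param a,b Granularity strings.
#' @return The coarser granularity.
#' @export
gran_coarser <- function(a, b) {
  GRANULARITIES[max(gran_level(a), gran_level(b))]
}

# TRUE if a is coarser than or equal to b
gran_ge <- function(a, b) gran_level(a) >= gran_level(b)

# classed error helper used across the package
stop_narratime <- function(class, message, ...) {
  stop(structure(
    class = c(paste0("narratime_", class), "narratime_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}
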