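# Rule-based normalization of free-text temporal expressions into
# timestamps and durations. Unrecognized input is a value (kind
# "unsupported" with a note), never an exception: annotation ingestion
# must be total over arbitrary strings.

MONTH_NAMES <- tolower(month.name)
MONTH_ABBREVS <- tolower(month.abb)

NUMBER_WORDS <- c(
  zero = 0L, one = 1L, two = 2L, three = 3L, four = 4L, five = 5L,
  six = 6L, seven = 7L, eight = 8L, nine = 9L, ten = 10L,
  eleven = 11L, twelve = 12L
)

norm_result <- function(kind, value, source_text, note = "") {
  structure(
    list(kind = kind, value = value, source_text = source_text, note = note),
    class = "normalization_result"
  )
}

unsupported <- function(text, note) norm_result("unsupported", NULL, text, note)

month_number <- function(word) {
  w <- tolower(word)
  m <- match(w, MONTH_NAMES)
  if (is.na(m)) m <- match(w, MONTH_ABBREVS)
  m
}

#' Normalize a temporal expression to a timestamp
#'
#' Recognizes, case-insensitively: ISO forms `YYYY`, `YYYY-MM`,
#' `YYYY-MM-DD`, `YYYY-MM-DDTHH` and `YYYY-MM-DDTHH:MM`; slash dates
#' (`MM/DD/YYYY` under the default US dialect, `DD/MM/YYYY` under
#' `dialect = "intl"`); and English month-name forms `"May 2006"` and
#' `"May 14, 2006"`. Anything else, including calendar-invalid dates,
#' yields `kind = "unsupported"` with an explanatory note.
#'
#' @param text Non-empty character scalar.
#' @param dialect `"us"` (month first) or `"intl"` (day first) for slash
#'   dates.
#' @return A `normalization_result`: list with `kind`
#'   (`"timestamp"`/`"unsupported"`), `value`, `source_text`, `note`.
#' @examples
#' normalize_time_expression("May 2006")
#' normalize_time_expression("2006-07-14")
#' @export
normalize_time_expression <- function(text, dialect = c("us", "intl")) {
  dialect <- match.arg(dialect)
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    return(unsupported(as.character(text)[1], "empty expression"))
  }
  s <- trimws(text)
  build <- function(...) {
    tryCatch(norm_result("timestamp", timestamp(...), s),
             narratime_error = function(e) unsupported(s, conditionMessage(e)))
  }
  m <- regmatches(s, regexec("^(\\d{4})-(\\d{2})-(\\d{2})[T ](\\d{1,2}):(\\d{2})$", s))[[1]]
  if (length(m)) {
    n <- as.integer(m[-1])
    return(build(n[1], n[2], n[3], n[4], n[5]))
  }
  m <- regmatches(s, regexec("^(\\d{4})-(\\d{2})-(\\d{2})[T ](\\d{1,2})$", s))[[1]]
  if (length(m)) {
    n <- as.integer(m[-1])
    return(build(n[1], n[2], n[3], n[4]))
  }
  m <- regmatches(s, regexec("^(\\d{4})-(\\d{2})-(\\d{2})$", s))[[1]]
  if (length(m)) {
    n <- as.integer(m[-1])
    return(build(n[1], n[2], n[3]))
  }
  m <- regmatches(s, regexec("^(\\d{4})-(\\d{2})$", s))[[1]]
  if (length(m)) {
    n <- as.integer(m[-1])
    return(build(n[1], n[2]))
  }
  m <- regmatches(s, regexec("^(\\d{1,2})/(\\d{1,2})/(\\d{4})$", s))[[1]]
  if (length(m)) {
    n <- as.integer(m[-1])
    if (dialect == "us") return(build(n[3], n[1], n[2]))
    return(build(n[3], n[2], n[1]))
  }
  m <- regmatches(s, regexec("^([A-Za-z]+)\\.?,?\\s+(\\d{1,2}),?\\s+(\\d{4})$", s))[[1]]
  if (length(m)) {
    mo <- month_number(m[2])
    if (!is.na(mo)) return(build(as.integer(m[4]), mo, as.integer(m[3])))
  }
  m <- regmatches(s, regexec("^([A-Za-z]+)\\.?,?\\s+(\\d{4})$", s))[[1]]
  if (length(m)) {
    mo <- month_number(m[2])
    if (!is.na(mo)) return(build(as.integer(m[3]), mo))
  }
  if (grepl("^\\d{4}$", s)) {
    return(build(as.integer(s)))
  }
  unsupported(s, "no parse rule")
}

parse_magnitude <- function(token) {
  token <- tolower(token)
  if (grepl("^\\d+$", token)) return(as.integer(token))
  if (token %in% names(NUMBER_WORDS)) return(NUMBER_WORDS[[token]])
  NA_integer_
}

UNIT_RE <- "(minutes?|mins?|hours?|hrs?|days?|months?|years?|yrs?)"

parse_unit <- function(token) {
  token <- tolower(token)
  if (grepl("^min", token)) return("minute")
  if (grepl("^(hour|hr)", token)) return("hour")
  if (grepl("^day", token)) return("day")
  if (grepl("^month", token)) return("month")
  if (grepl("^(year|yr)", token)) return("year")
  NA_character_
}

#' Normalize a duration expression
#'
#' Recognizes digit and English number-word magnitudes (zero through
#' twelve) with singular or plural units minute/hour/day/month/year, and
#' range forms `"2-3 months"`. Compound mixed-granularity expressions
#' ("two months and ten days") are a documented annotation failure mode
#' and are flagged unsupported with note `"mixed granularity"` rather than
#' silently guessed; set `resolve_mixed = TRUE` to convert them to the
#' finer unit under the 30-day-month convention instead.
#'
#' @param text Non-empty character scalar.
#' @param resolve_mixed Convert compound expressions to the finer unit
#'   instead of flagging them.
#' @return A `normalization_result` with `kind`
#'   (`"duration"`/`"unsupported"`).
#' @examples
#' normalize_duration_expression("two months")
#' normalize_duration_expression("2-3 months")
#' @export
normalize_duration_expression <- function(text, resolve_mixed = FALSE) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    return(unsupported(as.character(text)[1], "empty expression"))
  }
  s <- trimws(text)
  num_re <- "(\\d+|[A-Za-z]+)"
  # compound "X unit(s) and Y unit(s)"
  re <- paste0("^", num_re, "\\s+", UNIT_RE, ",?\\s+and\\s+", num_re, "\\s+", UNIT_RE, "$")
  m <- regmatches(s, regexec(re, s, ignore.case = TRUE))[[1]]
  if (length(m)) {
    m1 <- parse_magnitude(m[2]); u1 <- parse_unit(m[3])
    m2 <- parse_magnitude(m[4]); u2 <- parse_unit(m[5])
    if (is.na(m1) || is.na(m2)) return(unsupported(s, "magnitude not recognized"))
    if (!resolve_mixed) return(unsupported(s, "mixed granularity"))
    fine <- GRANULARITIES[min(gran_level(u1), gran_level(u2))]
    total <- convert_duration(duration(m1, u1), fine)$magnitude +
      convert_duration(duration(m2, u2), fine)$magnitude
    return(norm_result("duration", duration(total, fine), s))
  }
  # range "N-M unit"
  re <- paste0("^(\\d+)\\s*-\\s*(\\d+)\\s+", UNIT_RE, "$")
  m <- regmatches(s, regexec(re, s, ignore.case = TRUE))[[1]]
  if (length(m)) {
    lo <- as.integer(m[2]); hi <- as.integer(m[3]); u <- parse_unit(m[4])
    if (hi <= lo) return(unsupported(s, "range high end not above low end"))
    return(norm_result("duration", duration(lo, u, range_high = hi), s))
  }
  # simple "N unit"
  re <- paste0("^", num_re, "\\s+", UNIT_RE, "$")
  m <- regmatches(s, regexec(re, s, ignore.case = TRUE))[[1]]
  if (length(m)) {
    mag <- parse_magnitude(m[2])
    if (is.na(mag)) {
      note <- if (grepl("^[a-z]+$", tolower(m[2]))) {
        "number word outside zero-twelve"
      } else "magnitude not recognized"
      return(unsupported(s, note))
    }
    return(norm_result("duration", duration(mag, parse_unit(m[3])), s))
  }
  unsupported(s, "no parse rule")
}

#' @export
print.normalization_result <- function(x, ...) {
  if (x$kind == "unsupported") {
    cat(sprintf("<normalization '%s': unsupported (%s)>\n", x$source_text, x$note))
  } else {
    cat(sprintf("<normalization '%s': %s %s>\n", x$source_text, x$kind,
                format(x$value)))
  }
  invisible(x)
}
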