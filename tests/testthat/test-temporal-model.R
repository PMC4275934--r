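test_that("truncation removes finer fields and refuses to refine", {
  expect_equal(ts_truncate(timestamp(2006, 7, 14), "month"), timestamp(2006, 7))
  expect_equal(ts_truncate(timestamp(2006, 5), "month"), timestamp(2006, 5))
  expect_error(ts_truncate(timestamp(2006, 5), "day"),
               class = "narratime_cannot_refine")
  # idempotence over a grid of stamps and granularities
  stamps <- list(timestamp(2006, 7, 14, 13, 5), timestamp(2006, 7, 14),
                 timestamp(2006, 7), timestamp(2006))
  for (ts in stamps) {
    for (g in GRANULARITIES[gran_level(ts$granularity):5]) {
      once <- ts_truncate(ts, g)
      expect_equal(ts_truncate(once, g), once)
    }
  }
})

test_that("duration addition is calendar-correct", {
  # oracle: base-R Date arithmetic
  expect_equal(format(add_duration(timestamp(2006, 5, 1), duration(60, "day"), +1)),
               format(as.Date("2006-05-01") + 60))
  expect_equal(add_duration(timestamp(2006, 5), duration(2, "month"), +1),
               timestamp(2006, 7))
  ts <- timestamp(2006, 5, 1)
  expect_equal(add_duration(ts, duration(0, "day"), +1), ts)
  # leap-year day arithmetic
  expect_equal(format(add_duration(timestamp(2008, 2, 28), duration(1, "day"), +1)),
               "2008-02-29")
  # year rollover at month granularity
  expect_equal(add_duration(timestamp(2006, 11), duration(3, "month"), +1),
               timestamp(2007, 2))
  expect_error(add_duration(ts, duration(2, "month", range_high = 3), +1),
               class = "narratime_range_not_addable")
})

test_that("result granularity of addition is the coarser of the inputs", {
  # day offsets vanish against month stamps instead of minting fake days
  got <- add_duration(timestamp(2006, 7), duration(1, "day"), -1)
  expect_equal(got, timestamp(2006, 7))
  got <- add_duration(timestamp(2006, 5), duration(60, "day"), +1)
  expect_equal(got, timestamp(2006, 7))
  # month offsets coarsen day stamps
  got <- add_duration(timestamp(2006, 5, 17), duration(2, "month"), +1)
  expect_equal(got, timestamp(2006, 7))
})

test_that("add/subtract round-trips at the stamp's own resolution", {
  set.seed(42)
  for (i in 1:50) {
    base <- as.Date("2004-01-01") + sample(0:2000, 1)
    p <- as.POSIXlt(base)
    cases <- list(
      list(ts = timestamp(p$year + 1900, p$mon + 1, p$mday),
           d = duration(sample(0:400, 1), "day")),
      list(ts = timestamp(p$year + 1900, p$mon + 1),
           d = duration(sample(0:30, 1), "month")),
      list(ts = timestamp(p$year + 1900),
           d = duration(sample(0:10, 1), "year"))
    )
    for (cs in cases) {
      there <- add_duration(cs$ts, cs$d, +1)
      expect_equal(add_duration(there, cs$d, -1), cs$ts)
    }
  }
})

test_that("timestamp differences are exact and symmetric", {
  expect_equal(timestamp_difference(timestamp(2006, 5), timestamp(2006, 7), "month"),
               duration(2, "month"))
  x <- timestamp(2006, 7, 14)
  expect_equal(timestamp_difference(x, x, "day"), duration(0, "day"))
  expect_equal(timestamp_difference(x, x, "year"), duration(0, "year"))
  # oracle: calendar day count across February
  expect_equal(timestamp_difference(timestamp(2006, 1, 1), timestamp(2006, 3, 1), "day"),
               duration(as.integer(as.Date("2006-03-01") - as.Date("2006-01-01")), "day"))
  expect_equal(timestamp_difference(timestamp(2006, 1, 1), timestamp(2006, 3, 1), "day"),
               duration(59, "day"))
  set.seed(7)
  for (i in 1:25) {
    a <- timestamp(sample(2000:2010, 1), sample(1:12, 1), sample(1:28, 1))
    b <- timestamp(sample(2000:2010, 1), sample(1:12, 1), sample(1:28, 1))
    for (g in c("day", "month", "year")) {
      expect_equal(timestamp_difference(a, b, g), timestamp_difference(b, a, g))
    }
  }
  expect_error(timestamp_difference(timestamp(2006, 5), timestamp(2006, 7, 1), "day"),
               class = "narratime_cannot_refine")
})

test_that("duration conversion follows the fixed conventions", {
  expect_equal(convert_duration(duration(1, "year"), "month"), duration(12, "month"))
  expect_equal(convert_duration(duration(60, "day"), "month"), duration(2, "month"))
  expect_equal(convert_duration(duration(2, "month"), "month"), duration(2, "month"))
  # round half up at the tie
  expect_equal(convert_duration(duration(45, "day"), "month"), duration(2, "month"))
  expect_equal(convert_duration(duration(44, "day"), "month"), duration(1, "month"))
  expect_error(convert_duration(duration(2, "month", range_high = 3), "day"),
               class = "narratime_range_conversion")
  # exact round trips for unit multiples
  for (m in c(0L, 12L, 24L, 60L)) {
    expect_equal(
      convert_duration(convert_duration(duration(m, "month"), "year"), "month"),
      duration(m, "month"))
  }
  for (d in c(0L, 30L, 90L, 300L)) {
    expect_equal(
      convert_duration(convert_duration(duration(d, "day"), "month"), "day"),
      duration(d, "day"))
  }
})

test_that("timestamps validate calendar structure", {
  expect_error(timestamp(2006, 2, 29), class = "narratime_invalid_timestamp")
  expect_silent(timestamp(2008, 2, 29))  # leap year
  expect_error(timestamp(2006, 13), class = "narratime_invalid_timestamp")
  expect_error(timestamp(2006, day = 5), class = "narratime_invalid_timestamp")
  expect_error(duration(2, "month", range_high = 2),
               class = "narratime_invalid_duration")
  expect_error(duration(-1, "day"), class = "narratime_invalid_duration")
})
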