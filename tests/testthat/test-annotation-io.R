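test_that("the shipped example document reads with its annotations intact", {
  path <- system.file("extdata", "example-document.json", package = "narratime")
  doc <- read_document(path)
  expect_length(doc$events, 3)
  expect_length(doc$assertions, 1)
  expect_identical(doc$assertions[[1]]$relation, "EQUAL")
  expect_true(doc$assertions[[1]]$asserted)
  expect_equal(doc$timestamps[["EVENTID-1"]]$start, timestamp(2006, 5, 1))
})

test_that("write/read round-trips and writes are byte-stable", {
  doc <- fig4_doc()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_document(doc, p1)
  back <- read_document(p1)
  write_document(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(back$timestamps, doc$timestamps)
  expect_equal(back$assertions, doc$assertions)
  # inferred (asserted = FALSE) assertions survive the round trip
  doc$assertions <- c(doc$assertions,
                      list(assertion("EVENTID-1", "BEFORE", "EVENTID-2",
                                     asserted = FALSE)))
  write_document(doc, p1)
  back <- read_document(p1)
  flags <- vapply(back$assertions, `[[`, logical(1), "asserted")
  expect_equal(sort(flags), c(FALSE, TRUE))
  # deterministic bytes across two writes of the same document
  write_document(doc, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("schema violations are rejected with named errors", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"doc_id": "X", "assertions": []}', p)
  expect_error(read_document(p), "events", class = "narratime_schema_error")
  writeLines('{"doc_id": "X", "events": [{"id": "a"}], "assertions":
    [{"subject": "a", "relation": "BEFORE", "object": {"event": "ghost"}}]}', p)
  expect_error(read_document(p), "ghost", class = "narratime_schema_error")
  writeLines('{"doc_id": "X", "events": [{"id": "a"}], "assertions": [],
    "durations": {"a": "shortly"}}', p)
  expect_error(read_document(p), "shortly", class = "narratime_schema_error")
  expect_error(
    annotated_document("X", events = list(event("a"), event("a"))),
    "duplicate", class = "narratime_schema_error")
  expect_error(assertion("a", "BEFORE", "a"), class = "narratime_invalid_assertion")
  expect_error(assertion("a", "EQUAL", "b", offset = duration(1, "day")),
               class = "narratime_invalid_assertion")
})

test_that("turtle export has one triple per assertion plus fixed overhead", {
  doc <- fig4_doc()
  p <- withr::local_tempfile(fileext = ".ttl")
  export_turtle(doc, p)
  lines <- readLines(p)
  triples <- lines[grepl("[.]$", lines) & !startsWith(lines, "@prefix")]
  n_stamps <- sum(lengths(doc$timestamps))
  expect_length(triples,
                3 * length(doc$events) + length(doc$assertions) +
                  n_stamps + length(doc$durations))
  expect_true(any(grepl("ev:EVENTID_3 cntro:equal ev:EVENTID_1", triples)))
  expect_true(any(grepl('"2006-05-01"\\^\\^xsd:date', triples)))
  # empty document exports a valid empty graph (prefixes only)
  empty <- annotated_document("EMPTY", events = list())
  export_turtle(empty, p)
  lines <- readLines(p)
  expect_true(all(startsWith(lines[nzchar(lines)], "@prefix")))
  # month-granularity stamps become gYearMonth literals
  export_turtle(therapy_may_july_doc(), p)
  expect_true(any(grepl('"2006-05"\\^\\^xsd:gYearMonth', readLines(p))))
})

test_that("relation matrix tags asserted vs inferred and is skew-consistent", {
  doc <- fig4_doc()
  res <- reason_document(doc, axioms = study_axioms())
  rm <- relation_matrix(doc, res$inferred)
  m <- rm$matrix
  expect_equal(dim(m), c(3, 3))
  expect_identical(m["EVENTID-3", "EVENTID-1"], "EQUAL")       # asserted
  expect_identical(m["EVENTID-1", "EVENTID-2"], "BEFORE*")     # inferred
  expect_identical(m["EVENTID-2", "EVENTID-1"], "AFTER*")
  offdiag <- m[row(m) != col(m)]
  expect_gte(sum(endsWith(offdiag, "*")), 2)
  expect_equal(sum(!endsWith(offdiag, "*") & offdiag != "unknown"), 1)
  # skew consistency after stripping tags
  plain <- sub("[*]$", "", m)
  inv <- c(BEFORE = "AFTER", AFTER = "BEFORE", EQUAL = "EQUAL",
           STARTS = "STARTS", FINISHES = "FINISHES",
           CONTAINS = "DURING", DURING = "CONTAINS")
  for (i in rownames(m)) {
    for (j in colnames(m)) {
      if (i == j || plain[i, j] %in% c("unknown", "-")) next
      expect_identical(plain[j, i], unname(inv[plain[i, j]]))
    }
  }
  # single event: 1x1 with empty diagonal
  one <- annotated_document("ONE", events = list(event("a")))
  m1 <- relation_matrix(one)$matrix
  expect_equal(dim(m1), c(1, 1))
  expect_identical(m1[1, 1], "-")
  # TSV serialization
  p <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(rm, p)
  tab <- utils::read.delim(p, row.names = 1, check.names = FALSE)
  expect_equal(unname(as.matrix(tab)), unname(m))
})

test_that("gold standards round-trip through JSON", {
  gold <- gold_standard(
    "G1", ordered_events = list(c("a", "b"), "c"),
    event_durations = list(b = duration(2, "month")),
    pair_durations = list(list(a = "a", b = "c", duration = duration(14, "month")))
  )
  p <- withr::local_tempfile(fileext = ".json")
  write_gold(gold, p)
  back <- read_gold(p)
  expect_equal(back$ordered_events, gold$ordered_events)
  expect_equal(back$event_durations, gold$event_durations)
  expect_equal(back$pair_durations, gold$pair_durations)
  expect_error(gold_standard("G", list(c("a"), c("a"))),
               class = "narratime_schema_error")
})
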