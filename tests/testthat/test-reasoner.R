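test_that("assertions compile to the expected point constraints", {
  doc <- offset60_doc()
  g <- build_graph(doc)
  # offset BEFORE becomes an exact equality edge end(a) -> start(b)
  off <- Filter(function(e) !is.null(e$offset), g$edges)
  expect_length(off, 1)
  expect_identical(off[[1]]$from, "implant.end")
  expect_identical(off[[1]]$to, "disc.start")
  expect_equal(off[[1]]$offset, duration(60, "day"))
  # EQUAL contributes two equality edges
  g <- build_graph(fig4_doc())
  eq <- Filter(function(e) e$type == "eq" && grepl("assertion", e$source), g$edges)
  expect_length(eq, 2)
  # death_last injects one inequality per non-death event
  doc <- annotated_document("D", events = list(
    event("a", "stent_implantation"), event("b", "late_stent_thrombosis"),
    event("d", "death")))
  g <- build_graph(doc, axioms = axiom_set(death_last = TRUE))
  inj <- Filter(function(e) identical(e$source, "axiom:death_last"), g$edges)
  expect_length(inj, 2)
  expect_setequal(vapply(inj, `[[`, character(1), "to"),
                  rep("d.start", 2))
  expect_error(
    build_graph(annotated_document("X", events = list(event("a")))),
    NA)
})

test_that("transitivity, substitution and inversion close the graph", {
  doc <- annotated_document("T", events = list(event("A"), event("B"), event("C")),
                            assertions = list(assertion("A", "BEFORE", "B"),
                                              assertion("B", "BEFORE", "C")))
  inferred <- infer_relations(build_graph(doc))
  keys <- relation_keys(inferred)
  expect_true("A BEFORE C" %in% keys)
  expect_true("C AFTER A" %in% keys)
  # equality substitutes into order: A < B, B = C implies A < C
  doc <- annotated_document("S", events = list(event("A"), event("B"), event("C")),
                            assertions = list(assertion("A", "BEFORE", "B"),
                                              assertion("B", "EQUAL", "C")))
  keys <- relation_keys(infer_relations(build_graph(doc)))
  expect_true("A BEFORE C" %in% keys)
})

test_that("the three-event fixture decides all pairwise relations", {
  res <- reason_document(fig4_doc(), axioms = study_axioms())
  keys <- relation_keys(res$inferred)
  expect_true(all(c("EVENTID-1 BEFORE EVENTID-2",
                    "EVENTID-3 BEFORE EVENTID-2",
                    "EVENTID-1 EQUAL EVENTID-3") %in% keys))
  # the asserted EQUAL's timestamp was copied
  expect_equal(res$graph$stamps[["EVENTID-3.start"]], timestamp(2006, 5, 1))
})

test_that("closure matches the brute-force reachability oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:200) {
    rd <- random_relation_doc(seed)
    got <- relation_keys(infer_relations(build_graph(rd$doc)))
    want <- oracle_relations(rd$doc)
    expect_identical(got, want, label = sprintf("seed %d", seed))
  }
})

test_that("closure is idempotent and monotone under new assertions", {
  for (seed in c(3, 17, 101)) {
    rd <- random_relation_doc(seed)
    g <- build_graph(rd$doc)
    first <- relation_keys(infer_relations(g))
    expect_identical(relation_keys(infer_relations(g)), first)
    # asserting one of the latent truths never removes an inferred relation
    lat <- rd$latent
    ids <- names(lat$start)
    new <- NULL
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i != j && lat$end[i] < lat$start[j] &&
            !paste(ids[i], "BEFORE", ids[j]) %in%
              relation_keys(rd$doc$assertions)) {
          new <- assertion(ids[i], "BEFORE", ids[j])
          break
        }
      }
      if (!is.null(new)) break
    }
    if (is.null(new)) next
    doc2 <- rd$doc
    doc2$assertions <- c(doc2$assertions, list(new))
    second <- relation_keys(infer_relations(build_graph(doc2)))
    added_key <- paste(new$subject, "BEFORE", new$object)
    expect_true(all(setdiff(first, added_key) %in% second))
  }
})

test_that("timestamp propagation fills points and reports conflicts", {
  g <- propagate_timestamps(build_graph(fig4_doc(), axioms = study_axioms()))
  expect_equal(g$stamps[["EVENTID-3.start"]], timestamp(2006, 5, 1))
  expect_equal(g$stamps[["EVENTID-3.end"]], timestamp(2006, 5, 1))
  # offset edge computes across the calendar (oracle: base-R Dates)
  doc <- annotated_document("P", events = list(event("A"), event("B")),
    assertions = list(assertion("A", "BEFORE", "B", offset = duration(60, "day"))),
    timestamps = list(A = list(end = timestamp(2006, 5, 1))))
  g <- propagate_timestamps(build_graph(doc))
  expect_equal(format(g$stamps[["B.start"]]), format(as.Date("2006-05-01") + 60))
  # no timestamps: propagation is a no-op
  g0 <- build_graph(offset60_doc())
  expect_equal(propagate_timestamps(g0)$stamps, g0$stamps)
  # disagreeing derivations at a common granularity are an error
  doc <- annotated_document("C", events = list(event("A"), event("B")),
    assertions = list(assertion("A", "EQUAL", "B")),
    timestamps = list(A = list(start = timestamp(2006, 5, 1)),
                      B = list(start = timestamp(2006, 5, 2))))
  expect_error(propagate_timestamps(build_graph(doc)),
               class = "narratime_timestamp_conflict")
  # but a coarser stamp agreeing at its own granularity is no conflict
  doc$timestamps$B <- list(start = timestamp(2006, 5))
  expect_no_error(propagate_timestamps(build_graph(doc)))
})

test_that("event durations resolve by annotation, stamps, then chaining", {
  # (1) explicit annotation
  doc <- annotated_document("E1", events = list(event("therapy", "antiplatelet_therapy")),
                            durations = list(therapy = duration(2, "month")))
  expect_equal(event_duration(build_graph(doc), "therapy", "month"),
               duration(2, "month"))
  # (2) start/end stamps with granularity truncation: the day-before-surgery
  # offset vanishes at month level
  g <- build_graph(therapy_may_july_doc())
  expect_equal(event_duration(g, "therapy", "month"), duration(2, "month"))
  # (3) chaining through a related event
  doc <- annotated_document("E3",
    events = list(event("therapy", "antiplatelet_therapy"),
                  event("implant", "stent_implantation"),
                  event("lst", "late_stent_thrombosis")),
    assertions = list(assertion("therapy", "STARTS", "implant"),
                      assertion("implant", "BEFORE", "lst", offset = duration(8, "month")),
                      assertion("therapy", "FINISHES", "lst")))
  expect_equal(event_duration(build_graph(doc, axioms = study_axioms()),
                              "therapy", "month"),
               duration(8, "month"))
  # instantaneous events have zero duration
  doc <- annotated_document("E0", events = list(event("implant", "stent_implantation")))
  expect_equal(event_duration(build_graph(doc, axioms = study_axioms()),
                              "implant", "month"),
               duration(0, "month"))
  # no evidence / range-only evidence
  doc <- annotated_document("EX", events = list(event("x")))
  expect_error(event_duration(build_graph(doc), "x", "month"),
               class = "narratime_insufficient_information")
  doc <- annotated_document("ER", events = list(event("x")),
                            durations = list(x = duration(2, "month", range_high = 3)))
  expect_error(event_duration(build_graph(doc), "x", "month"),
               class = "narratime_insufficient_precision")
})

test_that("durations between events chain through intermediate events", {
  g <- build_graph(offset60_doc())
  expect_equal(duration_between(g, "implant", "disc", "day"), duration(60, "day"))
  expect_equal(duration_between(g, "disc", "implant", "day"), duration(60, "day"))
  expect_equal(duration_between(g, "implant", "implant", "day"), duration(0, "day"))
  expect_equal(duration_between(g, "implant", "disc", "month"), duration(2, "month"))
  # A -(1 month)-> B -(2 months)-> C
  doc <- annotated_document("CH", events = list(event("A"), event("B"), event("C")),
    assertions = list(
      assertion("A", "BEFORE", "B", offset = duration(1, "month")),
      assertion("B", "BEFORE", "C", offset = duration(2, "month"))))
  expect_equal(duration_between(build_graph(doc), "A", "C", "month"),
               duration(3, "month"))
  # granular relation contributes zero at its granularity
  g <- build_graph(granular183_doc())
  expect_equal(duration_between(g, "event1", "event3", "day"), duration(183, "day"))
  # with granular relations off the chain is unresolvable
  g_off <- build_graph(granular183_doc(),
                       config = reasoner_config(granular_relations = FALSE))
  expect_error(duration_between(g_off, "event1", "event3", "day"),
               class = "narratime_insufficient_information")
  # and the zero-at-day contribution cannot answer at finer granularity
  expect_error(duration_between(g, "event1", "event3", "minute"),
               class = "narratime_insufficient_precision")
  # unrelated events are unresolvable
  doc <- annotated_document("U", events = list(event("A"), event("B")))
  expect_error(duration_between(build_graph(doc), "A", "B", "day"),
               class = "narratime_insufficient_information")
})

test_that("chained offsets agree with the latent-distance oracle", {
  for (seed in 1:120) {
    rd <- random_offset_doc(seed)
    g <- build_graph(rd$doc)
    ids <- names(rd$pos)
    pick <- sample(ids, 2)
    got <- duration_between(g, pick[1], pick[2], "day")
    expect_equal(got, duration(abs(rd$pos[[pick[1]]] - rd$pos[[pick[2]]]), "day"),
                 label = sprintf("seed %d (%s, %s)", seed, pick[1], pick[2]))
  }
})

test_that("inconsistencies are detected and reported with a cycle", {
  doc <- annotated_document("CY", events = list(event("A"), event("B")),
                            assertions = list(assertion("A", "BEFORE", "B"),
                                              assertion("B", "BEFORE", "A")))
  rep_ <- check_consistency(build_graph(doc))
  expect_false(rep_$consistent)
  expect_length(rep_$cycles, 1)
  expect_identical(rep_$cycles[[1]][1], rep_$cycles[[1]][length(rep_$cycles[[1]])])
  expect_error(infer_relations(build_graph(doc)),
               class = "narratime_inconsistent_graph")
  # cycle through an equality chain: A < B, B = C, C < A
  doc <- annotated_document("CY2", events = list(event("A"), event("B"), event("C")),
                            assertions = list(assertion("A", "BEFORE", "B"),
                                              assertion("B", "EQUAL", "C"),
                                              assertion("C", "BEFORE", "A")))
  expect_false(check_consistency(build_graph(doc))$consistent)
  # consistent fixture: empty report
  rep_ <- check_consistency(build_graph(fig4_doc()))
  expect_true(rep_$consistent)
  expect_length(rep_$cycles, 0)
  expect_length(rep_$conflicts, 0)
})

test_that("config files round-trip reasoner options", {
  p <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# reasoner options", "granular_relations = off",
               "default_unit = day", "dialect = intl",
               "death_last = on", "instantaneous = death,er_admission"), p)
  cfg <- read_config(p)
  expect_false(cfg$config$granular_relations)
  expect_identical(cfg$config$default_unit, "day")
  expect_identical(cfg$config$dialect, "intl")
  expect_true(cfg$axioms$death_last)
  expect_setequal(cfg$axioms$instantaneous_event_types, c("death", "er_admission"))
})
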