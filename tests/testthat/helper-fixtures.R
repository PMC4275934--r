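# Fixtures and independent oracles used across the suite.

# Three point events, one asserted EQUAL, two annotated day timestamps:
# the sample evaluation-matrix scenario.
fig4_doc <- function() {
  annotated_document(
    doc_id = "FIG4",
    events = list(
      event("EVENTID-1", "stent_implantation", "initial stent implantation"),
      event("EVENTID-2", "late_stent_thrombosis", "late stent thrombosis"),
      event("EVENTID-3", "antiplatelet_start", "antiplatelet therapy started")
    ),
    assertions = list(assertion("EVENTID-3", "EQUAL", "EVENTID-1")),
    timestamps = list(
      `EVENTID-1` = list(start = timestamp(2006, 5, 1)),
      `EVENTID-2` = list(start = timestamp(2006, 7, 14))
    )
  )
}

# "60 days after stent implantation, antiplatelet therapy was discontinued"
offset60_doc <- function() {
  annotated_document(
    doc_id = "OFFSET60",
    events = list(event("implant", "stent_implantation"),
                  event("disc", "antiplatelet_stop")),
    assertions = list(
      assertion("implant", "BEFORE", "disc", offset = duration(60, "day"))
    )
  )
}

# therapy started May 2006, surgery July 2006, stopped the day before surgery
therapy_may_july_doc <- function() {
  annotated_document(
    doc_id = "MAYJULY",
    events = list(event("therapy", "antiplatelet_therapy"),
                  event("surgery", "unrelated_surgery")),
    assertions = list(
      assertion("therapy", "BEFORE", "surgery", offset = duration(1, "day"))
    ),
    timestamps = list(
      therapy = list(start = timestamp(2006, 5)),
      surgery = list(start = timestamp(2006, 7))
    )
  )
}

# event1 before event2 at day granularity; event3 183 days after event2
granular183_doc <- function() {
  annotated_document(
    doc_id = "GRAN183",
    events = list(event("event1"), event("event2"), event("event3")),
    assertions = list(
      assertion("event1", "BEFORE", "event2", relation_granularity = "day"),
      assertion("event2", "BEFORE", "event3", offset = duration(183, "day"))
    )
  )
}

# --- random relational documents with a latent interval model -------------

# each event gets latent integer endpoints start <= end; sampled assertions
# are true statements about the latent intervals, so the document is
# consistent by construction
random_relation_doc <- function(seed, max_events = 8L) {
  set.seed(seed)
  n <- sample(2:max_events, 1L)
  ids <- sprintf("ev%02d", seq_len(n))
  s <- sample(0:9, n, replace = TRUE)
  e <- s + sample(0:3, n, replace = TRUE)
  asrt <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (stats::runif(1) > 0.5) next
      rel <- if (e[i] < s[j]) "BEFORE"
        else if (e[j] < s[i]) "AFTER"
        else if (s[i] == s[j] && e[i] == e[j]) "EQUAL"
        else if (s[i] == s[j]) "STARTS"
        else if (e[i] == e[j]) "FINISHES"
        else if (s[j] <= s[i] && e[i] <= e[j]) "DURING"
        else if (s[i] <= s[j] && e[j] <= e[i]) "CONTAINS"
        else NA_character_
      if (is.na(rel)) next
      asrt[[length(asrt) + 1L]] <- assertion(ids[i], rel, ids[j])
    }
  }
  list(
    doc = annotated_document(sprintf("RAND-%d", seed),
                             events = lapply(ids, event),
                             assertions = asrt),
    latent = list(start = stats::setNames(s, ids), end = stats::setNames(e, ids))
  )
}

# --- independent endpoint-reachability oracle (igraph) ---------------------

# recompiles the document to point arcs on its own and decides pairwise
# relations by brute-force reachability; shares no code with the package's
# closure
oracle_relations <- function(doc) {
  ids <- vapply(doc$events, function(ev) ev$id, character(1))
  pts <- c(paste0("s.", ids), paste0("e.", ids))
  arcs <- data.frame(from = paste0("s.", ids), to = paste0("e.", ids),
                     strict = FALSE, stringsAsFactors = FALSE)
  add <- function(from, to, strict = FALSE) {
    arcs <<- rbind(arcs, data.frame(from = from, to = to, strict = strict,
                                    stringsAsFactors = FALSE))
  }
  for (a in doc$assertions) {
    sA <- paste0("s.", a$subject); eA <- paste0("e.", a$subject)
    sB <- paste0("s.", a$object); eB <- paste0("e.", a$object)
    switch(a$relation,
      BEFORE = add(eA, sB, TRUE),
      AFTER = add(eB, sA, TRUE),
      EQUAL = { add(sA, sB); add(sB, sA); add(eA, eB); add(eB, eA) },
      STARTS = { add(sA, sB); add(sB, sA) },
      FINISHES = { add(eA, eB); add(eB, eA) },
      DURING = { add(sB, sA); add(eA, eB) },
      CONTAINS = { add(sA, sB); add(eB, eA) }
    )
  }
  g <- igraph::graph_from_data_frame(arcs[, c("from", "to")], vertices = pts)
  D <- igraph::distances(g, mode = "out")
  LE <- is.finite(D[pts, pts])
  LT <- matrix(FALSE, length(pts), length(pts), dimnames = list(pts, pts))
  for (k in which(arcs$strict)) {
    LT <- LT | outer(LE[, arcs$from[k]], LE[arcs$to[k], ], "&")
  }
  EQ <- LE & t(LE)
  out <- character(0)
  emit <- function(a, rel, b) {
    inv <- c(BEFORE = "AFTER", AFTER = "BEFORE", EQUAL = "EQUAL",
             STARTS = "STARTS", FINISHES = "FINISHES",
             DURING = "CONTAINS", CONTAINS = "DURING")
    out <<- c(out, paste(a, rel, b), paste(b, inv[[rel]], a))
  }
  n <- length(ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- ids[i]; b <- ids[j]
      sA <- paste0("s.", a); eA <- paste0("e.", a)
      sB <- paste0("s.", b); eB <- paste0("e.", b)
      if (EQ[sA, sB] && EQ[eA, eB]) {
        emit(a, "EQUAL", b)
      } else if (LT[eA, sB]) {
        emit(a, "BEFORE", b)
      } else if (LT[eB, sA]) {
        emit(b, "BEFORE", a)
      } else {
        if (EQ[sA, sB]) emit(a, "STARTS", b)
        if (EQ[eA, eB]) emit(a, "FINISHES", b)
        if (LE[sB, sA] && LE[eA, eB] && (LT[sB, sA] || LT[eA, eB])) {
          emit(a, "DURING", b)
        } else if (LE[sA, sB] && LE[eB, eA] && (LT[sA, sB] || LT[eB, eA])) {
          emit(b, "DURING", a)
        }
      }
    }
  }
  asserted <- vapply(doc$assertions,
                     function(a) paste(a$subject, a$relation, a$object),
                     character(1))
  sort(setdiff(out, asserted))
}

relation_keys <- function(assertions) {
  sort(vapply(assertions,
              function(a) paste(a$subject, a$relation, a$object), character(1)))
}

# --- random exact-offset documents -----------------------------------------

# instantaneous events on a latent day grid, connected by a random tree of
# exact BEFORE offsets plus optional redundant extra edges
random_offset_doc <- function(seed, max_events = 8L) {
  set.seed(seed)
  n <- sample(3:max_events, 1L)
  ids <- sprintf("ev%02d", seq_len(n))
  pos <- stats::setNames(sort(sample(0:400, n)), ids)
  asrt <- list()
  link <- function(i, j) {
    gap <- pos[[j]] - pos[[i]]
    if (gap >= 0) {
      asrt[[length(asrt) + 1L]] <<-
        if (gap == 0) assertion(ids[i], "EQUAL", ids[j])
        else assertion(ids[i], "BEFORE", ids[j], offset = duration(gap, "day"))
    } else {
      asrt[[length(asrt) + 1L]] <<-
        assertion(ids[i], "AFTER", ids[j], offset = duration(-gap, "day"))
    }
  }
  for (k in 2:n) link(sample(seq_len(k - 1L), 1L), k)  # random spanning tree
  extra <- sample(0:2, 1L)
  for (k in seq_len(extra)) {
    ij <- sample(n, 2L)
    link(ij[1], ij[2])
  }
  list(doc = annotated_document(sprintf("OFF-%d", seed),
                                events = lapply(ids, event),
                                assertions = asrt),
       pos = pos)
}
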