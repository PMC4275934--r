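# JSON annotation interchange, RDF/Turtle export, and the relation matrix.
# JSON (not OWL) is the primary format: schema-checkable and reasoner-free.
# The published contract is inst/extdata/annotation-schema.json.

normalize_ts_field <- function(x, field, dialect = "us") {
  if (is_timestamp(x)) return(x)
  r <- normalize_time_expression(as.character(x), dialect = dialect)
  if (r$kind != "timestamp") {
    stop_narratime("schema_error",
                   sprintf("field '%s': cannot normalize '%s' (%s)", field, x, r$note))
  }
  r$value
}

normalize_dur_field <- function(x, field) {
  if (is_duration(x)) return(x)
  r <- normalize_duration_expression(as.character(x))
  if (r$kind != "duration") {
    stop_narratime("schema_error",
                   sprintf("field '%s': cannot normalize '%s' (%s)", field, x, r$note))
  }
  r$value
}

sort_named <- function(x) {
  if (!length(x)) return(structure(list(), names = character(0)))
  x[order(names(x))]
}

require_key <- function(x, key, where) {
  if (is.null(x[[key]])) {
    stop_narratime("schema_error", sprintf("missing '%s' key in %s", key, where))
  }
  x[[key]]
}

#' Read an annotated document from JSON
#'
#' Parses and validates a JSON annotation file (see the schema shipped at
#' `system.file("extdata", "annotation-schema.json", package = "narratime")`).
#' Temporal-expression strings in `timestamps`, `durations` and assertion
#' `offset`/timestamp-object fields are passed through the rule-based
#' normalizer.
#'
#' @param path Path to a JSON document.
#' @param dialect Slash-date dialect for the normalizer.
#' @return An `annotated_document`.
#' @export
read_document <- function(path, dialect = "us") {
  if (!file.exists(path)) {
    stop_narratime("io_error", sprintf("no such file: %s", path))
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc_from_list(raw, dialect = dialect)
}

doc_from_list <- function(raw, dialect = "us") {
  doc_id <- require_key(raw, "doc_id", "document")
  ev_raw <- require_key(raw, "events", "document")
  as_raw <- require_key(raw, "assertions", "document")
  events <- lapply(ev_raw, function(e) {
    event(require_key(e, "id", "event"),
          event_type = if (is.null(e$event_type)) "other" else e$event_type,
          label = if (is.null(e$label)) e$id else e$label,
          span = if (is.null(e$span)) NULL else unlist(e$span))
  })
  assertions <- lapply(as_raw, function(a) {
    obj <- require_key(a, "object", "assertion")
    obj <- if (!is.null(obj$event)) {
      obj$event
    } else if (!is.null(obj$time)) {
      normalize_ts_field(obj$time, "assertions.object.time", dialect)
    } else {
      stop_narratime("schema_error",
                     "assertion object must have an 'event' or 'time' key")
    }
    assertion(require_key(a, "subject", "assertion"),
              require_key(a, "relation", "assertion"),
              obj,
              offset = if (is.null(a$offset)) NULL else
                normalize_dur_field(a$offset, "assertions.offset"),
              relation_granularity = a$relation_granularity,
              asserted = if (is.null(a$asserted)) TRUE else isTRUE(a$asserted))
  })
  timestamps <- lapply(raw$timestamps, function(t) {
    out <- list()
    if (!is.null(t$start)) out$start <- normalize_ts_field(t$start, "timestamps.start", dialect)
    if (!is.null(t$end)) out$end <- normalize_ts_field(t$end, "timestamps.end", dialect)
    out
  })
  durations <- lapply(raw$durations, normalize_dur_field, field = "durations")
  annotated_document(
    doc_id = doc_id, events = events, assertions = assertions,
    timestamps = timestamps, durations = durations,
    narrative_text = raw$narrative_text,
    metadata = if (is.null(raw$metadata)) list() else raw$metadata
  )
}

doc_to_list <- function(doc) {
  ids <- event_ids(doc)
  ev <- lapply(doc$events[order(ids)], function(e) {
    out <- list(id = e$id, event_type = e$event_type, label = e$label)
    if (!is.null(e$span)) out$span <- e$span
    out
  })
  as_key <- vapply(doc$assertions, function(a) {
    paste(a$subject, a$relation,
          if (is_timestamp(a$object)) format(a$object) else a$object)
  }, character(1))
  asrt <- lapply(doc$assertions[order(as_key)], function(a) {
    out <- list(subject = a$subject, relation = a$relation,
                object = if (is_timestamp(a$object)) list(time = format(a$object))
                         else list(event = a$object))
    if (!is.null(a$offset)) out$offset <- format(a$offset)
    if (!is.null(a$relation_granularity)) out$relation_granularity <- a$relation_granularity
    out$asserted <- a$asserted
    out
  })
  stamps <- lapply(sort_named(doc$timestamps), function(t) lapply(t, format))
  durs <- lapply(sort_named(doc$durations), format)
  out <- list(doc_id = doc$doc_id)
  if (!is.null(doc$narrative_text)) out$narrative_text <- doc$narrative_text
  out$events <- ev
  out$assertions <- asrt
  out$timestamps <- stamps
  out$durations <- durs
  if (length(doc$metadata)) out$metadata <- sort_named(doc$metadata)
  out
}

write_canonical_json <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = 2, null = "null",
                          digits = NA)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Write an annotated document as canonical JSON
#'
#' Output is canonical (events sorted by id, assertions by subject/
#' relation/object, sorted map keys), so writing the same document twice
#' is byte-identical and `read_document(write_document(doc))` round-trips.
#'
#' @param doc An `annotated_document`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_document <- function(doc, path) {
  validate_document(doc)
  write_canonical_json(doc_to_list(doc), path)
}

#' Read a gold standard timeline from JSON
#' @param path Path to a gold JSON file.
#' @return A `gold_standard`.
#' @export
read_gold <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  gold_standard(
    doc_id = require_key(raw, "doc_id", "gold standard"),
    ordered_events = lapply(require_key(raw, "ordered_events", "gold standard"),
                            function(b) unlist(b)),
    event_durations = lapply(raw$event_durations, normalize_dur_field,
                             field = "event_durations"),
    pair_durations = lapply(raw$pair_durations, function(p) {
      list(a = p$a, b = p$b,
           duration = normalize_dur_field(p$duration, "pair_durations"))
    })
  )
}

#' Write a gold standard timeline as canonical JSON
#' @param gold A `gold_standard`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gold <- function(gold, path) {
  out <- list(
    doc_id = gold$doc_id,
    ordered_events = lapply(gold$ordered_events, function(b) as.list(sort(b))),
    event_durations = lapply(sort_named(gold$event_durations), format),
    pair_durations = lapply(gold$pair_durations, function(p) {
      list(a = p$a, b = p$b, duration = format(p$duration))
    })
  )
  write_canonical_json(out, path)
}

# ---------------------------------------------------------------------------
# RDF/Turtle export

TURTLE_PREFIX <- "http://example.org/cntro#"

turtle_escape_id <- function(id) gsub("[^A-Za-z0-9_]", "_", id)

turtle_literal <- function(ts) {
  xsd <- switch(ts$granularity,
    year = "xsd:gYear", month = "xsd:gYearMonth", day = "xsd:date",
    hour = "xsd:dateTime", minute = "xsd:dateTime")
  lex <- format(ts)
  if (ts$granularity == "hour") lex <- paste0(lex, ":00:00")
  if (ts$granularity == "minute") lex <- paste0(lex, ":00")
  sprintf("\"%s\"^^%s", lex, xsd)
}

#' Export an annotated document as RDF/Turtle
#'
#' One subject-predicate-object triple per assertion under the fixed
#' `cntro:` namespace, plus per-event type/eventType/label triples and one
#' triple per timestamp and per explicit duration. Timestamps are written
#' as xsd dateTime-family literals truncated to their granularity.
#' BEFORE/AFTER offsets and relation granularities are not serialized
#' (JSON is the lossless interchange format).
#'
#' Triple count = 2 * n_events + n_labels + n_assertions + n_timestamps +
#' n_durations, where n_timestamps counts start and end stamps separately.
#'
#' @param doc An `annotated_document`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_turtle <- function(doc, path) {
  validate_document(doc)
  lines <- c(
    sprintf("@prefix cntro: <%s> .", TURTLE_PREFIX),
    sprintf("@prefix ev: <http://example.org/cntro/doc/%s#> .",
            turtle_escape_id(doc$doc_id)),
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    ""
  )
  for (e in doc$events) {
    s <- paste0("ev:", turtle_escape_id(e$id))
    lines <- c(lines,
      sprintf("%s a cntro:Event .", s),
      sprintf("%s cntro:eventType \"%s\" .", s, e$event_type),
      if (!is.null(e$label)) sprintf("%s rdfs:label \"%s\" .", s,
                                     gsub("\"", "\\\\\"", e$label)))
  }
  anon <- 0L
  for (a in doc$assertions) {
    s <- paste0("ev:", turtle_escape_id(a$subject))
    p <- paste0("cntro:", tolower(a$relation))
    o <- if (is_timestamp(a$object)) turtle_literal(a$object)
         else paste0("ev:", turtle_escape_id(a$object))
    lines <- c(lines, sprintf("%s %s %s .", s, p, o))
  }
  for (id in names(doc$timestamps)) {
    s <- paste0("ev:", turtle_escape_id(id))
    t <- doc$timestamps[[id]]
    if (!is.null(t$start)) {
      lines <- c(lines, sprintf("%s cntro:startTime %s .", s, turtle_literal(t$start)))
    }
    if (!is.null(t$end)) {
      lines <- c(lines, sprintf("%s cntro:endTime %s .", s, turtle_literal(t$end)))
    }
  }
  for (id in names(doc$durations)) {
    lines <- c(lines, sprintf("ev:%s cntro:duration \"%s\" .",
                              turtle_escape_id(id), format(doc$durations[[id]])))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Relation matrix (asserted vs inferred), serializable as TSV

#' Build the event-by-event relation matrix
#'
#' A square table with one row and column per event. Cells carry the
#' relation label between the row event (subject) and column event
#' (object); inferred relations are tagged with a trailing `*`, asserted
#' ones are untagged, undecided pairs read `"unknown"` and the diagonal is
#' `"-"`. The matrix of a closed graph is skew-consistent: cell (i, j) =
#' BEFORE iff cell (j, i) = AFTER.
#'
#' @param doc An `annotated_document`.
#' @param inferred List of inferred assertions (from [infer_relations()]).
#' @return An object of class `relation_matrix` wrapping a character
#'   matrix.
#' @export
relation_matrix <- function(doc, inferred = list()) {
  ids <- event_ids(doc)
  n <- length(ids)
  m <- matrix("unknown", n, n, dimnames = list(ids, ids))
  diag(m) <- "-"
  fill <- function(a, tag) {
    if (!is.character(a$object)) return()
    if (!a$subject %in% ids || !a$object %in% ids) {
      stop_narratime("schema_error",
                     sprintf("assertion references unknown event: %s/%s",
                             a$subject, a$object))
    }
    cell <- paste0(a$relation, tag)
    if (m[a$subject, a$object] == "unknown") m[a$subject, a$object] <<- cell
  }
  for (a in inferred) fill(a, "*")
  for (a in doc$assertions) {
    if (!is.character(a$object)) next
    m[a$subject, a$object] <- a$relation  # asserted overrides inferred tag
  }
  structure(list(events = ids, matrix = m), class = "relation_matrix")
}

#' Write a relation matrix as TSV
#' @param rm A `relation_matrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(rm, path) {
  stopifnot(inherits(rm, "relation_matrix"))
  utils::write.table(rm$matrix, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @export
print.relation_matrix <- function(x, ...) {
  cat(sprintf("<relation matrix, %d events; '*' = inferred>\n", length(x$events)))
  print(x$matrix, quote = FALSE)
  invisible(x)
}
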