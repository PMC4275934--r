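#' Event type vocabulary
#'
#' The closed vocabulary of clinical events annotated in late-stent-
#' thrombosis adverse-event narratives, plus `other` for anything outside
#' it: initial and follow-up stent implantation, start/stop of antiplatelet
#' therapy (and the therapy interval itself), unrelated surgery, late stent
#' thrombosis, myocardial infarction, emergency-room admission, and death.
#'
#' @format Character vector.
#' @export
EVENT_TYPES <- c(
  "stent_implantation", "followup_stent_implantation",
  "antiplatelet_start", "antiplatelet_stop", "antiplatelet_therapy",
  "unrelated_surgery", "late_stent_thrombosis", "myocardial_infarction",
  "er_admission", "death", "other"
)

#' Temporal relation vocabulary
#'
#' BEFORE/AFTER/EQUAL/STARTS/FINISHES are the relations evidenced in the
#' annotation scheme; CONTAINS/DURING are accepted as an extension for
#' interval containment. STARTS and FINISHES are interpreted as
#' start-point (end-point) coincidence and are therefore symmetric.
#'
#' @format Character vector.
#' @export
RELATIONS <- c("BEFORE", "AFTER", "EQUAL", "STARTS", "FINISHES",
               "CONTAINS", "DURING")

RELATION_INVERSE <- c(
  BEFORE = "AFTER", AFTER = "BEFORE", EQUAL = "EQUAL",
  STARTS = "STARTS", FINISHES = "FINISHES",
  CONTAINS = "DURING", DURING = "CONTAINS"
)

#' Create an annotated event
#'
#' @param id Unique event identifier within its document.
#' @param event_type One of [EVENT_TYPES].
#' @param label Free-text label; defaults to the id.
#' @param span Optional integer pair: 0-based half-open character interval
#'   over the narrative text.
#' @return An object of class `cntro_event`.
#' @export
event <- function(id, event_type = "other", label = id, span = NULL) {
  if (length(id) != 1L || !nzchar(id)) {
    stop_narratime("invalid_event", "event id must be a non-empty string")
  }
  if (!event_type %in% EVENT_TYPES) {
    stop_narratime("invalid_event",
                   sprintf("event_type '%s' not in vocabulary", event_type))
  }
  if (!is.null(span)) {
    span <- as.integer(span)
    if (length(span) != 2L || any(is.na(span)) || span[1] < 0L || span[2] < span[1]) {
      stop_narratime("invalid_event", "span must be a 0-based half-open [start, end) pair")
    }
  }
  structure(list(id = id, event_type = event_type, label = label, span = span),
            class = "cntro_event")
}

#' Create a temporal assertion
#'
#' Connects two events (or an event and a timestamp): they occurred or
#' began at the same time, or one occurred before/after the other. A
#' quantified temporal offset ("60 days after") may accompany BEFORE and
#' AFTER only. A `relation_granularity` on BEFORE/AFTER records that the
#' comparison was made at that granularity, implying the two events are
#' simultaneous at it (e.g. "before, at day granularity" = same day).
#'
#' @param subject Event id.
#' @param relation One of [RELATIONS].
#' @param object Event id or a `cntro_timestamp`.
#' @param offset Optional `cntro_duration` (BEFORE/AFTER only).
#' @param relation_granularity Optional granularity string.
#' @param asserted `TRUE` for annotated relations, `FALSE` for inferred.
#' @return An object of class `cntro_assertion`.
#' @export
assertion <- function(subject, relation, object, offset = NULL,
                      relation_granularity = NULL, asserted = TRUE) {
  relation <- toupper(relation)
  if (!relation %in% RELATIONS) {
    stop_narratime("invalid_assertion",
                   sprintf("relation '%s' not in vocabulary", relation))
  }
  if (!is.null(offset)) {
    if (!is_duration(offset)) {
      stop_narratime("invalid_assertion", "offset must be a duration")
    }
    if (!relation %in% c("BEFORE", "AFTER")) {
      stop_narratime("invalid_assertion", "offset only permitted with BEFORE/AFTER")
    }
  }
  if (!is.null(relation_granularity)) {
    relation_granularity <- as_granularity(relation_granularity)
  }
  if (is.character(object) && identical(subject, object)) {
    stop_narratime("invalid_assertion", "subject and object must differ")
  }
  if (!is.character(object) && !is_timestamp(object)) {
    stop_narratime("invalid_assertion", "object must be an event id or a timestamp")
  }
  structure(
    list(subject = subject, relation = relation, object = object,
         offset = offset, relation_granularity = relation_granularity,
         asserted = isTRUE(asserted)),
    class = "cntro_assertion"
  )
}

#' @export
format.cntro_assertion <- function(x, ...) {
  obj <- if (is_timestamp(x$object)) format(x$object) else x$object
  extras <- c(
    if (!is.null(x$offset)) sprintf("offset %s", format(x$offset)),
    if (!is.null(x$relation_granularity)) sprintf("@%s", x$relation_granularity),
    if (!x$asserted) "inferred"
  )
  sprintf("%s %s %s%s", x$subject, x$relation, obj,
          if (length(extras)) paste0(" [", paste(extras, collapse = ", "), "]") else "")
}

#' @export
print.cntro_assertion <- function(x, ...) {
  cat("<assertion ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Assemble an annotated narrative document
#'
#' The unit of reasoning: one narrative's events, temporal assertions,
#' event timestamps (start and optionally end), explicit event durations,
#' and free-form metadata.
#'
#' @param doc_id Document identifier.
#' @param events List of [event()] objects.
#' @param assertions List of [assertion()] objects.
#' @param timestamps Named list (by event id) of `list(start =, end =)`
#'   with `cntro_timestamp` entries (either may be absent).
#' @param durations Named list (by event id) of `cntro_duration` objects.
#' @param narrative_text Optional raw narrative text.
#' @param metadata Free-form named list.
#' @return An object of class `annotated_document`.
#' @export
annotated_document <- function(doc_id, events, assertions = list(),
                               timestamps = list(), durations = list(),
                               narrative_text = NULL, metadata = list()) {
  doc <- structure(
    list(doc_id = doc_id, narrative_text = narrative_text,
         events = events, assertions = assertions,
         timestamps = timestamps, durations = durations,
         metadata = metadata),
    class = "annotated_document"
  )
  validate_document(doc)
  doc
}

#' Validate an annotated document
#'
#' Checks id uniqueness, vocabulary membership, and referential integrity:
#' every assertion subject/object and every timestamp/duration key must
#' name an existing event.
#'
#' @param doc An `annotated_document`.
#' @return The document, invisibly; errors name the offending field.
#' @export
validate_document <- function(doc) {
  if (!inherits(doc, "annotated_document")) {
    stop_narratime("schema_error", "not an annotated_document")
  }
  if (length(doc$doc_id) != 1L || !nzchar(doc$doc_id)) {
    stop_narratime("schema_error", "field 'doc_id' must be a non-empty string")
  }
  ids <- vapply(doc$events, function(e) e$id, character(1))
  if (anyDuplicated(ids)) {
    stop_narratime("schema_error",
                   sprintf("duplicate event ids: %s",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  dangling <- character(0)
  for (a in doc$assertions) {
    if (!a$subject %in% ids) dangling <- c(dangling, a$subject)
    if (is.character(a$object) && !a$object %in% ids) dangling <- c(dangling, a$object)
  }
  dangling <- c(dangling,
                setdiff(names(doc$timestamps), ids),
                setdiff(names(doc$durations), ids))
  if (length(dangling)) {
    stop_narratime("schema_error",
                   sprintf("dangling event references: %s",
                           paste(unique(dangling), collapse = ", ")))
  }
  invisible(doc)
}

event_ids <- function(doc) vapply(doc$events, function(e) e$id, character(1))

#' @export
print.annotated_document <- function(x, ...) {
  cat(sprintf("<annotated document '%s': %d events, %d assertions, %d timestamped, %d durations>\n",
              x$doc_id, length(x$events), length(x$assertions),
              length(x$timestamps), length(x$durations)))
  invisible(x)
}

#' Assemble a gold standard timeline
#'
#' The manually recorded truth a reasoned document is scored against:
#' events in timeline order (as buckets of simultaneous events, earliest
#' first), known event durations, and known between-event durations.
#'
#' @param doc_id Document identifier.
#' @param ordered_events List of character vectors: timeline buckets,
#'   earliest first. Every event id appears in exactly one bucket.
#' @param event_durations Named list (event id) of `cntro_duration`.
#' @param pair_durations List of `list(a =, b =, duration =)` entries.
#' @return An object of class `gold_standard`.
#' @export
gold_standard <- function(doc_id, ordered_events, event_durations = list(),
                          pair_durations = list()) {
  if (!length(ordered_events) || any(!lengths(ordered_events))) {
    stop_narratime("schema_error", "gold buckets must be non-empty")
  }
  all_ids <- unlist(ordered_events)
  if (anyDuplicated(all_ids)) {
    stop_narratime("schema_error", "event appears in more than one gold bucket")
  }
  structure(
    list(doc_id = doc_id, ordered_events = ordered_events,
         event_durations = event_durations, pair_durations = pair_durations),
    class = "gold_standard"
  )
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold standard '%s': %d buckets, %d event durations, %d pair durations>\n",
              x$doc_id, length(x$ordered_events), length(x$event_durations),
              length(x$pair_durations)))
  invisible(x)
}
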