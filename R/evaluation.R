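# Scoring reasoned timelines and durations against gold standards, and
# corpus-level aggregation of the three accuracy measures: event ordering,
# single-event durations, and between-event durations.

#' Score a predicted timeline against a gold ordering
#'
#' `strict` requires the bucket sequences to be identical (same partition
#' into simultaneity classes, same order) — the document counts as
#' correctly ordered only then. `pairwise` is a diagnostic: the fraction
#' of event pairs whose relative order (before/equal/after) matches the
#' gold standard; pairs the prediction leaves incomparable count as
#' mismatches.
#'
#' @param predicted A `timeline` (or a plain list of bucket id vectors).
#' @param gold A `gold_standard`.
#' @return List with `strict` (logical) and `pairwise` (fraction).
#' @export
score_ordering <- function(predicted, gold) {
  pred_buckets <- if (inherits(predicted, "timeline")) {
    timeline_buckets(predicted)
  } else {
    predicted
  }
  total <- !inherits(predicted, "timeline") || predicted$total_order
  gold_buckets <- gold$ordered_events
  pred_ids <- sort(unlist(pred_buckets))
  gold_ids <- sort(unlist(gold_buckets))
  if (!identical(pred_ids, gold_ids)) {
    stop_narratime("id_mismatch",
                   "predicted and gold timelines cover different event sets")
  }
  bucket_index <- function(buckets) {
    idx <- integer(0)
    for (i in seq_along(buckets)) {
      idx[buckets[[i]]] <- i
    }
    idx
  }
  pi <- bucket_index(pred_buckets)
  gi <- bucket_index(gold_buckets)
  strict <- total && length(pred_buckets) == length(gold_buckets) &&
    all(vapply(seq_along(pred_buckets),
               function(i) setequal(pred_buckets[[i]], gold_buckets[[i]]),
               logical(1)))
  incmp <- if (inherits(predicted, "timeline")) predicted$incomparable_pairs else list()
  incmp_key <- vapply(incmp, function(p) paste(sort(p), collapse = "\r"), character(1))
  # representative-pair incomparability extends to whole buckets
  is_incomparable <- function(a, b) {
    if (!length(incmp_key)) return(FALSE)
    paste(sort(c(a, b)), collapse = "\r") %in% incmp_key
  }
  n <- length(gold_ids)
  if (n < 2L) {
    return(list(strict = strict, pairwise = 1.0))
  }
  ok <- 0L; total_pairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- gold_ids[i]; b <- gold_ids[j]
      total_pairs <- total_pairs + 1L
      if (is_incomparable(a, b)) next
      # bucket-level incomparability: same predicted relation as gold?
      if (sign(pi[[a]] - pi[[b]]) == sign(gi[[a]] - gi[[b]])) ok <- ok + 1L
    }
  }
  list(strict = strict, pairwise = ok / total_pairs)
}

#' Score predicted durations against gold durations
#'
#' Exact-match fraction after converting both sides to the working unit
#' (month by default, matching the corpus analysis convention).
#' Unresolvable predictions (`NULL` or `NA` entries) count as incorrect.
#'
#' @param predicted Named list of `cntro_duration` (or `NA` for
#'   unresolvable).
#' @param gold Named list of `cntro_duration`; its names define what is
#'   scored.
#' @param unit Working unit.
#' @return Fraction correct, or `NA` when gold is empty.
#' @export
score_durations <- function(predicted, gold, unit = "month") {
  unit <- as_granularity(unit)
  if (!length(gold)) return(NA_real_)
  ok <- vapply(names(gold), function(id) {
    p <- predicted[[id]]
    if (is.null(p) || !is_duration(p)) return(FALSE)
    if (p$is_range || gold[[id]]$is_range) {
      return(identical(unclass(p), unclass(gold[[id]])))
    }
    convert_duration(p, unit)$magnitude == convert_duration(gold[[id]], unit)$magnitude
  }, logical(1))
  mean(ok)
}

pair_key <- function(a, b) paste(a, b, sep = "\r")

# run the pipeline on one document and score it against gold
score_document <- function(doc, gold, axioms, config, unit) {
  res <- reason_document(doc, axioms = axioms, config = config)
  ordering <- score_ordering(res$timeline, gold)
  dur_err <- character(0)
  safe_duration <- function(expr, what) {
    tryCatch(expr, narratime_error = function(e) {
      dur_err <<- c(dur_err, sprintf("%s: %s", what, conditionMessage(e)))
      NA
    })
  }
  pred_event <- lapply(stats::setNames(nm = names(gold$event_durations)),
                       function(id) {
    safe_duration(event_duration(res$graph, id, unit), id)
  })
  pred_pair <- lapply(gold$pair_durations, function(p) {
    safe_duration(duration_between(res$graph, p$a, p$b, unit),
                  pair_key(p$a, p$b))
  })
  gold_pair <- lapply(gold$pair_durations, `[[`, "duration")
  names(gold_pair) <- vapply(gold$pair_durations,
                             function(p) pair_key(p$a, p$b), character(1))
  names(pred_pair) <- names(gold_pair)
  list(
    doc_id = doc$doc_id,
    ordered_ok = isTRUE(ordering$strict),
    pairwise = ordering$pairwise,
    n_event_durations = length(gold$event_durations),
    event_duration_acc = score_durations(pred_event, gold$event_durations, unit),
    n_pair_durations = length(gold_pair),
    pair_duration_acc = score_durations(pred_pair, gold_pair, unit),
    duration_errors = dur_err
  )
}

#' Evaluate a corpus of documents against gold standards
#'
#' Runs the full reasoning pipeline on every document and aggregates the
#' three accuracy measures: fraction of documents whose full timeline is
#' strictly correct, exact-match accuracy of single-event durations (over
#' documents whose gold records any), and of between-event durations.
#' Documents without a matching gold standard are skipped with a warning.
#'
#' @param docs List of `annotated_document`, or a directory of
#'   `*.doc.json` files.
#' @param golds List of `gold_standard`, or a directory of `*.gold.json`
#'   files; matched to documents by `doc_id`.
#' @param axioms Axioms for the run; defaults to [study_axioms()].
#' @param config Reasoner configuration.
#' @param unit Working duration unit (month).
#' @return An `evaluation_report`.
#' @export
evaluate_corpus <- function(docs, golds, axioms = study_axioms(),
                            config = reasoner_config(), unit = "month") {
  if (is.character(docs)) {
    docs <- lapply(sort(list.files(docs, pattern = "\\.doc\\.json$",
                                   full.names = TRUE)), read_document)
  }
  if (is.character(golds)) {
    golds <- lapply(sort(list.files(golds, pattern = "\\.gold\\.json$",
                                    full.names = TRUE)), read_gold)
  }
  if (!length(docs)) stop_narratime("empty_corpus", "no documents")
  gold_ids <- vapply(golds, `[[`, character(1), "doc_id")
  per_doc <- list()
  for (doc in docs) {
    m <- match(doc$doc_id, gold_ids)
    if (is.na(m)) {
      warning(sprintf("no gold standard for document '%s'; skipped", doc$doc_id))
      next
    }
    per_doc[[length(per_doc) + 1L]] <-
      score_document(doc, golds[[m]], axioms, config, unit)
  }
  if (!length(per_doc)) stop_narratime("empty_corpus", "no documents")
  gv <- function(f) vapply(per_doc, function(d) as.numeric(d[[f]]), numeric(1))
  has_event <- gv("n_event_durations") > 0
  has_pair <- gv("n_pair_durations") > 0
  wmean <- function(acc, n) if (sum(n) == 0) NA_real_ else sum(acc * n, na.rm = TRUE) / sum(n)
  structure(
    list(
      n_docs = length(per_doc),
      ordering_accuracy = mean(vapply(per_doc, `[[`, logical(1), "ordered_ok")),
      n_event_duration_docs = sum(has_event),
      event_duration_accuracy = wmean(gv("event_duration_acc")[has_event],
                                      gv("n_event_durations")[has_event]),
      n_pair_duration_docs = sum(has_pair),
      pair_duration_accuracy = wmean(gv("pair_duration_acc")[has_pair],
                                     gv("n_pair_durations")[has_pair]),
      per_doc = per_doc,
      unit = unit
    ),
    class = "evaluation_report"
  )
}

#' Write the per-document evaluation table as TSV
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  df <- data.frame(
    doc_id = vapply(report$per_doc, `[[`, character(1), "doc_id"),
    ordered_ok = vapply(report$per_doc, `[[`, logical(1), "ordered_ok"),
    pairwise = vapply(report$per_doc, `[[`, numeric(1), "pairwise"),
    event_duration_acc = vapply(report$per_doc, `[[`, numeric(1),
                                "event_duration_acc"),
    pair_duration_acc = vapply(report$per_doc, `[[`, numeric(1),
                               "pair_duration_acc"),
    errors = vapply(report$per_doc,
                    function(d) paste(d$duration_errors, collapse = "; "),
                    character(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.evaluation_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "n/a" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("<evaluation of %d documents>\n", x$n_docs))
  cat(sprintf("  ordering accuracy:        %s (strict, per document)\n",
              pct(x$ordering_accuracy)))
  cat(sprintf("  event duration accuracy:  %s over %d documents (unit: %s)\n",
              pct(x$event_duration_accuracy), x$n_event_duration_docs, x$unit))
  cat(sprintf("  pair duration accuracy:   %s over %d documents (unit: %s)\n",
              pct(x$pair_duration_accuracy), x$n_pair_duration_docs, x$unit))
  invisible(x)
}
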