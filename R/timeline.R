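# Sorting events of a closed graph into ordered timeline buckets.
#
# Bucket semantics are occurrence-time (start-point) semantics: two events
# share a bucket when their start points coincide structurally or their
# (propagated) start timestamps agree at the working granularity; buckets
# are ordered by strict start-point order or strictly ordered timestamps.
# For instantaneous events — the narrative corpus case — this coincides
# with full-interval equality.

#' Sort events into timeline buckets
#'
#' Merges events into simultaneity classes at the working granularity and
#' orders the classes. If a total order exists the buckets are returned
#' earliest first; otherwise the result flags the partial order and lists
#' the incomparable pairs instead of forcing a guess. Ordering is
#' deterministic: ties in reporting are broken by event id.
#'
#' @param graph A consistent `constraint_graph` (timestamps are propagated
#'   internally).
#' @param granularity Working granularity; default is the coarsest
#'   granularity among the document's timestamps (day when none).
#' @return An object of class `timeline`: list of buckets
#'   (`index`, `event_ids`, `anchor`), plus `total_order`,
#'   `incomparable_pairs`, `granularity`.
#' @export
sort_timeline <- function(graph, granularity = NULL) {
  rep_ <- check_consistency(graph)
  if (length(rep_$cycles)) {
    stop_narratime("inconsistent_graph",
                   sprintf("inconsistent constraints; cycle: %s",
                           paste(rep_$cycles[[1]], collapse = " -> ")))
  }
  graph <- propagate_timestamps(graph)
  if (is.null(granularity)) {
    grans <- vapply(graph$stamps, function(s) s$granularity, character(1))
    granularity <- if (length(grans)) GRANULARITIES[max(vapply(grans, gran_level, 1L))]
                   else "day"
  }
  g <- as_granularity(granularity)
  cl <- closure(graph)
  ids <- sort(graph$events)
  n <- length(ids)
  starts <- p_start(ids)
  stamp <- lapply(starts, function(p) graph$stamps[[p]])
  names(stamp) <- ids

  # union-find over events: same bucket when start points coincide or
  # start stamps agree at the working granularity
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) { parent[max(find(i), find(j))] <<- min(find(i), find(j)) }
  cmp_at_g <- function(i, j) {
    si <- stamp[[ids[i]]]; sj <- stamp[[ids[j]]]
    if (is.null(si) || is.null(sj)) return(NA_integer_)
    gg <- gran_coarser(g, gran_coarser(si$granularity, sj$granularity))
    c1 <- ts_truncate(si, gg); c2 <- ts_truncate(sj, gg)
    ts_compare(c1, c2)$cmp
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        same <- cl$EQ[starts[i], starts[j]] || isTRUE(cmp_at_g(i, j) == 0L)
        if (same) union(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  classes <- split(seq_len(n), roots)
  k <- length(classes)

  # class-level strict order: structural strict start order, or strictly
  # ordered stamps at the working granularity
  before <- matrix(FALSE, k, k)
  for (x in seq_len(k)) {
    for (y in seq_len(k)) {
      if (x == y) next
      for (i in classes[[x]]) {
        for (j in classes[[y]]) {
          if (cl$LT[starts[i], starts[j]] || isTRUE(cmp_at_g(i, j) < 0L)) {
            before[x, y] <- TRUE
          }
        }
      }
    }
  }
  for (m in seq_len(k)) {  # transitive closure across mixed evidence
    before <- before | outer(before[, m], before[m, ], "&")
  }
  if (any(before & t(before)) || any(diag(before))) {
    stop_narratime("inconsistent_graph",
                   sprintf("events inconsistently ordered at granularity '%s'", g))
  }
  n_pred <- colSums(before)
  min_id <- vapply(classes, function(cc) min(ids[cc]), character(1))
  ord <- order(n_pred, min_id)
  incomparable <- list()
  for (x in seq_len(k)) {
    for (y in seq_len(k)) {
      if (x < y && !before[x, y] && !before[y, x]) {
        pair <- unname(sort(c(min_id[x], min_id[y])))
        incomparable[[length(incomparable) + 1L]] <- pair
      }
    }
  }
  buckets <- lapply(seq_along(ord), function(pos) {
    cc <- classes[[ord[pos]]]
    anchor <- NULL
    for (i in cc) {
      s <- stamp[[ids[i]]]
      if (!is.null(s) && gran_ge(g, s$granularity)) {
        anchor <- ts_truncate(s, g)
        break
      }
    }
    list(index = pos, event_ids = sort(ids[cc]), anchor = anchor)
  })
  structure(
    list(buckets = buckets, total_order = length(incomparable) == 0L,
         incomparable_pairs = incomparable, granularity = g),
    class = "timeline"
  )
}

#' Bucket id sets of a timeline, earliest first
#' @param tl A `timeline`.
#' @return List of character vectors.
#' @export
timeline_buckets <- function(tl) {
  stopifnot(inherits(tl, "timeline"))
  lapply(tl$buckets, `[[`, "event_ids")
}

#' Write a timeline as JSON
#'
#' One entry per bucket: `index`, `event_ids`, `anchor` (canonical
#' timestamp string or null).
#'
#' @param tl A `timeline`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_timeline_json <- function(tl, path) {
  out <- list(
    granularity = tl$granularity,
    total_order = tl$total_order,
    buckets = lapply(tl$buckets, function(b) {
      list(index = b$index, event_ids = as.list(b$event_ids),
           anchor = if (is.null(b$anchor)) NULL else format(b$anchor))
    }),
    incomparable_pairs = lapply(tl$incomparable_pairs, as.list)
  )
  write_canonical_json(out, path)
}

#' @export
print.timeline <- function(x, ...) {
  cat(sprintf("<timeline at %s granularity%s>\n", x$granularity,
              if (x$total_order) "" else " (PARTIAL ORDER)"))
  for (b in x$buckets) {
    cat(sprintf("  %d. %s%s\n", b$index, paste(b$event_ids, collapse = ", "),
                if (is.null(b$anchor)) "" else paste0("  @", format(b$anchor))))
  }
  if (!x$total_order) {
    for (p in x$incomparable_pairs) {
      cat(sprintf("  incomparable: %s | %s\n", p[1], p[2]))
    }
  }
  invisible(x)
}
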