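# The reasoning engine. Interval relations are compiled to constraints
# over event start/end points, which turns relation closure into a
# reachability problem over a small point graph: < and <= edges for order,
# equality edges (optionally carrying an exact duration offset) for
# coincidence and quantified delays. Timestamps are propagated to a
# fixpoint along equality/offset edges, and durations are recovered by
# summing offsets along simple paths.

#' Reasoner configuration
#'
#' @param granular_relations Honor relation granularities: "A before B at
#'   day granularity" additionally means A and B fall on the same day, so
#'   the pair contributes a zero offset at day granularity to duration
#'   chains and copies day-truncated timestamps. Default on.
#' @param default_unit Default output unit for durations (the narrative
#'   corpus is analyzed at month granularity).
#' @param dialect Slash-date dialect for the normalizer.
#' @return A `reasoner_config` list.
#' @export
reasoner_config <- function(granular_relations = TRUE,
                            default_unit = "month",
                            dialect = c("us", "intl")) {
  structure(
    list(granular_relations = isTRUE(granular_relations),
         default_unit = as_granularity(default_unit),
         dialect = match.arg(dialect)),
    class = "reasoner_config"
  )
}

#' Read a key=value reasoner configuration file
#'
#' Recognized keys: `granular_relations` (on/off), `default_unit`,
#' `dialect`, `death_last` (on/off), `instantaneous`
#' (comma-separated event types). Lines starting with `#` are ignored.
#'
#' @param path Path to the config file.
#' @return List with elements `config` ([reasoner_config()]) and `axioms`
#'   ([axiom_set()]).
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  get <- function(k, default) if (k %in% keys) vals[match(k, keys)] else default
  on_off <- function(v) tolower(v) %in% c("on", "true", "yes", "1")
  list(
    config = reasoner_config(
      granular_relations = on_off(get("granular_relations", "on")),
      default_unit = get("default_unit", "month"),
      dialect = get("dialect", "us")
    ),
    axioms = axiom_set(
      death_last = on_off(get("death_last", "off")),
      instantaneous_event_types =
        if ("instantaneous" %in% keys) {
          trimws(strsplit(get("instantaneous", ""), ",")[[1]])
        } else character(0)
    )
  )
}

#' Background domain axioms
#'
#' Domain knowledge the narratives leave implicit: patient death is
#' inherently the last event of a patient-care timeline, and procedures
#' such as a stent implantation occur at a single point in time (a
#' procedure cannot last for months). Both are off by default and enabled
#' per corpus.
#'
#' @param death_last Constrain every other event to end at or before each
#'   death event's start.
#' @param instantaneous_event_types Event types whose start and end points
#'   are collapsed.
#' @return An `axiom_set` list.
#' @seealso [study_axioms()] for the adverse-event study defaults.
#' @export
axiom_set <- function(death_last = FALSE,
                      instantaneous_event_types = character(0)) {
  bad <- setdiff(instantaneous_event_types, EVENT_TYPES)
  if (length(bad)) {
    stop_narratime("invalid_axioms",
                   sprintf("unknown event types: %s", paste(bad, collapse = ", ")))
  }
  structure(list(death_last = isTRUE(death_last),
                 instantaneous_event_types = instantaneous_event_types),
            class = "axiom_set")
}

#' Axiom defaults for the stent-thrombosis corpus
#'
#' Death is last, and all point-like clinical events (implantations,
#' therapy start/stop, surgery, thrombosis, infarction, ER admission,
#' death) are instantaneous. The antiplatelet therapy interval is the only
#' genuinely extended event type.
#'
#' @return An `axiom_set`.
#' @export
study_axioms <- function() {
  axiom_set(
    death_last = TRUE,
    instantaneous_event_types = setdiff(EVENT_TYPES,
                                        c("antiplatelet_therapy", "other"))
  )
}

# ---------------------------------------------------------------------------
# graph construction

new_edge <- function(from, to, type, offset = NULL, gran = NULL, source = "") {
  list(from = from, to = to, type = type, offset = offset, gran = gran,
       source = source)
}

p_start <- function(id) paste0(id, ".start")
p_end <- function(id) paste0(id, ".end")

#' Compile a document into a point constraint graph
#'
#' Each event contributes a start and an end point with `start <= end`.
#' Assertions compile to point constraints: BEFORE as `end(a) < start(b)`
#' (an exact-offset equality when a temporal offset is annotated), EQUAL
#' as coincidence of both endpoints, STARTS/FINISHES as start-point/
#' end-point coincidence, DURING/CONTAINS as nested endpoint
#' inequalities. Explicit (non-range) event durations become exact
#' start-to-end offsets, timestamps attach to points, and enabled axioms
#' inject their constraints.
#'
#' @param doc An `annotated_document`.
#' @param axioms An [axiom_set()].
#' @param config A [reasoner_config()].
#' @return An object of class `constraint_graph`.
#' @export
build_graph <- function(doc, axioms = axiom_set(), config = reasoner_config()) {
  validate_document(doc)
  ids <- event_ids(doc)
  points <- as.vector(rbind(p_start(ids), p_end(ids)))
  edges <- list()
  stamps <- list()
  add <- function(...) edges[[length(edges) + 1L]] <<- new_edge(...)

  types <- stats::setNames(vapply(doc$events, function(e) e$event_type,
                                  character(1)), ids)
  for (id in ids) {
    if (types[[id]] %in% axioms$instantaneous_event_types) {
      add(p_start(id), p_end(id), "eq", source = "axiom:instantaneous")
    } else {
      add(p_start(id), p_end(id), "le", source = "structure")
    }
  }
  for (id in names(doc$durations)) {
    d <- doc$durations[[id]]
    if (!d$is_range) {
      add(p_start(id), p_end(id), "eq", offset = d, source = "duration")
    }
  }
  anon <- 0L
  for (i in seq_along(doc$assertions)) {
    a <- doc$assertions[[i]]
    src <- sprintf("assertion %d", i)
    if (is_timestamp(a$object)) {
      anon <- anon + 1L
      pt <- sprintf(".t%d", anon)
      points <- c(points, pt)
      stamps[[pt]] <- a$object
      obj_s <- pt; obj_e <- pt
    } else {
      obj_s <- p_start(a$object); obj_e <- p_end(a$object)
    }
    sub_s <- p_start(a$subject); sub_e <- p_end(a$subject)
    switch(a$relation,
      BEFORE = {
        if (!is.null(a$offset)) {
          add(sub_e, obj_s, "eq", offset = a$offset, source = src)
        } else {
          add(sub_e, obj_s, "lt", gran = a$relation_granularity, source = src)
        }
      },
      AFTER = {
        if (!is.null(a$offset)) {
          add(obj_e, sub_s, "eq", offset = a$offset, source = src)
        } else {
          add(obj_e, sub_s, "lt", gran = a$relation_granularity, source = src)
        }
      },
      EQUAL = {
        add(sub_s, obj_s, "eq", source = src)
        add(sub_e, obj_e, "eq", source = src)
      },
      STARTS = add(sub_s, obj_s, "eq", source = src),
      FINISHES = add(sub_e, obj_e, "eq", source = src),
      DURING = {
        add(obj_s, sub_s, "le", source = src)
        add(sub_e, obj_e, "le", source = src)
      },
      CONTAINS = {
        add(sub_s, obj_s, "le", source = src)
        add(obj_e, sub_e, "le", source = src)
      }
    )
  }
  if (axioms$death_last) {
    deaths <- ids[types == "death"]
    for (d in deaths) {
      for (e in setdiff(ids, d)) {
        add(p_end(e), p_start(d), "le", source = "axiom:death_last")
      }
    }
  }
  for (id in names(doc$timestamps)) {
    t <- doc$timestamps[[id]]
    if (!is.null(t$start)) stamps[[p_start(id)]] <- t$start
    if (!is.null(t$end)) stamps[[p_end(id)]] <- t$end
  }
  structure(
    list(doc = doc, events = ids, event_types = types, points = points,
         edges = edges, stamps = stamps, axioms = axioms, config = config),
    class = "constraint_graph"
  )
}

#' @export
print.constraint_graph <- function(x, ...) {
  cat(sprintf("<constraint graph: %d events, %d points, %d edges, %d stamped points>\n",
              length(x$events), length(x$points), length(x$edges),
              length(x$stamps)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# closure: boolean reachability over points
# LE[i,j]: point i <= point j derivable; LT[i,j]: i < j derivable (some
# path uses a strict step). Equality edges with a positive offset are
# strict; zero or unquantified equality edges connect both ways.

edge_is_strict <- function(e) {
  switch(e$type,
    lt = TRUE,
    eq = !is.null(e$offset) && e$offset$magnitude > 0L && !e$offset$is_range,
    FALSE
  )
}

closure <- function(graph) {
  pts <- graph$points
  n <- length(pts)
  idx <- stats::setNames(seq_len(n), pts)
  LE <- diag(n) > 0
  LT <- matrix(FALSE, n, n)
  for (e in graph$edges) {
    i <- idx[[e$from]]; j <- idx[[e$to]]
    strict <- edge_is_strict(e)
    LE[i, j] <- TRUE
    if (strict) LT[i, j] <- TRUE
    if (e$type == "eq" && !strict) LE[j, i] <- TRUE
  }
  for (k in seq_len(n)) {
    le_k <- LE[, k]; le_from_k <- LE[k, ]
    lt_k <- LT[, k]; lt_from_k <- LT[k, ]
    LE <- LE | outer(le_k, le_from_k, "&")
    LT <- LT | outer(lt_k, le_from_k, "&") | outer(le_k, lt_from_k, "&")
  }
  dimnames(LE) <- dimnames(LT) <- list(pts, pts)
  list(LE = LE, LT = LT, EQ = LE & t(LE))
}

#' Check a constraint graph for inconsistencies
#'
#' Reports strict cycles (a chain of constraints forcing a point strictly
#' before itself) and timestamp conflicts (two derivations of a point's
#' timestamp that disagree at their common granularity). An empty report
#' means the graph is consistent.
#'
#' @param graph A `constraint_graph`.
#' @return A `consistency_report`: list with `consistent`, `cycles` (each
#'   a character vector of point names), and `conflicts`.
#' @export
check_consistency <- function(graph) {
  cl <- closure(graph)
  cycles <- list()
  bad <- which(diag(cl$LT))
  seen <- rep(FALSE, length(graph$points))
  for (i in bad) {
    if (seen[i]) next
    members <- which(cl$EQ[i, ] & diag(cl$LT))
    seen[members] <- TRUE
    cycles[[length(cycles) + 1L]] <- minimal_cycle(graph, graph$points[i])
  }
  conflicts <- tryCatch({
    propagate_timestamps(graph)
    list()
  }, narratime_timestamp_conflict = function(e) list(conditionMessage(e)))
  structure(list(consistent = length(cycles) == 0L && length(conflicts) == 0L,
                 cycles = cycles, conflicts = conflicts),
            class = "consistency_report")
}

# shortest cycle through `point` containing at least one strict step:
# BFS over states (point, strict-step-seen)
minimal_cycle <- function(graph, point) {
  arcs <- list()
  for (e in graph$edges) {
    strict <- edge_is_strict(e)
    arcs[[length(arcs) + 1L]] <- list(from = e$from, to = e$to, strict = strict)
    if (e$type == "eq" && !strict) {
      arcs[[length(arcs) + 1L]] <- list(from = e$to, to = e$from, strict = FALSE)
    }
  }
  frontier <- list(list(at = point, strict = FALSE, path = point))
  visited <- character(0)
  while (length(frontier)) {
    nxt <- list()
    for (st in frontier) {
      for (a in arcs) {
        if (a$from != st$at) next
        strict <- st$strict || a$strict
        if (a$to == point && strict) return(c(st$path, point))
        key <- paste(a$to, strict)
        if (key %in% visited) next
        visited <- c(visited, key)
        nxt[[length(nxt) + 1L]] <- list(at = a$to, strict = strict,
                                        path = c(st$path, a$to))
      }
    }
    frontier <- nxt
  }
  point
}

#' @export
print.consistency_report <- function(x, ...) {
  if (x$consistent) {
    cat("<consistent constraint graph>\n")
  } else {
    cat(sprintf("<INCONSISTENT: %d strict cycle(s), %d timestamp conflict(s)>\n",
                length(x$cycles), length(x$conflicts)))
    for (cy in x$cycles) cat("  cycle:", paste(cy, collapse = " -> "), "\n")
    for (cf in x$conflicts) cat("  conflict:", cf, "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# timestamp propagation

#' Propagate timestamps to a fixpoint
#'
#' Equality edges copy timestamps between points; exact-offset edges
#' compute new ones by calendar arithmetic (in both directions); with
#' granular relations enabled, "before at granularity g" copies
#' g-truncated timestamps (the pair shares the same g-unit). Points are
#' only ever assigned, never reassigned, so iteration terminates. Two
#' derivations that disagree at their common granularity raise a
#' `timestamp conflict` error.
#'
#' @param graph A `constraint_graph`.
#' @return The graph with `stamps` extended.
#' @export
propagate_timestamps <- function(graph) {
  stamps <- graph$stamps
  gran_on <- graph$config$granular_relations
  check_agree <- function(existing, candidate, at) {
    cmp <- ts_compare(existing, candidate)
    if (cmp$cmp != 0L) {
      stop_narratime("timestamp_conflict",
                     sprintf("timestamp conflict at %s: %s vs %s (compared at %s)",
                             at, format(existing), format(candidate),
                             cmp$granularity))
    }
  }
  place <- function(point, candidate) {
    if (is.null(stamps[[point]])) {
      stamps[[point]] <<- candidate
      TRUE
    } else {
      check_agree(stamps[[point]], candidate, point)
      FALSE
    }
  }
  repeat {
    changed <- FALSE
    for (e in graph$edges) {
      sf <- stamps[[e$from]]; st <- stamps[[e$to]]
      if (is.null(sf) && is.null(st)) next
      if (e$type == "eq") {
        if (!is.null(e$offset) && e$offset$is_range) next
        if (!is.null(sf)) {
          cand <- if (is.null(e$offset)) sf else add_duration(sf, e$offset, +1L)
          changed <- place(e$to, cand) || changed
        }
        sf <- stamps[[e$from]]; st <- stamps[[e$to]]
        if (!is.null(st) && is.null(sf)) {
          cand <- if (is.null(e$offset)) st else add_duration(st, e$offset, -1L)
          changed <- place(e$from, cand) || changed
        }
      } else if (e$type == "lt" && !is.null(e$gran) && gran_on) {
        # same g-unit assumption: copy g-truncated stamps both ways
        if (!is.null(sf)) {
          g <- gran_coarser(e$gran, sf$granularity)
          changed <- place(e$to, ts_truncate(sf, g)) || changed
        }
        st <- stamps[[e$to]]
        if (!is.null(st) && is.null(stamps[[e$from]])) {
          g <- gran_coarser(e$gran, st$granularity)
          changed <- place(e$from, ts_truncate(st, g)) || changed
        }
      }
    }
    if (!changed) break
  }
  graph$stamps <- stamps
  graph
}

# ---------------------------------------------------------------------------
# relation inference

assertion_key <- function(a) {
  paste(a$subject, a$relation,
        if (is_timestamp(a$object)) format(a$object) else a$object)
}

#' Infer event-level temporal relations
#'
#' Closes the point graph under transitivity of order and equality,
#' substitution of equalities into inequalities, and inversion (every
#' derived BEFORE emits its AFTER twin), then adds relations decided by
#' comparing propagated timestamps at their coarser common granularity:
#' strictly smaller yields BEFORE, equality at that granularity yields
#' EQUAL with `relation_granularity` set. Pairs that remain undecidable
#' are reported by their absence, never guessed.
#'
#' @param graph A `constraint_graph` (timestamps are propagated
#'   internally).
#' @return List of `cntro_assertion` objects with `asserted = FALSE`,
#'   excluding relations identical to asserted ones. Errors with a minimal
#'   cycle if the graph is inconsistent.
#' @export
infer_relations <- function(graph) {
  rep_ <- check_consistency(graph)
  if (length(rep_$cycles)) {
    stop_narratime("inconsistent_graph",
                   sprintf("inconsistent constraints; cycle: %s",
                           paste(rep_$cycles[[1]], collapse = " -> ")))
  }
  graph <- propagate_timestamps(graph)
  cl <- closure(graph)
  LE <- cl$LE; LT <- cl$LT; EQ <- cl$EQ
  stamps <- graph$stamps
  ids <- graph$events
  out <- list()
  emit <- function(sub, rel, obj, gran = NULL) {
    out[[length(out) + 1L]] <<- assertion(sub, rel, obj,
                                          relation_granularity = gran,
                                          asserted = FALSE)
    out[[length(out) + 1L]] <<- assertion(obj, RELATION_INVERSE[[rel]], sub,
                                          relation_granularity = gran,
                                          asserted = FALSE)
  }
  # stamp of a point, falling back to its twin when the event is collapsed
  stamp_of <- function(p, twin) {
    s <- stamps[[p]]
    if (is.null(s) && EQ[p, twin]) s <- stamps[[twin]]
    s
  }
  n <- length(ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        a <- ids[i]; b <- ids[j]
        sa <- p_start(a); ea <- p_end(a)
        sb <- p_start(b); eb <- p_end(b)
        decided <- FALSE
        if (EQ[sa, sb] && EQ[ea, eb]) {
          emit(a, "EQUAL", b); decided <- TRUE
        } else if (LT[ea, sb]) {
          emit(a, "BEFORE", b); decided <- TRUE
        } else if (LT[eb, sa]) {
          emit(b, "BEFORE", a); decided <- TRUE
        }
        if (!decided) {
          ta_end <- stamp_of(ea, sa); tb_start <- stamp_of(sb, eb)
          ta_start <- stamp_of(sa, ea); tb_end <- stamp_of(eb, sb)
          if (!is.null(ta_end) && !is.null(tb_start) &&
              ts_compare(ta_end, tb_start)$cmp < 0L) {
            emit(a, "BEFORE", b); decided <- TRUE
          } else if (!is.null(tb_end) && !is.null(ta_start) &&
                     ts_compare(tb_end, ta_start)$cmp < 0L) {
            emit(b, "BEFORE", a); decided <- TRUE
          } else if (!is.null(ta_start) && !is.null(tb_start) &&
                     !is.null(ta_end) && !is.null(tb_end)) {
            c1 <- ts_compare(ta_start, tb_start)
            c2 <- ts_compare(ta_end, tb_end)
            if (c1$cmp == 0L && c2$cmp == 0L) {
              emit(a, "EQUAL", b, gran = gran_coarser(c1$granularity,
                                                      c2$granularity))
              decided <- TRUE
            }
          }
        }
        if (!decided) {
          if (EQ[sa, sb]) emit(a, "STARTS", b)
          if (EQ[ea, eb]) emit(a, "FINISHES", b)
          if (LE[sb, sa] && LE[ea, eb] && (LT[sb, sa] || LT[ea, eb])) {
            emit(a, "DURING", b)
          } else if (LE[sa, sb] && LE[eb, ea] && (LT[sa, sb] || LT[eb, ea])) {
            emit(b, "DURING", a)
          }
        }
      }
    }
  }
  asserted_keys <- vapply(graph$doc$assertions, assertion_key, character(1))
  out[!vapply(out, assertion_key, character(1)) %in% asserted_keys]
}

# ---------------------------------------------------------------------------
# duration machinery: signed-offset traversal over points

# arcs: list(from, to, minutes, floor_gran or NA). floor_gran is the
# granularity at which a zero contribution is sound (granular relations);
# the requested output unit must be at or coarser than every floor on the
# path. exclude_width_of: event id whose implicit zero-width start-end arc
# must not be used (event_duration must not assume its own answer).
traversal_arcs <- function(graph, exclude_width_of = NULL) {
  arcs <- list()
  push <- function(from, to, minutes, floor_gran = NA_character_) {
    arcs[[length(arcs) + 1L]] <<- list(from = from, to = to, minutes = minutes,
                                       floor_gran = floor_gran)
    arcs[[length(arcs) + 1L]] <<- list(from = to, to = from, minutes = -minutes,
                                       floor_gran = floor_gran)
  }
  for (e in graph$edges) {
    if (e$type == "eq") {
      if (!is.null(e$offset) && e$offset$is_range) next
      push(e$from, e$to,
           if (is.null(e$offset)) 0 else duration_minutes(e$offset))
    } else if (e$type == "lt" && !is.null(e$gran) &&
               graph$config$granular_relations) {
      push(e$from, e$to, 0, floor_gran = e$gran)
    }
  }
  # point-event default: an event with no duration annotation contributes
  # zero width when chained through
  for (id in graph$events) {
    if (id %in% names(graph$doc$durations)) next
    if (graph$event_types[[id]] %in% graph$axioms$instantaneous_event_types) next
    if (identical(id, exclude_width_of)) next
    push(p_start(id), p_end(id), 0)
  }
  arcs
}

# all simple-path sums (minutes) from src to dst; each result carries the
# coarsest floor granularity seen on its path
path_sums <- function(arcs, src, dst, max_depth) {
  results <- list()
  by_from <- split(arcs, vapply(arcs, `[[`, character(1), "from"))
  walk <- function(at, visited, total, floor_lvl) {
    if (at == dst) {
      results[[length(results) + 1L]] <<- list(minutes = total,
                                               floor_lvl = floor_lvl)
      return()
    }
    if (length(visited) > max_depth) return()
    for (a in by_from[[at]]) {
      if (a$to %in% visited) next
      fl <- floor_lvl
      if (!is.na(a$floor_gran)) fl <- max(fl, gran_level(a$floor_gran))
      walk(a$to, c(visited, a$to), total + a$minutes, fl)
    }
  }
  walk(src, src, 0, 0L)
  results
}

resolve_paths <- function(graph, src, dst, out_unit, exclude_width_of = NULL) {
  arcs <- traversal_arcs(graph, exclude_width_of = exclude_width_of)
  sums <- path_sums(arcs, src, dst, max_depth = length(graph$points))
  if (!length(sums)) return(NULL)
  valid <- Filter(function(s) gran_level(out_unit) >= s$floor_lvl, sums)
  if (!length(valid)) {
    stop_narratime("insufficient_precision",
                   sprintf("paths only decide the duration at coarser granularity than '%s'",
                           out_unit))
  }
  vals <- unique(vapply(valid, function(s) {
    round_half_up(abs(s$minutes) / MINUTES_PER_UNIT[[out_unit]])
  }, numeric(1)))
  if (length(vals) > 1L) {
    stop_narratime("inconsistent_offsets",
                   sprintf("simple paths disagree at unit '%s': %s",
                           out_unit, paste(sort(vals), collapse = ", ")))
  }
  duration(vals, out_unit)
}

#' Duration of a single event
#'
#' Resolution order: (1) an explicit duration annotation; (2) start and
#' end timestamps, differenced at their coarser common granularity;
#' (3) chaining through related events, summing exact offsets along simple
#' paths from the event's start point to its end point (all paths must
#' agree at the output unit). The result is converted to `out_unit` under
#' the 30-day-month conventions. Range-only evidence raises an
#' insufficient-precision error; no evidence raises insufficient
#' information.
#'
#' @param graph A `constraint_graph`.
#' @param e Event id.
#' @param out_unit Output granularity (defaults to the config's default
#'   unit, month).
#' @return A `cntro_duration`.
#' @export
event_duration <- function(graph, e, out_unit = graph$config$default_unit) {
  out_unit <- as_granularity(out_unit)
  if (!e %in% graph$events) {
    stop_narratime("unknown_event", sprintf("no event '%s' in graph", e))
  }
  d <- graph$doc$durations[[e]]
  if (!is.null(d) && !d$is_range) {
    return(convert_duration(d, out_unit))
  }
  graph <- propagate_timestamps(graph)
  ts_s <- graph$stamps[[p_start(e)]]
  ts_e <- graph$stamps[[p_end(e)]]
  if (!is.null(ts_s) && !is.null(ts_e)) {
    g0 <- gran_coarser(ts_s$granularity, ts_e$granularity)
    return(convert_duration(timestamp_difference(ts_s, ts_e, g0), out_unit))
  }
  res <- resolve_paths(graph, p_start(e), p_end(e), out_unit,
                       exclude_width_of = e)
  if (!is.null(res)) return(res)
  if (!is.null(d) && d$is_range) {
    stop_narratime("insufficient_precision",
                   sprintf("only a range duration ('%s') is annotated for '%s'",
                           format(d), e))
  }
  stop_narratime("insufficient_information",
                 sprintf("insufficient information to resolve the duration of '%s'", e))
}

#' Duration between two events
#'
#' Resolution order: (1) both events carry (propagated) start timestamps,
#' differenced at their coarser common granularity; (2) otherwise offsets
#' are summed along simple paths between the two events' start points —
#' exact BEFORE/AFTER offsets, equalities, zero-width traversal of
#' point-like intermediate events, and (with granular relations on) zero
#' contributions at the relation's granularity. All simple paths must
#' agree at the output unit; disagreement is an error, never averaged.
#' The magnitude is symmetric in the two events.
#'
#' @param graph A `constraint_graph`.
#' @param a,b Event ids.
#' @param out_unit Output granularity.
#' @return A non-negative `cntro_duration`.
#' @export
duration_between <- function(graph, a, b, out_unit = graph$config$default_unit) {
  out_unit <- as_granularity(out_unit)
  for (id in c(a, b)) {
    if (!id %in% graph$events) {
      stop_narratime("unknown_event", sprintf("no event '%s' in graph", id))
    }
  }
  if (identical(a, b)) return(duration(0, out_unit))
  graph <- propagate_timestamps(graph)
  ts_a <- graph$stamps[[p_start(a)]]
  ts_b <- graph$stamps[[p_start(b)]]
  if (!is.null(ts_a) && !is.null(ts_b)) {
    g0 <- gran_coarser(ts_a$granularity, ts_b$granularity)
    return(convert_duration(timestamp_difference(ts_a, ts_b, g0), out_unit))
  }
  res <- resolve_paths(graph, p_start(a), p_start(b), out_unit)
  if (!is.null(res)) return(res)
  stop_narratime("insufficient_information",
                 sprintf("insufficient information to resolve the duration between '%s' and '%s'",
                         a, b))
}

# ---------------------------------------------------------------------------

#' Run the full reasoning pipeline on a document
#'
#' Builds the constraint graph, checks consistency, propagates timestamps,
#' infers relations, and sorts the timeline.
#'
#' @param doc An `annotated_document`.
#' @param axioms An [axiom_set()].
#' @param config A [reasoner_config()].
#' @param granularity Working granularity for the timeline; default the
#'   coarsest granularity present in the document's timestamps.
#' @return A `narratime_result`: list with `graph` (propagated),
#'   `inferred`, `timeline`, and `matrix`.
#' @export
reason_document <- function(doc, axioms = axiom_set(),
                            config = reasoner_config(), granularity = NULL) {
  graph <- build_graph(doc, axioms = axioms, config = config)
  inferred <- infer_relations(graph)
  graph <- propagate_timestamps(graph)
  tl <- sort_timeline(graph, granularity = granularity)
  structure(
    list(graph = graph, inferred = inferred, timeline = tl,
         matrix = relation_matrix(doc, inferred)),
    class = "narratime_result"
  )
}

#' @export
print.narratime_result <- function(x, ...) {
  cat(sprintf("<reasoned document '%s': %d inferred relations>\n",
              x$graph$doc$doc_id, length(x$inferred)))
  print(x$timeline)
  invisible(x)
}
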