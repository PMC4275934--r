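# Seeded generator of MAUDE-style late-stent-thrombosis annotation
# documents with exact ground truth. Each document samples a latent true
# timeline (implant; antiplatelet therapy starting at implant; therapy
# stop; optional unrelated surgery; late stent thrombosis; optional MI /
# ER admission; optional death, always last) and renders it into
# annotations in one of several expression styles, so granularity
# truncation effects (month-level reporting of day-level truth) arise
# naturally. The gold standard records the latent truth.

#' Specification of a synthetic adverse-event corpus
#'
#' Durations are lognormal on the month scale (strictly positive and
#' right-skewed, like adverse-event timing). Defaults emulate the
#' published late-stent-thrombosis case mix: therapy duration with median
#' 6 months; implant-to-thrombosis interval with median about 14.6 months
#' for short-therapy patients, shifted later by `lst_therapy_effect` (log
#' scale) when therapy reaches 6 months, reproducing the qualitative
#' longer-therapy-later-thrombosis pattern.
#'
#' @param n_docs Number of documents (the study corpus had 238).
#' @param seed Integer seed; each document draws from its own substream.
#' @param p_surgery,p_mi,p_er,p_death Inclusion probabilities of the
#'   optional events.
#' @param therapy_duration_distribution List `meanlog`, `sdlog` (months).
#' @param implant_to_lst_distribution List `meanlog`, `sdlog` (months).
#' @param lst_therapy_effect Added to `meanlog` of the implant-to-LST
#'   distribution when therapy lasts 6 or more months.
#' @param expression_style_mix Named weights (summing to 1) over rendering
#'   styles `absolute_day`, `absolute_month`, `offset_days`,
#'   `offset_months`, `explicit_duration`.
#' @param p_missing_duration Probability that a narrative omits the
#'   information fixing the therapy stop time (such narratives were
#'   excluded from the published survival analysis).
#' @param p_range_duration Probability that the therapy duration is only
#'   reported as a range ("6-7 months").
#' @return A `corpus_spec`.
#' @export
corpus_spec <- function(n_docs = 238L,
                        seed = 20140101L,
                        p_surgery = 0.35,
                        p_mi = 0.30,
                        p_er = 0.40,
                        p_death = 0.12,
                        therapy_duration_distribution = list(meanlog = log(6), sdlog = 0.6),
                        implant_to_lst_distribution = list(meanlog = log(14.6), sdlog = 0.45),
                        lst_therapy_effect = 0.6,
                        expression_style_mix = c(absolute_day = 0.25,
                                                 absolute_month = 0.20,
                                                 offset_days = 0.20,
                                                 offset_months = 0.15,
                                                 explicit_duration = 0.20),
                        p_missing_duration = 0.15,
                        p_range_duration = 0.05) {
  probs <- c(p_surgery = p_surgery, p_mi = p_mi, p_er = p_er,
             p_death = p_death, p_missing_duration = p_missing_duration,
             p_range_duration = p_range_duration)
  if (any(probs < 0 | probs > 1)) {
    stop_narratime("invalid_spec", "probabilities must lie in [0, 1]")
  }
  styles <- c("absolute_day", "absolute_month", "offset_days",
              "offset_months", "explicit_duration")
  if (!setequal(names(expression_style_mix), styles) ||
      abs(sum(expression_style_mix) - 1) > 1e-8 ||
      any(expression_style_mix < 0)) {
    stop_narratime("invalid_spec",
                   "expression_style_mix must be non-negative weights over the five styles summing to 1")
  }
  for (d in list(therapy_duration_distribution, implant_to_lst_distribution)) {
    if (!is.numeric(d$meanlog) || !is.numeric(d$sdlog) || d$sdlog <= 0) {
      stop_narratime("invalid_spec", "distributions need meanlog and positive sdlog")
    }
  }
  structure(
    list(n_docs = as.integer(n_docs), seed = as.integer(seed),
         p_surgery = p_surgery, p_mi = p_mi, p_er = p_er, p_death = p_death,
         therapy_duration_distribution = therapy_duration_distribution,
         implant_to_lst_distribution = implant_to_lst_distribution,
         lst_therapy_effect = lst_therapy_effect,
         expression_style_mix = expression_style_mix[styles],
         p_missing_duration = p_missing_duration,
         p_range_duration = p_range_duration),
    class = "corpus_spec"
  )
}

#' Simulate one annotated document with its gold standard
#'
#' Samples the latent timeline, renders it in a sampled expression style,
#' and returns both the rendered annotation document and the ground truth.
#' Documents whose rendering provably under-determines the ordering or the
#' therapy duration (missing or range-only duration information) carry
#' `metadata$ambiguous = TRUE`.
#'
#' @param spec A [corpus_spec()].
#' @param seed Integer seed for this document's substream.
#' @param doc_id Document identifier.
#' @return List with `document` (`annotated_document`) and `gold`
#'   (`gold_standard`).
#' @export
simulate_document <- function(spec, seed, doc_id = sprintf("SYN-%09d", seed)) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(seed)
  style <- sample(names(spec$expression_style_mix), 1L,
                  prob = spec$expression_style_mix)
  month_grid <- style %in% c("absolute_month", "offset_months", "explicit_duration")

  tdist <- spec$therapy_duration_distribution
  ldist <- spec$implant_to_lst_distribution
  therapy_months_raw <- stats::rlnorm(1, tdist$meanlog, tdist$sdlog)
  eff <- spec$lst_therapy_effect * (therapy_months_raw >= 6)
  lst_months_raw <- stats::rlnorm(1, ldist$meanlog + eff, ldist$sdlog)

  # latent positions: days since implant (month-grid styles sample whole
  # months and place events on a 30-day grid so month-level rendering is
  # exact)
  if (month_grid) {
    stop_m <- max(1L, as.integer(round(therapy_months_raw)))
    lst_m <- max(stop_m + 2L, as.integer(round(lst_months_raw)))
    unit_days <- 30L
    pos <- c(implant = 0L, ap_start = 0L, ap_stop = stop_m, lst = lst_m)
    surgery_range <- if (lst_m - stop_m >= 2L) (stop_m + 1L):(lst_m - 1L) else integer(0)
    death_gap <- sample(1:3, 1L)
  } else {
    stop_d <- max(1L, as.integer(round(therapy_months_raw * 30)))
    lst_d <- max(stop_d + 4L, as.integer(round(lst_months_raw * 30)))
    unit_days <- 1L
    pos <- c(implant = 0L, ap_start = 0L, ap_stop = stop_d, lst = lst_d)
    surgery_range <- if (lst_d - stop_d >= 2L) (stop_d + 1L):(lst_d - 1L) else integer(0)
    death_gap <- sample(3:45, 1L)
  }
  if (stats::runif(1) < spec$p_surgery && length(surgery_range)) {
    pos["surgery"] <- if (length(surgery_range) == 1L) surgery_range
                      else sample(surgery_range, 1L)
  }
  if (stats::runif(1) < spec$p_mi) pos["mi"] <- pos[["lst"]]
  if (stats::runif(1) < spec$p_er) pos["er"] <- pos[["lst"]]
  if (stats::runif(1) < spec$p_death) pos["death"] <- pos[["lst"]] + death_gap
  pos["therapy"] <- pos[["ap_start"]]  # interval event, anchored at start

  missing_dur <- stats::runif(1) < spec$p_missing_duration
  range_dur <- !missing_dur && stats::runif(1) < spec$p_range_duration

  type_of <- c(implant = "stent_implantation", ap_start = "antiplatelet_start",
               ap_stop = "antiplatelet_stop", therapy = "antiplatelet_therapy",
               surgery = "unrelated_surgery", lst = "late_stent_thrombosis",
               mi = "myocardial_infarction", er = "er_admission",
               death = "death")
  label_of <- c(implant = "drug-eluting stent implantation",
                ap_start = "antiplatelet therapy started",
                ap_stop = "antiplatelet therapy discontinued",
                therapy = "antiplatelet therapy",
                surgery = "unrelated surgery",
                lst = "late stent thrombosis",
                mi = "myocardial infarction",
                er = "emergency room admission",
                death = "patient death")
  ids <- names(pos)
  events <- lapply(ids, function(id) event(id, type_of[[id]], label_of[[id]]))

  base_year <- sample(2004:2008, 1L)
  base_month <- sample(1:12, 1L)
  base_day <- sample(1:28, 1L)
  stamp_at <- function(p) {
    if (month_grid) {
      s <- shift_months(base_year, base_month, NA_integer_, p)
      timestamp(s$year, s$month)
    } else {
      date_to_ts(ts_to_date(timestamp(base_year, base_month, base_day)) + p)
    }
  }
  off_unit <- if (month_grid) "month" else "day"

  assertions <- list(
    assertion("ap_start", "EQUAL", "implant"),
    assertion("therapy", "STARTS", "ap_start"),
    assertion("therapy", "FINISHES", "ap_stop")
  )
  timestamps <- list()
  durations <- list()

  # the therapy-stop anchor is dropped when the narrative omits duration
  # information; a range annotation likewise fixes nothing exactly
  instants <- setdiff(ids, "therapy")
  anchored <- if (missing_dur || range_dur) setdiff(instants, "ap_stop") else instants

  if (style %in% c("absolute_day", "absolute_month")) {
    for (id in anchored) timestamps[[id]] <- list(start = stamp_at(pos[[id]]))
  } else {
    timestamps[["implant"]] <- list(start = stamp_at(0L))
    chain_ids <- if (style == "explicit_duration") setdiff(anchored, "ap_stop") else anchored
    # chain distinct positions in order; co-located events get EQUAL links
    upos <- sort(unique(pos[chain_ids]))
    groups <- lapply(upos, function(p) chain_ids[pos[chain_ids] == p])
    reps <- vapply(groups, `[[`, character(1), 1L)
    for (g in groups) {
      for (other in g[-1]) {
        if (other == "ap_start" || g[[1]] == "implant") next  # already EQUAL
        assertions[[length(assertions) + 1L]] <-
          assertion(other, "EQUAL", g[[1]])
      }
    }
    if (length(reps) >= 2L) {
      for (i in seq_len(length(reps) - 1L)) {
        gap <- (upos[i + 1L] - upos[i])
        assertions[[length(assertions) + 1L]] <-
          assertion(reps[i], "BEFORE", reps[i + 1L],
                    offset = duration(gap, off_unit))
      }
    }
  }
  if (style == "explicit_duration" && !missing_dur) {
    durations[["therapy"]] <- if (range_dur) {
      duration(stop_m, "month", range_high = stop_m + 1L)
    } else {
      duration(stop_m, "month")
    }
  } else if (range_dur) {
    m <- as.integer(round(pos[["ap_stop"]] * unit_days / 30))
    durations[["therapy"]] <- duration(max(1L, m), "month",
                                       range_high = max(1L, m) + 1L)
  }
  if (missing_dur || range_dur) {
    # order is still partially known: therapy stopped before thrombosis
    assertions[[length(assertions) + 1L]] <-
      assertion("ap_stop", "BEFORE", "lst")
    assertions[[length(assertions) + 1L]] <-
      assertion("implant", "BEFORE", "ap_stop")
  }

  doc <- annotated_document(
    doc_id = doc_id, events = events, assertions = assertions,
    timestamps = timestamps, durations = durations,
    metadata = list(style = style,
                    ambiguous = missing_dur || range_dur,
                    ambiguous_reason = if (missing_dur) "missing therapy duration"
                                       else if (range_dur) "range therapy duration"
                                       else "")
  )
  upos_all <- sort(unique(pos))
  gold <- gold_standard(
    doc_id = doc_id,
    ordered_events = lapply(upos_all, function(p) sort(ids[pos == p])),
    event_durations = list(
      therapy = duration(pos[["ap_stop"]], if (month_grid) "month" else "day")
    ),
    pair_durations = list(
      list(a = "implant", b = "lst",
           duration = duration(pos[["lst"]], if (month_grid) "month" else "day"))
    )
  )
  list(document = doc, gold = gold)
}

#' Simulate a corpus
#'
#' Draws one seed per document up front from `spec$seed` (a counter-based
#' substream: document i is reproducible regardless of evaluation order)
#' and simulates `n_docs` documents. With `out_dir` given, writes
#' `<id>.doc.json`, `<id>.gold.json` and a `manifest.json` recording the
#' spec; otherwise returns the corpus in memory.
#'
#' @param spec A [corpus_spec()].
#' @param out_dir Output directory, or `NULL` for an in-memory corpus.
#' @return Invisibly (on disk) or visibly (in memory): list with
#'   `documents`, `golds`, and `manifest`.
#' @export
simulate_corpus <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  doc_seeds <- sample.int(2147483646L, spec$n_docs)
  pairs <- lapply(seq_len(spec$n_docs), function(i) {
    simulate_document(spec, doc_seeds[i], doc_id = sprintf("SYN-%04d", i))
  })
  manifest <- list(
    generator = "narratime synthetic late-stent-thrombosis corpus",
    n_docs = spec$n_docs,
    seed = spec$seed,
    spec = unclass(spec)[setdiff(names(spec), c("n_docs", "seed"))],
    doc_ids = lapply(pairs, function(p) p$document$doc_id)
  )
  out <- list(documents = lapply(pairs, `[[`, "document"),
              golds = lapply(pairs, `[[`, "gold"),
              manifest = manifest)
  if (is.null(out_dir)) return(out)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (p in pairs) {
    write_document(p$document, file.path(out_dir, paste0(p$document$doc_id, ".doc.json")))
    write_gold(p$gold, file.path(out_dir, paste0(p$gold$doc_id, ".gold.json")))
  }
  write_canonical_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(out)
}
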