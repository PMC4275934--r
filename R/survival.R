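# Downstream survival-trend demonstration: group narratives by
# antiplatelet-therapy duration and compare time from implantation to late
# stent thrombosis with the Kaplan-Meier product-limit estimator and the
# log-rank test. Both statistics are implemented from their standard
# formulas so the demonstration is dependency-light and bit-reproducible;
# the test suite cross-checks them against the survival package.

#' Extract the survival analysis table from a reasoned corpus
#'
#' One record per document in which BOTH the antiplatelet-therapy duration
#' and the implantation-to-thrombosis interval resolve at month
#' granularity; narratives that do not fix the therapy duration are
#' excluded, mirroring the published analysis. Therapy shorter than the
#' threshold puts a record in the `shorter` group; at or above it, in
#' `longer`. Every record is an observed event (adverse-event reports all
#' end in thrombosis; no censoring).
#'
#' @param corpus List of `annotated_document` (e.g.
#'   `simulate_corpus(spec)$documents`) or a directory of `*.doc.json`
#'   files.
#' @param threshold_months Group cut point (default 6, the guideline
#'   duration).
#' @param axioms,config Reasoning options; defaults are the study axioms.
#' @return Data frame with columns `doc_id`, `therapy_duration_months`,
#'   `time_to_lst_months`, `event_observed`, `group`.
#' @export
extract_survival_table <- function(corpus, threshold_months = 6,
                                   axioms = study_axioms(),
                                   config = reasoner_config()) {
  if (is.character(corpus)) {
    corpus <- lapply(sort(list.files(corpus, pattern = "\\.doc\\.json$",
                                     full.names = TRUE)), read_document)
  }
  rows <- list()
  for (doc in corpus) {
    types <- vapply(doc$events, function(e) e$event_type, character(1))
    ids <- event_ids(doc)
    implant <- ids[types == "stent_implantation"][1]
    lst <- ids[types == "late_stent_thrombosis"][1]
    therapy <- ids[types == "antiplatelet_therapy"][1]
    if (is.na(implant) || is.na(lst)) next
    graph <- build_graph(doc, axioms = axioms, config = config)
    therapy_m <- tryCatch({
      if (!is.na(therapy)) {
        event_duration(graph, therapy, "month")$magnitude
      } else {
        start_ev <- ids[types == "antiplatelet_start"][1]
        stop_ev <- ids[types == "antiplatelet_stop"][1]
        if (is.na(start_ev) || is.na(stop_ev)) NA_real_
        else duration_between(graph, start_ev, stop_ev, "month")$magnitude
      }
    }, narratime_error = function(e) NA_real_)
    lst_m <- tryCatch(duration_between(graph, implant, lst, "month")$magnitude,
                      narratime_error = function(e) NA_real_)
    if (is.na(therapy_m) || is.na(lst_m)) next
    rows[[length(rows) + 1L]] <- data.frame(
      doc_id = doc$doc_id,
      therapy_duration_months = therapy_m,
      time_to_lst_months = lst_m,
      event_observed = TRUE,
      group = if (therapy_m < threshold_months) "shorter" else "longer",
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(doc_id = character(0),
                      therapy_duration_months = numeric(0),
                      time_to_lst_months = numeric(0),
                      event_observed = logical(0),
                      group = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Kaplan-Meier product-limit estimator
#'
#' With no censoring the estimator equals the empirical survival function
#' exactly. The reported median is the smallest time at which survival
#' drops to 0.5 or below (`NA` if survival never reaches 0.5).
#'
#' @param times Positive event/censoring times.
#' @param observed Logical; `TRUE` for an observed event, `FALSE` for
#'   censoring. Defaults to all observed.
#' @return A `km_fit`: list with `steps` (data frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`) and `median`.
#' @export
km_estimate <- function(times, observed = rep(TRUE, length(times))) {
  if (!length(times)) stop_narratime("empty_input", "no survival times")
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop_narratime("invalid_argument", "times must be positive and finite")
  }
  if (length(observed) != length(times)) {
    stop_narratime("invalid_argument", "times and observed lengths differ")
  }
  ut <- sort(unique(times))
  n <- length(times)
  surv <- 1
  steps <- data.frame(time = ut, n_risk = NA_real_, n_event = NA_real_,
                      n_censor = NA_real_, survival = NA_real_)
  for (i in seq_along(ut)) {
    t <- ut[i]
    at_risk <- sum(times >= t)
    d <- sum(times == t & observed)
    c_ <- sum(times == t & !observed)
    if (at_risk > 0 && d > 0) surv <- surv * (1 - d / at_risk)
    steps[i, ] <- c(t, at_risk, d, c_, surv)
  }
  med <- steps$time[steps$survival <= 0.5 + 1e-12]
  structure(
    list(steps = steps, median = if (length(med)) med[1] else NA_real_,
         n = n),
    class = "km_fit"
  )
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<Kaplan-Meier fit: n = %d, median = %s>\n", x$n,
              if (is.na(x$median)) "not reached" else format(x$median)))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Log-rank test for two survival curves
#'
#' Standard observed-minus-expected chi-square on one degree of freedom:
#' at each distinct event time the expected group-1 event count under the
#' null is `d * n1 / n` with hypergeometric variance
#' `d (n1/n)(1 - n1/n)(n - d)/(n - 1)`. Identical groups give statistic 0
#' and p = 1; relabelling the groups leaves the statistic unchanged.
#'
#' @param times1,times2 Event times of the two groups (both non-empty).
#' @param observed1,observed2 Optional censoring indicators.
#' @return A `logrank_test`: list with `statistic`, `p_value`, `observed`,
#'   `expected` (group-1 counts), `df`.
#' @export
logrank_test <- function(times1, times2,
                         observed1 = rep(TRUE, length(times1)),
                         observed2 = rep(TRUE, length(times2))) {
  if (!length(times1) || !length(times2)) {
    stop_narratime("empty_input", "both groups must be non-empty")
  }
  times <- c(times1, times2)
  observed <- c(observed1, observed2)
  grp1 <- rep(c(TRUE, FALSE), c(length(times1), length(times2)))
  event_times <- sort(unique(times[observed]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in event_times) {
    n_at <- sum(times >= t)
    n1_at <- sum(times >= t & grp1)
    d <- sum(times == t & observed)
    d1 <- sum(times == t & observed & grp1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1_at / n_at
    if (n_at > 1) {
      V <- V + d * (n1_at / n_at) * (1 - n1_at / n_at) * (n_at - d) / (n_at - 1)
    }
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  structure(
    list(statistic = stat,
         p_value = if (V > 0) stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1,
         observed = O1, expected = E1, variance = V, df = 1L),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("<log-rank test: chi-square = %.4f (1 df), p = %.4g>\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Compare time-to-thrombosis between therapy-duration groups
#'
#' Convenience wrapper around [extract_survival_table()],
#' [km_estimate()] and [logrank_test()]: fits one Kaplan-Meier curve per
#' group and tests the difference.
#'
#' @param corpus Documents (or directory) as in
#'   [extract_survival_table()], or an already-extracted records data
#'   frame.
#' @param threshold_months Group cut point.
#' @param ... Passed to [extract_survival_table()].
#' @return A `survival_comparison`: list with `records`, `km` (named list
#'   `shorter`/`longer`), `test`, `threshold_months`.
#' @export
compare_therapy_groups <- function(corpus, threshold_months = 6, ...) {
  records <- if (is.data.frame(corpus)) corpus
             else extract_survival_table(corpus, threshold_months, ...)
  shorter <- records$time_to_lst_months[records$group == "shorter"]
  longer <- records$time_to_lst_months[records$group == "longer"]
  if (!length(shorter) || !length(longer)) {
    stop_narratime("empty_input",
                   "need at least one record in each therapy-duration group")
  }
  structure(
    list(records = records,
         km = list(shorter = km_estimate(shorter), longer = km_estimate(longer)),
         test = logrank_test(shorter, longer),
         threshold_months = threshold_months),
    class = "survival_comparison"
  )
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("<therapy-duration survival comparison (threshold %g months)>\n",
              x$threshold_months))
  cat(sprintf("  shorter therapy: n = %d, median time to LST = %s months\n",
              x$km$shorter$n, format(x$km$shorter$median)))
  cat(sprintf("  longer therapy:  n = %d, median time to LST = %s months\n",
              x$km$longer$n, format(x$km$longer$median)))
  cat(sprintf("  log-rank: chi-square = %.3f, p = %.4g\n",
              x$test$statistic, x$test$p_value))
  invisible(x)
}

#' Write a survival comparison as TSV + JSON summary
#'
#' Writes the per-group step functions to `<path>` (TSV) and, when
#' `json_path` is given, a JSON summary with group sizes, medians, and the
#' log-rank result.
#'
#' @param cmp A `survival_comparison`.
#' @param path TSV output path.
#' @param json_path Optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_survival_tsv <- function(cmp, path, json_path = NULL) {
  stopifnot(inherits(cmp, "survival_comparison"))
  tab <- do.call(rbind, lapply(names(cmp$km), function(g) {
    cbind(group = g, cmp$km[[g]]$steps)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    write_canonical_json(list(
      threshold_months = cmp$threshold_months,
      n = list(shorter = cmp$km$shorter$n, longer = cmp$km$longer$n),
      median_months = list(shorter = cmp$km$shorter$median,
                           longer = cmp$km$longer$median),
      logrank = list(statistic = cmp$test$statistic,
                     p_value = cmp$test$p_value)
    ), json_path)
  }
  invisible(path)
}
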