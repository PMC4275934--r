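test_that("the product-limit estimator matches hand computations", {
  fit <- km_estimate(c(5, 5, 5))
  expect_equal(fit$steps$survival, 0)
  expect_equal(fit$median, 5)
  fit <- km_estimate(c(1, 2, 3, 4))
  expect_equal(fit$steps$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(fit$steps$survival[fit$steps$time == 2], 0.5)
  expect_equal(fit$median, 2)
  # no censoring: the estimator is the empirical survival function
  set.seed(1)
  times <- sample(1:20, 30, replace = TRUE)
  fit <- km_estimate(times)
  for (i in seq_len(nrow(fit$steps))) {
    expect_equal(fit$steps$survival[i], mean(times > fit$steps$time[i]))
  }
  # monotone non-increasing even with censoring
  fit <- km_estimate(c(1, 2, 2, 3, 7, 9), observed = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_true(all(diff(fit$steps$survival) <= 1e-12))
  expect_error(km_estimate(numeric(0)), class = "narratime_empty_input")
  expect_error(km_estimate(c(1, -2)), class = "narratime_invalid_argument")
})

test_that("the log-rank test matches the hand-computed risk table", {
  # {1,2,3} vs {10,20,30}: O1 = 3, E1 = 1/2 + 2/5 + 1/4, V = 1/4 + 6/25 + 3/16
  res <- logrank_test(c(1, 2, 3), c(10, 20, 30))
  E1 <- 1 / 2 + 2 / 5 + 1 / 4
  V <- (1 / 2) * (1 / 2) + (2 / 5) * (3 / 5) + (1 / 4) * (3 / 4)
  expect_equal(res$statistic, (3 - E1)^2 / V)
  expect_equal(res$p_value, pchisq((3 - E1)^2 / V, 1, lower.tail = FALSE))
  # identical groups: statistic 0, p = 1
  res <- logrank_test(c(2, 4, 9), c(2, 4, 9))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # invariant under group relabelling
  set.seed(2)
  a <- rexp(15, 1 / 10); b <- rexp(20, 1 / 20)
  expect_equal(logrank_test(a, b)$statistic, logrank_test(b, a)$statistic)
  expect_error(logrank_test(numeric(0), 1), class = "narratime_empty_input")
})

test_that("KM and log-rank agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(123)
  for (i in 1:20) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    t1 <- round(rexp(n1, 1 / 12) + 1); t2 <- round(rexp(n2, 1 / 20) + 1)
    fit <- km_estimate(c(t1, t2))
    sf <- survival::survfit(survival::Surv(c(t1, t2), rep(1, n1 + n2)) ~ 1)
    expect_equal(fit$steps$survival, sf$surv, tolerance = 1e-12)
    sd_ <- survival::survdiff(
      survival::Surv(c(t1, t2), rep(1, n1 + n2)) ~ rep(1:2, c(n1, n2)))
    res <- logrank_test(t1, t2)
    expect_equal(res$statistic, sd_$chisq, tolerance = 1e-12)
    expect_equal(res$p_value, pchisq(sd_$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("survival records are extracted and grouped at the threshold", {
  mk <- function(id, therapy_m, lst_m) {
    annotated_document(id,
      events = list(event("implant", "stent_implantation"),
                    event("therapy", "antiplatelet_therapy"),
                    event("lst", "late_stent_thrombosis")),
      assertions = list(
        assertion("therapy", "STARTS", "implant"),
        assertion("implant", "BEFORE", "lst", offset = duration(lst_m, "month"))),
      timestamps = list(implant = list(start = timestamp(2006, 1))),
      durations = list(therapy = duration(therapy_m, "month")))
  }
  docs <- list(mk("A", 2, 14), mk("B", 6, 20), mk("C", 9, 30))
  tab <- extract_survival_table(docs)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$group, c("shorter", "longer", "longer"))  # exactly 6 = longer
  expect_equal(tab$time_to_lst_months, c(14, 20, 30))
  expect_true(all(tab$event_observed))
  # unresolvable therapy duration excludes the document
  bad <- mk("D", 2, 14)
  bad$durations <- list()
  tab <- extract_survival_table(c(docs, list(bad)))
  expect_equal(nrow(tab), 3)
})

test_that("a true group effect is detected while no effect is not overcalled", {
  run_p <- function(effect, seed) {
    spec <- corpus_spec(n_docs = 60, seed = seed,
                        lst_therapy_effect = effect,
                        p_missing_duration = 0, p_range_duration = 0)
    corp <- simulate_corpus(spec)
    compare_therapy_groups(corp$documents)$test$p_value
  }
  p_eff <- vapply(1:5, function(s) run_p(1.0, 1000 + s), numeric(1))
  p_null <- vapply(1:5, function(s) run_p(0.0, 2000 + s), numeric(1))
  expect_gte(sum(p_eff < 0.05), 4)   # strong effect: nearly always detected
  expect_lte(sum(p_null < 0.05), 2)  # null: rarely rejected
})

test_that("the group comparison reproduces the qualitative therapy pattern", {
  spec <- corpus_spec(n_docs = 120, seed = 77,
                      p_missing_duration = 0, p_range_duration = 0)
  corp <- simulate_corpus(spec)
  cmp <- compare_therapy_groups(corp$documents)
  expect_gt(cmp$km$longer$median, cmp$km$shorter$median)
  expect_lt(cmp$test$p_value, 0.05)
  p <- withr::local_tempfile(fileext = ".tsv")
  pj <- withr::local_tempfile(fileext = ".json")
  write_survival_tsv(cmp, p, json_path = pj)
  expect_true(all(c("group", "time", "survival") %in%
                    names(utils::read.delim(p))))
  js <- jsonlite::fromJSON(pj)
  expect_equal(js$logrank$p_value, cmp$test$p_value)
})
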