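---
title: "Temporal reasoning over annotated adverse-event narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal reasoning over annotated adverse-event narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(narratime)
```

## The problem

Adverse-event report narratives describe a patient's clinical course —
stent implantation, antiplatelet therapy, an unrelated surgery, late stent
thrombosis, sometimes death — with temporal information that is partial,
relative, and expressed at mixed granularities: "May 2006", "for two
months", "60 days after stent implantation", "the day before surgery".
`narratime` takes *annotated* versions of such narratives (events plus
temporal assertions, timestamps, and durations) and recovers what the text
implies but does not state: the order of events, missing timestamps, and
the durations of and between events. This vignette documents the reasoning
semantics, the numerical conventions, the design decisions that were
genuinely open, and what the shipped synthetic corpus does and does not
demonstrate.

## Point-based reasoning semantics

Every event contributes two points, its start and its end, with
`start <= end`. Assertions compile to point constraints:

| assertion | point constraints |
|---|---|
| `a BEFORE b` | `end(a) < start(b)` |
| `a BEFORE b` with offset `d` | `start(b) = end(a) + d` (exact) |
| `a EQUAL b` | `start(a) = start(b)`, `end(a) = end(b)` |
| `a STARTS b` | `start(a) = start(b)` |
| `a FINISHES b` | `end(a) = end(b)` |
| `a DURING b` | `start(b) <= start(a)`, `end(a) <= end(b)` |
| duration `d` annotated on `a` | `end(a) = start(a) + d` |

This reformulation makes relation inference a reachability problem: the
closure is computed by a Warshall sweep over boolean "at-or-before" and
"strictly-before" matrices, consistency is the absence of a strict cycle
(reported with a witness cycle), and every derived BEFORE automatically
emits its AFTER twin. The brute-force transparency of this formulation is
deliberate — the test suite checks the closure against an independent
reachability oracle (igraph shortest-path reachability over an
independently compiled arc list) on a thousand random interval
configurations, and duration chaining against latent ground-truth distances
on hundreds of random offset graphs.

STARTS and FINISHES are interpreted purely as start-point (end-point)
coincidence, which makes them symmetric; CONTAINS/DURING are accepted as an
interval-containment extension beyond the relations the annotation scheme
itself exercises.

Timestamps attach to points and are propagated to a fixpoint: equality
edges copy stamps, offset edges apply calendar arithmetic in either
direction. Points are only ever assigned, never reassigned, so propagation
terminates; two derivations that disagree when compared at their common
granularity raise a timestamp-conflict error rather than being silently
averaged.

## Granularity conventions

Granularity (minute < hour < day < month < year) is an explicit field of
every timestamp and duration, and three conventions govern all arithmetic.
These are package choices — the annotation scheme itself does not fix a
day/month conversion — made once and used everywhere:

* **Conversion constants.** 1 year = 12 months, 1 month = 30 days, 1 day =
  24 hours, 1 hour = 60 minutes. Converting to a coarser unit rounds to the
  nearest integer, ties up (60 days → 2 months, 45 days → 2 months). The
  30-day month suits a corpus analyzed at month granularity; it would bias
  year-scale day counts (365 vs 360 days), which is why durations reported
  in years are converted through the 12-month factor, never through days.
* **Result granularity of addition.** `add_duration` returns the coarser of
  the stamp's granularity and the duration's unit, converting the magnitude
  first: adding 60 days to "2006-05" gives "2006-07", adding 1 day to
  "2006-07" gives "2006-07" again. Precision is never invented, and
  fine-grained offsets correctly vanish against coarse stamps — this is
  exactly what makes "therapy stopped the day before a July 2006 surgery"
  resolve to a May–July span of 2 months. The price is that a month-unit
  addition to a day-granularity stamp coarsens it to months, so the
  day-of-month clamping convention (Jan 31 + 1 month = Feb 28/29) only
  matters inside the internal month-shift helper.
* **Calendar model.** Proleptic Gregorian via base R's `Date`/`POSIXct`
  (UTC); day and sub-day arithmetic is exact, leap years included.

A temporal relation may carry its own granularity: "event1 before event2 at
day granularity" means the comparison was made at day level, i.e. the two
events fell on the same day. With `granular_relations = TRUE` (the
default), such a pair contributes a zero offset *at that granularity* to
duration chains and copies granularity-truncated timestamps — so a 183-day
offset downstream of such a pair yields a 183-day answer. The zero
contribution is only sound at the relation's granularity or coarser;
requesting a finer output unit raises an insufficient-precision error. Set
`granular_relations = FALSE` to treat such relations as pure order
statements.

Duration *ranges* ("2-3 months") are representable and round-trip through
the JSON format, but are excluded from all arithmetic: a range is reported
as insufficient precision, never resolved to its midpoint. Compound
mixed-granularity expressions ("two months and ten days") are likewise
flagged by the normalizer rather than guessed, with an opt-in
(`resolve_mixed = TRUE`) that converts to the finer unit under the 30-day
convention.

## Duration resolution order

`event_duration(graph, e)` tries, in order: (1) an explicit duration
annotation; (2) the difference of the event's (propagated) start and end
timestamps at their coarser common granularity; (3) summing exact offsets
along simple paths from `start(e)` to `end(e)` through related events.
`duration_between(graph, a, b)` differences the two start timestamps when
both are known, and otherwise path-sums between the start points. All
simple paths must agree at the requested output unit; disagreement is an
`inconsistent offsets` error, never an average — when annotations
contradict each other the right output is a complaint, not a compromise.

Events with no duration annotation are treated as zero-width when a chain
merely passes *through* them (point events dominate this corpus: an
implantation or an ER admission has no meaningful extent at the working
granularities). An event's own width is never defaulted to zero when it is
itself the query — `event_duration` excludes that arc, so an unannotated
event with no other evidence is honestly unresolvable rather than zero.

## Background axioms

Two pieces of domain knowledge that narratives leave implicit can be
injected per run (`axiom_set()`; both off by default, since they are
corpus-specific): `death_last` constrains every other event to end at or
before each death event's start, and `instantaneous_event_types` collapses
the start and end points of procedure-like events (an implantation cannot
span months). `study_axioms()` bundles the configuration used for the
stent-thrombosis corpus: death last, and every event type except the
antiplatelet-therapy interval instantaneous.

## Timeline buckets

`sort_timeline` merges events into simultaneity classes at a working
granularity (default: the coarsest granularity appearing in the document's
timestamps) and orders the classes. Simultaneity and order are computed on
event *start* points — occurrence-time semantics. For instantaneous events
this coincides with full-interval equality; for the one extended event type
it places the therapy interval in the bucket where it began, which is also
how gold-standard timelines record it. A document whose events cannot be
totally ordered yields a result flagged `total_order = FALSE` with the
incomparable pairs listed; the evaluator scores such documents as not
strictly ordered rather than forcing a guess. Ties in reporting are broken
by event id, so output is deterministic.

## Evaluation measures

`evaluate_corpus` reproduces three accuracy measures over a corpus with
gold standards: the fraction of documents whose entire bucket sequence is
exactly right (strict ordering — one wrong document costs the whole
document), and exact-match fractions for single-event durations and
between-event durations at the working unit (month), where an unresolvable
prediction counts as incorrect. A pairwise ordering fraction is reported
per document as a softer diagnostic; strict correctness implies pairwise
1.0. The strict reading is the primary metric because gold standards record
full manual orderings; whether partially-ordered outputs should ever score
as correct is genuinely debatable, so both numbers are exposed and the
strict one is used for the headline rate.

## The synthetic corpus

The original 238 MAUDE narratives are not redistributable, so
`simulate_corpus` generates annotation documents with the same shape and
exact ground truth. Each document samples a latent timeline — implant (day
0), therapy starting at implant, therapy stop, optional unrelated surgery
strictly between stop and thrombosis, late stent thrombosis, optional
MI/ER admission at the thrombosis date, optional death last — and renders
it in one of five expression styles (absolute day or month timestamps,
day or month offset chains, explicit therapy-duration annotation), so
granularity-truncation effects arise naturally. Default parameters are
fixed once as the package's model of the published case mix, not tunable
toward any test outcome:

* therapy duration ~ lognormal(meanlog = log 6, sdlog = 0.6) months —
  median at the 6-month guideline boundary, so both therapy groups are
  populated;
* implant-to-thrombosis interval ~ lognormal(meanlog = log 14.6,
  sdlog = 0.45) months, shifted by `lst_therapy_effect = 0.6` on the log
  scale when therapy reaches 6 months. The defaults reproduce the
  qualitative published pattern (short-therapy median near 15 months,
  long-therapy near twice that); the effect knob exists so power
  properties can be tested against a known truth, including zero;
* optional-event probabilities (surgery 0.35, MI 0.30, ER 0.40, death
  0.12) chosen as plausible report rates; the reasoning accuracy is
  insensitive to them, they control timeline length;
* 15% of documents omit the information fixing the therapy stop
  (narratives without a therapy duration existed and were excluded from
  the published survival analysis) and 5% report it only as a range. Both
  renderings provably under-determine the document and are flagged
  `metadata$ambiguous`.

Month-style documents sample their latent timeline in whole months (a
30-day grid) and day-style documents in days, so an unambiguous rendering
is always exactly recoverable: on a corpus generated with the ambiguity
rates at zero, the reasoner achieves 100% on all three measures, which is a
*generator-correctness* property (rendering loses nothing the reasoner
cannot recover), not evidence about real narratives. What the synthetic
corpus does not emulate: free-text noise, annotation errors, unannotated
intermediate events (a published failure mode of long chains),
inter-annotator disagreement, and MAUDE reporting biases. Accuracy numbers
on it therefore validate the machinery, not the difficulty of the real
task.

Reproducibility: the corpus seed drives one `sample.int` draw of per-
document seeds, and each document is simulated from its own seed, so
document *i* is identical whether generated alone or in a full corpus run.

## Survival demonstration

`extract_survival_table` keeps the documents where both the therapy
duration and the implant-to-thrombosis interval resolve at month
granularity, groups them at a 6-month threshold (less than 6 months =
shorter; 6 or more = longer), and `compare_therapy_groups` fits one
Kaplan–Meier curve per group and runs the log-rank test. Every record is an
observed event — adverse-event reports all end in thrombosis, so there is
no censoring, and the product-limit estimator reduces to the empirical
survival function (the implementation still supports censoring flags). The
reported median is the smallest time at which survival reaches 0.5 or
below; with an even number of uncensored observations this is the lower of
the two middle values, a convention chosen for its step-function
naturalness and stated here because other software sometimes interpolates.
Both statistics are implemented from their standard formulas (product-limit
factors `1 - d/n`; observed-minus-expected with hypergeometric variance)
and are cross-checked against `survival::survfit`/`survdiff` to 1e-9 in the
tests. The published group medians and p-value depended on the original
narrative subset and are not reproduction targets; the shipped defaults
exhibit the same qualitative pattern.

## Degenerate inputs and numerical choices

* Empty documents, single events, and graphs with no timestamps are all
  valid; propagation is a no-op and a single event sorts into one bucket.
* Inconsistent assertions (strict cycles, conflicting timestamps,
  disagreeing offset paths) raise classed errors with a witness, and
  `check_consistency` reports them without throwing.
* Unrecognized temporal expressions are values (`kind = "unsupported"`
  with a note), never exceptions, so ingestion is total; calendar-invalid
  dates ("2006-02-30") are rejected the same way.
* Slash dates default to the US month-first reading (the source database
  is a US registry); a `dialect` flag switches to day-first.
* Number words are supported zero through twelve, covering the
  expressions that occur in this domain without a full number grammar.
* Path search enumerates simple paths with depth capped at the number of
  points; documents here have at most a dozen events, far below anything
  that would make this costly.

## Problem sizes used in the shipped checks

The test suite validates closure on 1,000 random documents of up to 8
events, duration chaining on 500 random offset graphs, exact recovery on a
238-document unambiguous corpus, and the survival statistics on 100 random
datasets against the survival package — sizes chosen to give the oracles
dense coverage of the small-document regime this tool actually operates in
(adverse-event narratives rarely annotate more than a handful of events).

## Known limitations

* No uncertainty or probabilistic reasoning: ambiguity is surfaced, not
  resolved.
* No disjunctive constraints and no full 13-relation interval composition
  table; the point compilation covers the relations the annotation scheme
  uses.
* Relative expressions anchored to document time ("next Friday") and
  non-English text are out of scope for the normalizer.
* Turtle export is a one-way interoperability surface (one triple per
  assertion); offsets and relation granularities live only in the JSON
  format.
* Time zones and sub-minute granularity are unsupported.
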