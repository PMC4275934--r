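Package: narratime
Title: Temporal Reasoning over Annotated Clinical Adverse-Event Narratives
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A timeline reasoning toolkit for annotated clinical
    adverse-event narratives. Normalizes free-text temporal expressions
    into granularity-aware timestamps and durations, compiles annotated
    temporal relations into a point-based constraint graph, infers new
    relations and timestamps by constraint propagation, computes event
    durations and between-event durations by iterative chaining through
    intermediate events, sorts events into ordered timeline buckets, and
    scores results against gold standards. Ships a seeded generator of
    synthetic late-stent-thrombosis annotation documents with exact
    ground truth, and a downstream survival-trend demonstration
    (Kaplan-Meier estimation and the log-rank test) comparing
    time-to-thrombosis between antiplatelet-therapy duration groups.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
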