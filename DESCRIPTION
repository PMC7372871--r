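Package: chainlog
Title: Immutable Audit-Log Indexing and Querying over Append-Only Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stores genomic data-access audit events in an append-only
    key-value stream ledger and queries them efficiently. Each log record is
    written under a two-level index: a data stream maps unique record
    identifiers to the full record payload, and one stream per column maps
    column values back to record identifiers, with an additional per-node
    ordering stream keyed by timestamp. The query engine supports single
    column=value clauses in time proportional to the result size, conjunctive
    clauses via a minimum-cardinality candidate-set heuristic, and inclusive
    timestamp-range queries via binary search over the per-node ordering
    streams, plus stable sorting by any column. Includes an in-memory
    reference ledger backend, a seeded synthetic log-file generator, a
    brute-force oracle, and an equivalence/instrumentation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
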