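---
title: "Indexing and querying immutable audit logs on an append-only stream ledger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing and querying immutable audit logs on an append-only stream ledger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainlog)
```

## The problem

When genomic datasets such as GTEx are shared across sites, every access
event — who touched which resource, from which node, when — should land in a
tamper-evident audit trail. Permissioned ledgers give immutability cheaply,
but they are not databases: the store exposes only named append-only
*streams* of key/value items, with per-key item lists, cached per-key counts,
and positional access in publish order. There is no secondary index, no set
intersection, and no ordering primitive. `chainlog` implements an insertion
scheme and query engine that work entirely within that contract, against an
in-memory reference backend that reproduces it exactly (a live-ledger adapter
can be slotted behind the same functions).

An access event is one log line with seven whitespace-separated fields:

```
timestamp node id ref-id user activity resource
1522000126703 2 28 17 3 FILE_ACCESS GTEx
```

`timestamp` is milliseconds since epoch; `node` is the originating site;
`id` is the per-node record number; `ref-id` and `user` are integers;
`activity` and `resource` are free tokens. `(node, id)` is unique, giving
each record the identifier `UID_<node>_<id>`.

## The two-level index

Inserting one record publishes exactly nine entries, atomically:

```{r}
index_entries(parse_log_line("1522000126703 2 28 17 3 FILE_ACCESS GTEx"))
```

Level two is the `logdata` stream, mapping the UID to the full JSON payload.
Level one is one stream per column, mapping `<COLUMN>_<value>` keys back to
UIDs. The ninth entry goes to the record's `node<X>timestamps` ordering
stream, keyed by the decimal timestamp with the UID as value; since each
node's insertions are monotone in timestamp, positional access over that
stream enumerates the node's records in time order.

Storage is therefore linear and deterministic: a ledger built from *N*
records holds exactly *9N* entries.

## The three query modalities

Queries use the dialect
`QUERY col=val ... [timestamprange=[lo,hi]] [sortby=Col]`. With *n* inserted
records and *m* results:

* **Single clause** — one key lookup on the column's index stream yields the
  matching UIDs; each is fetched from `logdata`. Cost O(*m*), independent
  of *n*.
* **Conjunction** — the result is the intersection of the clauses' UID sets,
  but the store has no intersection primitive, and fetching every set to
  intersect locally retrieves data that is mostly thrown away. Instead the
  planner reads only the *cached counts* of each clause key and fetches the
  minimum-cardinality candidate set S_i, of which the result is necessarily a
  subset; every candidate is then validated against all clauses and
  non-matches are discarded. Cost O(|S_i|). A zero-count clause
  short-circuits: nothing is fetched. Count ties break by the fixed column
  order `timestamp, node, id, ref-id, user, activity, resource`, so the plan
  (and the fetch statistics) are reproducible.
* **Timestamp range** — for each node, binary search over the ordering
  stream finds the leftmost position with timestamp ≥ lo and one past the
  rightmost with timestamp ≤ hi, in at most 2(⌊log₂ n⌋ + 1) positional reads
  per boundary even with repeated timestamps. Without clauses, exactly the
  records in the positional windows are fetched. With clauses, the
  minimum-cardinality clause's candidates are pruned against each node's
  window *before* any record fetch: by membership in the window's UID set
  when the window is smaller than the candidate set, otherwise by comparing
  the candidate's id with the ids at the window boundaries (valid because
  per-node ids increase with insertion). Cost O(max(*m*, |S_i|) + log *n*).

Every path fills a `fetch_stats` counter set (`stream_calls`,
`uid_candidates`, `records_fetched`, `records_discarded`), which is how the
cost claims above are asserted in the test suite rather than merely stated.
Sorting (`sortby=`) is ascending and stable, numeric for the five integer
columns and byte-lexicographic (C locale) for tokens; it is applied after
retrieval to the assembled result list.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `lines_per_node` | — | records generated per node |
| `n_nodes` | 4 | nodes / ordering streams |
| `start_timestamp` | 1522000000000 ms | first timestamp per node |
| `max_step_ms` | 1000 ms | max gap between a node's consecutive records |
| `duplicate_ts_prob` | 0.2 | chance a record repeats its predecessor's timestamp |
| `n_users`, `n_ref_ids` | 10, 100 | integer value pools (`1..k`) |
| `n_activities`, `n_resources` | 5, 4 | token pools (`activityA…`, `resA…`) |
| `throttle` (insert) | off | records/s/node pacing for live deployments |

The pool sizes mirror the scale of the challenge-style queries
(`activity=activityE`, `resource=resD`, `user=5`); with 2,000 lines per node
they put single-clause cardinalities in the hundreds-to-thousands range, so
the conjunctive heuristic is exercised with both near-empty and large
candidate sets. `duplicate_ts_prob` defaults to 0.2 because repeated
timestamps are the regression that most easily breaks naïve range
boundaries; the binary-search tests push it to 0.35–0.5.

## What the generator emulates — and what it does not

`generate_dataset()` reproduces the structural guarantees the engine relies
on: per-node non-decreasing timestamps with configurable duplication,
per-node ids counting from 0 in insertion order (so id order coincides with
time order — the invariant the range pruning exploits), and uniform draws
from fixed value pools. The same spec and seed reproduce the dataset and its
rendered log files byte for byte; the documented standard fixture is
4 nodes × 2,000 lines at seed `standard_fixture_seed()`.

It deliberately does **not** model realistic access patterns: no burstiness,
user sessions, skewed value frequencies, or cross-node clock offsets.
Passing tests therefore demonstrate correctness of the index and planner
under the stated structural assumptions, not performance on production
traffic — in particular, uniform pools understate the discard penalty that
heavily skewed real columns can produce (two popular values with a tiny
joint occurrence). The adversarial fixture in the oracle tests constructs
exactly that worst case to pin down the behaviour: discards equal
|S_i| − m.

## Numerical and design choices

* **Timestamps** are stored as doubles: 13-digit millisecond values are well
  inside the 2^53 exact-integer range, and rendering uses `%.0f` so no
  scientific notation ever reaches a key or log line.
* **Range endpoints are inclusive**, matching the `[lo,hi]` bracket
  notation; `lo > hi` is well-formed and returns an empty result rather than
  an error. Both conventions are applied identically in the engine and the
  brute-force oracle.
* **Insertion verifies instead of trusting**: per-node timestamp
  monotonicity, strictly increasing per-node ids, and UID uniqueness are
  enforced at `insert_record()` time, failing fast rather than silently
  corrupting the binary-search precondition. Id *gaps* are tolerated —
  pruning compares against ids read back from boundary positions, never id
  arithmetic.
* **Default result order** (no `sortby`) is nodes ascending, insertion order
  within a node — a deterministic choice made for testability; the dialect
  itself does not specify one. A `timestamp` equality clause may coexist
  with a range; both are applied.
* **Payloads** are strict JSON with the seven keys in fixed order; the
  reader also accepts the unquoted shorthand `{timestamp:...,activity:FILE_ACCESS,...}`
  seen in ledger dumps, and tokens are assumed whitespace/comma-free (the
  generator only emits such tokens).
* **Record fetches are sequential.** A thread-pool fetch is a recognised
  optimisation on a networked ledger, but it cannot change observable output
  (results are order-normalised), and against the in-memory backend it
  would only add overhead, so the reference engine keeps a single worker.

## Problem sizes used in the checks

The shipped test suite and `scripts/acceptance.R` run the standard fixture
(4 nodes × 2,000 records, duplicate-timestamp probability 0.2) with 57
seeded nine-query suites — 513 queries spanning the three modalities and
sorting — comparing the engine against the brute-force oracle, plus
boundary-search instrumentation on streams of sizes 1, 2, 1,000 and 2,000
and storage-linearity checks at N ∈ {0, 1, 400, 8,000}. These sizes were
chosen so the whole validation runs comfortably on a laptop while still
exercising multi-node windows, duplicate-timestamp boundaries, and non-empty
discard histograms.

## Known limitations

* The backend is a single-process reference implementation: no consensus,
  permissioning, replication, or chain reorganisation; it has one ordering,
  so any divergence between a real ledger's local and global orderings is
  out of scope.
* Only equality clauses, one inclusive timestamp range, and ascending
  single-column sorting are supported — no OR, negation, inequality on other
  columns, or pagination.
* The conjunctive heuristic's cost is bounded by the smallest clause
  cardinality, not the result size; adversarially correlated columns make it
  fetch-and-discard heavily. Multidimensional key interleaving (Z-ordering)
  could address this under tighter value-domain constraints and is left as
  future work.
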