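test_that("the challenge query dialect parses, case-insensitively", {
  q1 <- parse_query("QUERY user=5")
  expect_equal(q1$clauses, list(user = 5))
  expect_null(q1$ts_range)
  expect_null(q1$sort_by)

  q2 <- parse_query("QUERY resource=resD activity=activityE")
  expect_equal(q2$clauses, list(resource = "resD", activity = "activityE"))

  q3 <- parse_query("QUERY user=6 timestamprange=[32226847,82574461] sortby=Ref-ID")
  expect_equal(q3$clauses, list(user = 6))
  expect_equal(q3$ts_range, c(32226847, 82574461))
  expect_equal(q3$sort_by, "ref-id")

  q4 <- parse_query("QUERY timestamprange=[99171676,102561181]")
  expect_equal(q4$ts_range, c(99171676, 102561181))
  expect_length(q4$clauses, 0L)
})

test_that("malformed queries raise parse errors", {
  expect_error(parse_query("QUERY"), class = "chainlog_query_parse_error")
  expect_error(parse_query("user=5"), class = "chainlog_query_parse_error")
  expect_error(parse_query("QUERY color=red"),
               class = "chainlog_query_parse_error")
  expect_error(parse_query("QUERY timestamprange=[5,]"),
               class = "chainlog_query_parse_error")
  expect_error(parse_query("QUERY user=5 user=6"),
               class = "chainlog_query_parse_error")
  expect_error(parse_query("QUERY sortby=User"),
               class = "chainlog_query_parse_error")
  expect_error(parse_query("QUERY user=abc"),
               class = "chainlog_query_parse_error")
})

test_that("single-clause retrieval equals a linear-scan oracle", {
  fx <- small_fixture(lines_per_node = 150, seed = 23)
  uids <- single_clause_uids(fx$ledger, "activity", "activityA")
  want <- record_uid(fx$records)[fx$records$activity == "activityA"]
  expect_setequal(uids, want)
  expect_identical(single_clause_uids(fx$ledger, "user", 999),
                   character(0))
  # the worked example: one matching record
  lg <- ledger(); setup_streams(lg, 4); insert_record(lg, table1_record())
  expect_identical(single_clause_uids(lg, "activity", "FILE_ACCESS"),
                   "UID_2_28")
})

test_that("min-cardinality selection uses counts only and breaks ties by column order", {
  lg <- ledger()
  setup_streams(lg, 1)
  recs <- generate_dataset(dataset_spec(lines_per_node = 40, n_nodes = 1,
                                        seed = 2, n_users = 2,
                                        n_activities = 8))
  insert_batch(lg, recs)
  u <- recs$user[1]; a <- recs$activity[1]
  cu <- clause_count(recs, "user", u)
  ca <- clause_count(recs, "activity", a)
  sel <- select_min_cardinality(lg, list(user = u, activity = a))
  expect_equal(sel$count, min(cu, ca))
  expect_equal(sel$column, if (ca < cu) "activity" else "user")
  # single clause returns itself
  sel1 <- select_min_cardinality(lg, list(user = u))
  expect_equal(sel1$column, "user")
  # exact tie: node=1 and id=0 both have count matching; node precedes id? no:
  # fixed order is timestamp,node,id,... so node wins a node/user tie
  lg2 <- ledger(); setup_streams(lg2, 1)
  insert_record(lg2, log_record(10, 1, 0, 7, 7, "a", "r"))
  sel2 <- select_min_cardinality(lg2, list(user = 7, node = 1))  # both count 1
  expect_equal(sel2$column, "node")
})

test_that("conjunctive queries match brute force over 100 random 2-3 clause queries", {
  fx <- small_fixture(lines_per_node = 500, seed = 31)
  recs <- fx$records
  set.seed(99)
  pools <- list(user = unique(recs$user), `ref-id` = unique(recs$ref_id),
                activity = unique(recs$activity),
                resource = unique(recs$resource))
  for (i in 1:100) {
    cols <- sample(names(pools), sample(2:3, 1))
    clauses <- lapply(pools[cols], sample, size = 1)
    q <- query(clauses)
    out <- conjunctive_query(fx$ledger, q$clauses)
    want <- brute_force_query(recs, q)
    expect_setequal(record_uid(out$records), record_uid(want))
    # fetch bound: exactly the min-cardinality candidate set is fetched
    min_count <- min(vapply(names(q$clauses), function(col) {
      clause_count(recs, col, q$clauses[[col]])
    }, numeric(1)))
    expect_equal(out$stats$records_fetched, as.integer(min_count))
    expect_equal(out$stats$records_discarded,
                 out$stats$records_fetched - nrow(out$records))
  }
})

test_that("a zero-count clause short-circuits with no record fetches", {
  fx <- small_fixture(lines_per_node = 50, seed = 4)
  out <- conjunctive_query(fx$ledger,
                           list(user = 1, activity = "no_such_activity"))
  expect_equal(nrow(out$records), 0L)
  expect_equal(out$stats$records_fetched, 0L)
  expect_equal(out$stats$uid_candidates, 0L)
})

test_that("boundary binary searches agree with a linear scan and respect the probe bound", {
  # streams of size 1, 2, 1000, 2000, duplicate-heavy
  sizes <- c(1L, 2L, 1000L, 2000L)
  for (n in sizes) {
    spec <- dataset_spec(lines_per_node = n, n_nodes = 1, seed = n + 100L,
                         duplicate_ts_prob = 0.4, max_step_ms = 5L)
    recs <- generate_dataset(spec)
    lg <- build_ledger(recs, 1)
    ts <- recs$timestamp  # node stream order == generation order
    bound <- 2 * (floor(log2(n)) + 1)
    probe_ts <- unique(c(ts[1] - 1, ts, ts[length(ts)] + 1,
                         sample(ts, min(20, n))))
    for (t in probe_ts) {
      lb <- ts_lower_bound(lg, 1, t)
      ub <- ts_upper_bound(lg, 1, t)
      expect_equal(as.integer(lb), sum(ts < t))      # leftmost ts >= t
      expect_equal(as.integer(ub), sum(ts <= t))     # one past rightmost <= t
      expect_lte(attr(lb, "probes"), bound)
      expect_lte(attr(ub, "probes"), bound)
    }
  }
  # degenerate: all-equal-timestamp stream
  lg <- ledger(); setup_streams(lg, 1)
  same <- as_log_records(do.call(rbind, lapply(0:4, function(i) {
    log_record(1000, 1, i, 1, 1, "a", "r")
  })))
  insert_batch(lg, same)
  expect_equal(as.integer(ts_lower_bound(lg, 1, 1000)), 0L)
  expect_equal(as.integer(ts_upper_bound(lg, 1, 1000)), 5L)
  expect_equal(as.integer(ts_lower_bound(lg, 1, 999)), 0L)
  expect_equal(as.integer(ts_upper_bound(lg, 1, 999)), 0L)
  expect_equal(as.integer(ts_lower_bound(lg, 1, 1001)), 5L)
})

test_that("range queries are inclusive, handle duplicates, and match brute force", {
  fx <- small_fixture(lines_per_node = 300, seed = 37, dup = 0.3,
                      max_step_ms = 20)
  recs <- fx$records
  set.seed(7)
  span <- range(recs$timestamp)
  for (i in 1:50) {
    r <- sort(sample(seq(span[1], span[2]), 2))
    q <- query(ts_range = r)
    out <- range_query(fx$ledger, q)
    want <- brute_force_query(recs, q)
    expect_setequal(record_uid(out$records), record_uid(want))
    expect_equal(out$stats$records_fetched, nrow(want))  # fetches = m
  }
  # endpoints are inclusive: a degenerate [t,t] range finds records at t
  t <- recs$timestamp[5]
  hits <- brute_force_query(recs, query(ts_range = c(t, t)))
  expect_gt(nrow(hits), 0L)
  out <- range_query(fx$ledger, query(ts_range = c(t, t)))
  expect_setequal(record_uid(out$records), record_uid(hits))
  # range covering everything returns the whole dataset
  all_out <- range_query(fx$ledger, query(ts_range = span))
  expect_equal(nrow(all_out$records), nrow(recs))
  expect_equal(all_out$stats$records_fetched, nrow(recs))
  # lo > hi: well-formed, empty, nothing fetched
  rev_out <- range_query(fx$ledger, query(ts_range = c(span[2], span[1])))
  expect_equal(nrow(rev_out$records), 0L)
  expect_equal(rev_out$stats$records_fetched, 0L)
})

test_that("range+clause queries prune candidates before fetching and match brute force", {
  fx <- small_fixture(lines_per_node = 300, seed = 41, dup = 0.25,
                      max_step_ms = 20)
  recs <- fx$records
  set.seed(17)
  span <- range(recs$timestamp)
  for (i in 1:50) {
    r <- sort(sample(seq(span[1], span[2]), 2))
    clauses <- list(user = sample(unique(recs$user), 1))
    if (i %% 2 == 0) clauses$activity <- sample(unique(recs$activity), 1)
    q <- query(clauses, ts_range = r)
    out <- range_query(fx$ledger, q)
    want <- brute_force_query(recs, q)
    expect_setequal(record_uid(out$records), record_uid(want))
    # never fetches more than the candidate set
    expect_lte(out$stats$records_fetched, out$stats$uid_candidates)
  }
  # timestamp as both equality clause and range: both constraints apply
  t <- recs$timestamp[10]
  q <- query(list(timestamp = t), ts_range = span)
  out <- execute_query(fx$ledger, q)
  expect_setequal(record_uid(out$records),
                  record_uid(brute_force_query(recs, q)))
})

test_that("validate_record applies clauses and inclusive range", {
  rec <- table1_record()
  expect_true(validate_record(rec, query(list(user = 3))))
  expect_false(validate_record(rec, query(list(user = 4))))
  expect_true(validate_record(
    rec, query(ts_range = c(1522000126703, 1522000126703))))
  expect_false(validate_record(
    rec, query(list(user = 3), ts_range = c(0, 1522000126702))))
})

test_that("sorting is ascending, stable, numeric-aware", {
  recs <- as_log_records(rbind(
    log_record(3, 1, 0, 17, 1, "b", "r"),
    log_record(1, 1, 1, 3, 1, "a", "r"),
    log_record(2, 1, 2, 9, 1, "a", "r")))
  by_ref <- sort_records(recs, "Ref-ID")
  expect_equal(by_ref$ref_id, c(3L, 9L, 17L))
  # numeric, not lexicographic: 9 < 17
  expect_equal(sort_records(recs, "timestamp")$timestamp, c(1, 2, 3))
  # stability: equal activity keys keep pre-sort order (ids 0 then 1 then 2
  # for "a","a" pair -> 1,2)
  by_act <- sort_records(recs, "activity")
  expect_equal(by_act$id, c(1L, 2L, 0L))
  expect_equal(sort_records(by_act, "activity")$id, by_act$id)
})

test_that("dispatch covers the three modalities and errors on empty queries", {
  fx <- small_fixture(lines_per_node = 100, seed = 43)
  recs <- fx$records
  # single clause: one index lookup plus one fetch per result
  out <- execute_query(fx$ledger, "QUERY user=5")
  m <- clause_count(recs, "user", 5)
  expect_equal(nrow(out$records), m)
  expect_equal(out$stats$records_fetched, m)
  expect_equal(out$stats$stream_calls, 1L + m)
  expect_equal(out$stats$records_discarded, 0L)
  # the four challenge query templates agree with the oracle
  templates <- c("QUERY user=5",
                 "QUERY resource=resD activity=activityE",
                 sprintf("QUERY timestamprange=[%.0f,%.0f]",
                         min(recs$timestamp), max(recs$timestamp)),
                 sprintf("QUERY user=6 timestamprange=[%.0f,%.0f] sortby=Ref-ID",
                         min(recs$timestamp), max(recs$timestamp)))
  for (tmpl in templates) {
    got <- record_uid(execute_query(fx$ledger, tmpl)$records)
    want <- record_uid(brute_force_query(recs, tmpl))
    q <- parse_query(tmpl)
    if (is.null(q$sort_by)) expect_setequal(got, want)
    else expect_identical(got, want)
  }
  expect_error(execute_query(fx$ledger, "QUERY"),
               class = "chainlog_query_parse_error")
})
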