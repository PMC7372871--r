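# Query execution over the two-level index.
#
# Three modalities, dispatched as in the control-flow of the engine:
#   * single clause: one index-key lookup, fetch the m matching records, O(m);
#   * conjunction: pick the minimum-cardinality clause by cached counts,
#     fetch only its candidate set S_i, validate, discard non-matches,
#     O(|S_i|);
#   * timestamp range: binary search each node's ordering stream for the
#     inclusive window boundaries, O(max(m, |S_i|) + log n).

#' Fetch statistics
#'
#' Instrumentation counters populated by every query path: `stream_calls`
#' (ledger read operations, including positional probes), `uid_candidates`
#' (candidate UIDs considered), `records_fetched` (payloads retrieved from the
#' data stream), `records_discarded` (fetched records failing full
#' validation; always `records_fetched` minus results returned).
#'
#' @param stream_calls,uid_candidates,records_fetched,records_discarded
#'   Counter values.
#' @export
fetch_stats <- function(stream_calls = 0L, uid_candidates = 0L,
                        records_fetched = 0L, records_discarded = 0L) {
  structure(list(stream_calls = as.integer(stream_calls),
                 uid_candidates = as.integer(uid_candidates),
                 records_fetched = as.integer(records_fetched),
                 records_discarded = as.integer(records_discarded)),
            class = "fetch_stats")
}

#' @export
print.fetch_stats <- function(x, ...) {
  cat(sprintf(
    "<fetch_stats: %d stream calls, %d candidates, %d fetched, %d discarded>\n",
    x$stream_calls, x$uid_candidates, x$records_fetched,
    x$records_discarded))
  invisible(x)
}

# fetch payloads for a UID set from the data stream (one key-item listing per
# UID) and parse them; preserves input UID order
.fetch_records <- function(ledger, uids) {
  if (!length(uids)) return(empty_log_records())
  payloads <- vapply(uids, function(u) {
    items <- list_stream_key_items(ledger, "logdata", u)
    if (length(items) != 1L) {
      .chainlog_error(sprintf("UID %s has %d logdata payloads, expected 1",
                              u, length(items)), "chainlog_dangling_uid")
    }
    items
  }, character(1L), USE.NAMES = FALSE)
  payloads_to_records(payloads)
}

#' Single-clause candidate UIDs
#'
#' All UIDs whose record has `column == value`: one key lookup against the
#' column's index stream.
#'
#' @param ledger A ledger built by [insert_batch()].
#' @param column One of [log_columns()].
#' @param value Column value.
#' @return Character vector of UIDs in publish order.
#' @export
single_clause_uids <- function(ledger, column, value) {
  column <- .match_column(column)
  list_stream_key_items(ledger, column, column_key(column, value))
}

#' Minimum-cardinality clause selection
#'
#' The conjunctive result set is a subset of every clause's UID set, hence of
#' the smallest one. Cardinalities come from cached per-key counts only —
#' no item list is retrieved. Ties break by the fixed column order
#' `timestamp, node, id, ref-id, user, activity, resource`, keeping the
#' planner deterministic.
#'
#' @param ledger A ledger.
#' @param clauses Named list of column=value constraints.
#' @return List with `column`, `value`, `count`, and `counts` (all clause
#'   cardinalities, named by column).
#' @export
select_min_cardinality <- function(ledger, clauses) {
  stopifnot(length(clauses) >= 1L)
  cols <- intersect(log_columns(), names(clauses))  # fixed column order
  counts <- vapply(cols, function(col) {
    stream_key_count(ledger, col, column_key(col, clauses[[col]]))
  }, integer(1L))
  best <- which.min(counts)  # first minimum under the fixed order
  list(column = cols[best], value = clauses[[cols[best]]],
       count = counts[[best]], counts = counts)
}

#' Conjunctive query (multi-clause, no range)
#'
#' Fetches only the minimum-cardinality clause's candidate set, validates
#' every candidate against all clauses, and discards non-matches. A clause
#' with zero count short-circuits: nothing is fetched.
#'
#' @param ledger A ledger.
#' @param clauses Named list of >= 2 column=value constraints.
#' @return List `records` (matching `log_records`) and `stats`
#'   ([fetch_stats()]).
#' @export
conjunctive_query <- function(ledger, clauses) {
  stopifnot(length(clauses) >= 2L)
  sel <- select_min_cardinality(ledger, clauses)
  calls <- length(clauses)  # one count lookup per clause
  if (sel$count == 0L) {
    return(list(records = empty_log_records(),
                stats = fetch_stats(stream_calls = calls)))
  }
  uids <- single_clause_uids(ledger, sel$column, sel$value)
  recs <- .fetch_records(ledger, uids)
  calls <- calls + 1L + length(uids)
  keep <- validate_records(recs, query(clauses))
  list(records = recs[keep, , drop = FALSE],
       stats = fetch_stats(stream_calls = calls,
                           uid_candidates = length(uids),
                           records_fetched = length(uids),
                           records_discarded = sum(!keep)))
}

# positional probe into an ordering stream: timestamp at 0-based position
.ts_at <- function(ledger, stream, pos) {
  as.numeric(get_item_at_position(ledger, stream, pos)$key)
}

#' Range-boundary binary search
#'
#' Over a node's ordering stream (positionally non-decreasing in timestamp),
#' `ts_lower_bound` returns the leftmost 0-based position with timestamp
#' `>= t` and `ts_upper_bound` one past the rightmost position with timestamp
#' `<= t` (both return the stream count when no position qualifies /
#' all qualify). Each search issues at most `2 * (floor(log2(n)) + 1)`
#' positional reads; the count is attached as attribute `"probes"`.
#'
#' @param ledger A ledger.
#' @param node Node number.
#' @param t Millisecond timestamp.
#' @return Integer position with attribute `probes`.
#' @export
ts_lower_bound <- function(ledger, node, t) {
  stream <- node_stream_name(node)
  lo <- 0L
  hi <- stream_item_count(ledger, stream)
  probes <- 0L
  while (lo < hi) {
    mid <- lo + (hi - lo) %/% 2L
    probes <- probes + 1L
    if (.ts_at(ledger, stream, mid) >= t) hi <- mid else lo <- mid + 1L
  }
  structure(lo, probes = probes)
}

#' @rdname ts_lower_bound
#' @export
ts_upper_bound <- function(ledger, node, t) {
  stream <- node_stream_name(node)
  lo <- 0L
  hi <- stream_item_count(ledger, stream)
  probes <- 0L
  while (lo < hi) {
    mid <- lo + (hi - lo) %/% 2L
    probes <- probes + 1L
    if (.ts_at(ledger, stream, mid) <= t) lo <- mid + 1L else hi <- mid
  }
  structure(lo, probes = probes)
}

# node numbers that have an ordering stream on this ledger
.ledger_nodes <- function(ledger) {
  nms <- stream_names(ledger)
  hits <- regmatches(nms, regexec("^node([0-9]+)timestamps$", nms))
  sort(as.integer(vapply(hits[lengths(hits) == 2L], `[`, character(1L), 2L)))
}

#' Timestamp-range query
#'
#' For each node, binary-searches the ordering stream for the inclusive
#' window `[lo, hi]`. Without clauses, exactly the records in the positional
#' windows are fetched. With clauses, the minimum-cardinality clause's
#' candidate UIDs are pruned against each node's window *before* any record
#' fetch — by membership in the window's UID set when the window is smaller
#' than the candidate set, else by comparing the candidate's record id with
#' the window's UID id bounds (valid because per-node ids increase with
#' insertion, which insertion enforces) — and only survivors are fetched and
#' validated.
#'
#' @param ledger A ledger.
#' @param q A `chainlog_query` with `ts_range` set (or query string).
#' @return List `records` and `stats`.
#' @export
range_query <- function(ledger, q) {
  q <- .as_query(q)
  stopifnot(!is.null(q$ts_range))
  lo <- q$ts_range[1L]
  hi <- q$ts_range[2L]
  if (lo > hi) {
    return(list(records = empty_log_records(), stats = fetch_stats()))
  }
  nodes <- .ledger_nodes(ledger)
  calls <- 0L

  # per-node inclusive positional windows [from, to)
  windows <- lapply(nodes, function(nd) {
    lb <- ts_lower_bound(ledger, nd, lo)
    ub <- ts_upper_bound(ledger, nd, hi)
    calls <<- calls + attr(lb, "probes") + attr(ub, "probes")
    list(node = nd, from = as.integer(lb), to = as.integer(ub))
  })
  names(windows) <- as.character(nodes)

  if (!length(q$clauses)) {
    uids <- unlist(lapply(windows, function(w) {
      if (w$to <= w$from) return(character(0))
      calls <<- calls + 1L
      .stream_slice(ledger, node_stream_name(w$node), w$from, w$to)$vals
    }), use.names = FALSE)
    recs <- .fetch_records(ledger, uids)
    calls <- calls + length(uids)
    keep <- validate_records(recs, q)  # window is exact; belt and braces
    return(list(records = recs[keep, , drop = FALSE],
                stats = fetch_stats(stream_calls = calls,
                                    uid_candidates = length(uids),
                                    records_fetched = length(uids),
                                    records_discarded = sum(!keep))))
  }

  sel <- select_min_cardinality(ledger, q$clauses)
  calls <- calls + length(q$clauses)
  if (sel$count == 0L) {
    return(list(records = empty_log_records(),
                stats = fetch_stats(stream_calls = calls)))
  }
  uids <- single_clause_uids(ledger, sel$column, sel$value)
  calls <- calls + 1L
  parsed <- parse_uids(uids)

  survive <- logical(length(uids))
  for (w in windows) {
    cand <- which(parsed$node == w$node)
    if (!length(cand) || w$to <= w$from) next
    wsize <- w$to - w$from
    if (wsize < length(cand)) {
      # small window: collect its UID set and test membership
      calls <- calls + 1L
      wuids <- .stream_slice(ledger, node_stream_name(w$node),
                             w$from, w$to)$vals
      survive[cand] <- uids[cand] %in% wuids
    } else {
      # wide window: per-node id bounds from the boundary positions
      id_min <- parse_uids(get_item_at_position(
        ledger, node_stream_name(w$node), w$from)$value)$id
      id_max <- parse_uids(get_item_at_position(
        ledger, node_stream_name(w$node), w$to - 1L)$value)$id
      calls <- calls + 2L
      survive[cand] <- parsed$id[cand] >= id_min & parsed$id[cand] <= id_max
    }
  }
  fetched <- uids[survive]
  recs <- .fetch_records(ledger, fetched)
  calls <- calls + length(fetched)
  keep <- validate_records(recs, q)
  list(records = recs[keep, , drop = FALSE],
       stats = fetch_stats(stream_calls = calls,
                           uid_candidates = length(uids),
                           records_fetched = length(fetched),
                           records_discarded = sum(!keep)))
}

#' Execute a query
#'
#' Dispatch over the three modalities: a timestamp range (with or without
#' clauses) goes to [range_query()]; otherwise a single clause takes the
#' direct index-lookup path and two or more clauses take
#' [conjunctive_query()]. Results are put in the deterministic default order
#' (nodes ascending, per-node insertion order) and then stably sorted by
#' `sortby` when present.
#'
#' @param ledger A ledger built by [insert_batch()].
#' @param q A `chainlog_query` or query string
#'   (`"QUERY user=5 sortby=Ref-ID"`).
#' @return A `query_result`: list with `records` and `stats`.
#' @examples
#' \dontrun{
#' execute_query(lg, "QUERY user=6 timestamprange=[32226847,82574461] sortby=Ref-ID")
#' }
#' @export
execute_query <- function(ledger, q) {
  q <- .as_query(q)
  if (!is.null(q$ts_range)) {
    out <- range_query(ledger, q)
  } else if (length(q$clauses) == 1L) {
    col <- names(q$clauses)[1L]
    uids <- single_clause_uids(ledger, col, q$clauses[[col]])
    recs <- .fetch_records(ledger, uids)
    out <- list(records = recs,
                stats = fetch_stats(stream_calls = 1L + length(uids),
                                    uid_candidates = length(uids),
                                    records_fetched = length(uids),
                                    records_discarded = 0L))
  } else {
    out <- conjunctive_query(ledger, q$clauses)
  }
  recs <- out$records
  # default deterministic order: node ascending, insertion (id) order within
  recs <- recs[order(recs$node, recs$id, method = "radix"), , drop = FALSE]
  if (!is.null(q$sort_by)) recs <- sort_records(recs, q$sort_by)
  rownames(recs) <- NULL
  structure(list(records = recs, stats = out$stats, query = q),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result: %d record%s> %s\n", nrow(x$records),
              if (nrow(x$records) == 1L) "" else "s", format(x$query)))
  print(x$stats)
  invisible(x)
}
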