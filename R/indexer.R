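# Insertion engine: maps one log record to its full stream-entry set under
# the two-level index and publishes it atomically.
#
# Two-level index layout, per record:
#   logdata            UID_<node>_<id>      -> JSON payload (level 2)
#   <column>           <COLUMN>_<value>     -> UID          (level 1, x7)
#   node<X>timestamps  <timestamp>          -> UID          (range ordering)
# giving exactly 9 entries per record.

#' Index layout
#'
#' Stream names of the two-level index: the data stream `logdata`, one index
#' stream per column, and one `node<X>timestamps` ordering stream per node.
#'
#' @param n_nodes Number of originating nodes (default 4).
#' @return List with `data_stream`, `column_streams`, `node_streams`,
#'   `n_nodes`.
#' @export
index_layout <- function(n_nodes = 4L) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 1L)
  list(data_stream = "logdata",
       column_streams = log_columns(),
       node_streams = node_stream_name(seq_len(n_nodes)),
       n_nodes = n_nodes)
}

#' @rdname index_layout
#' @param node Node number(s).
#' @export
node_stream_name <- function(node) {
  sprintf("node%dtimestamps", as.integer(node))
}

#' Column index key
#'
#' Index keys are `<COLUMN-NAME-UPPERCASED>_<value>`, e.g. `NODE_2`,
#' `ACTIVITY_FILE_ACCESS`, `REF-ID_17`.
#'
#' @param column One of [log_columns()].
#' @param value Column value (numeric values are rendered as plain decimals).
#' @export
column_key <- function(column, value) {
  if (is.numeric(value)) value <- format_ts(value)
  sprintf("%s_%s", toupper(column), value)
}

#' Create the index streams
#'
#' Creates `logdata`, the seven column-index streams, and the per-node
#' ordering streams on a fresh ledger.
#'
#' @param ledger A [ledger()].
#' @param n_nodes Number of nodes.
#' @return The layout, invisibly.
#' @export
setup_streams <- function(ledger, n_nodes = 4L) {
  layout <- index_layout(n_nodes)
  for (nm in c(layout$data_stream, layout$column_streams,
               layout$node_streams)) {
    create_stream(ledger, nm)
  }
  invisible(layout)
}

#' Stream entries for one record
#'
#' The full entry set inserted for one log line: the payload under its UID in
#' `logdata`, seven column-index entries mapping `<COLUMN>_<value>` back to
#' the UID, and one ordering entry in the record's `node<X>timestamps` stream
#' keyed by the decimal timestamp.
#'
#' @param record One-row `log_records` data.frame.
#' @return data.frame with columns `stream`, `key`, `value` (9 rows).
#' @examples
#' index_entries(parse_log_line("1522000126703 2 28 17 3 FILE_ACCESS GTEx"))
#' @export
index_entries <- function(record) {
  stopifnot(nrow(record) == 1L)
  uid <- record_uid(record)
  cols <- log_columns()
  vals <- c(format_ts(record$timestamp), record$node, record$id,
            record$ref_id, record$user, record$activity, record$resource)
  data.frame(
    stream = c("logdata", cols, node_stream_name(record$node)),
    key = c(uid, sprintf("%s_%s", toupper(cols), vals),
            format_ts(record$timestamp)),
    value = c(records_to_payloads(record), rep(uid, 8L)),
    stringsAsFactors = FALSE)
}

# per-node high-water marks read back from the ledger itself, so the checks
# survive snapshot round-trips and need no side state
.node_tail <- function(ledger, node) {
  ns <- node_stream_name(node)
  n <- stream_item_count(ledger, ns)
  if (n == 0L) return(NULL)
  last <- get_item_at_position(ledger, ns, n - 1L)
  list(ts = as.numeric(last$key), id = parse_uids(last$value)$id)
}

#' Insert one record
#'
#' Publishes the record's 9 index entries atomically. Per-node invariants are
#' enforced at insertion time rather than trusted: timestamps must be
#' non-decreasing and record ids strictly increasing within a node (the
#' ordering streams' binary-search precondition), and `(node, id)` must be
#' unseen.
#'
#' @param ledger A ledger prepared with [setup_streams()].
#' @param record One-row `log_records` data.frame.
#' @return The record's UID, invisibly.
#' @export
insert_record <- function(ledger, record) {
  stopifnot(nrow(record) == 1L)
  tail <- .node_tail(ledger, record$node)
  if (!is.null(tail)) {
    if (record$timestamp < tail$ts) {
      .chainlog_error(sprintf(
        "timestamp regression on node %d: %s < %s", record$node,
        format_ts(record$timestamp), format_ts(tail$ts)),
        "chainlog_monotonicity_error")
    }
    if (record$id == tail$id) {
      .chainlog_error(sprintf("duplicate record UID_%d_%d",
                              record$node, record$id),
                      "chainlog_duplicate_record")
    }
    if (record$id < tail$id) {
      .chainlog_error(sprintf(
        "record id regression on node %d: %d after %d",
        record$node, record$id, tail$id), "chainlog_id_order_error")
    }
  }
  publish_atomic(ledger, index_entries(record))
  invisible(record_uid(record))
}

#' Insert a batch of records
#'
#' Records are inserted in row order; each node's subsequence must satisfy
#' the per-node monotonicity invariants. On the first violation the batch
#' aborts (records before the failure remain inserted, the ledger being
#' append-only) and the error names the failing row.
#'
#' @param ledger A ledger prepared with [setup_streams()].
#' @param records `log_records` data.frame.
#' @param throttle Optional insertion rate cap in records per second per node
#'   (`NULL`, the default, disables pacing). Matches the conservative pacing a
#'   live multi-node ledger deployment may need; the in-memory backend does
#'   not require it.
#' @return An `insert_report`: records inserted, per-node counts, elapsed
#'   seconds.
#' @export
insert_batch <- function(ledger, records, throttle = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(throttle)) stopifnot(is.numeric(throttle), throttle > 0)
  t0 <- proc.time()[["elapsed"]]
  node_started <- numeric(0)  # per-node pacing anchors
  node_count <- integer(0)
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    nd <- as.character(rec$node)
    tryCatch(insert_record(ledger, rec), chainlog_error = function(e) {
      .chainlog_error(sprintf("batch aborted at row %d: %s", i,
                              conditionMessage(e)),
                      c("chainlog_batch_error", class(e)[1L]))
    })
    cnt <- if (nd %in% names(node_count)) node_count[[nd]] + 1L else 1L
    node_count[[nd]] <- cnt
    if (!is.null(throttle)) {
      if (!nd %in% names(node_started)) {
        node_started[[nd]] <- proc.time()[["elapsed"]]
      }
      due <- node_started[[nd]] + cnt / throttle
      wait <- due - proc.time()[["elapsed"]]
      if (wait > 0) Sys.sleep(wait)
    }
  }
  structure(list(records_inserted = nrow(records),
                 per_node = node_count[order(as.integer(names(node_count)))],
                 elapsed_s = proc.time()[["elapsed"]] - t0),
            class = "insert_report")
}

#' @export
print.insert_report <- function(x, ...) {
  cat(sprintf("<insert_report: %d records in %.2fs>\n",
              x$records_inserted, x$elapsed_s))
  if (length(x$per_node)) {
    cat("  per node:", paste(sprintf("node %s: %d", names(x$per_node),
                                     x$per_node), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Total entries across all streams
#'
#' Storage-linearity check: a ledger built by [insert_batch()] holds exactly
#' 9 entries per inserted record.
#'
#' @param ledger A `ledger`.
#' @export
ledger_entry_count <- function(ledger) {
  sum(vapply(stream_names(ledger),
             function(n) stream_item_count(ledger, n), integer(1L)))
}
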