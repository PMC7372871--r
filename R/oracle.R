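# Brute-force reference evaluator and the equivalence harness. The oracle
# never touches the ledger: it linearly scans the full record collection and
# applies the same validation/sorting semantics, so any divergence implicates
# the indexed engine.

#' Brute-force query evaluation
#'
#' Linear scan over the full record collection: keep records passing
#' [validate_records()], order them deterministically (node ascending,
#' per-node insertion order), then stably sort by the query's `sortby` column
#' if set.
#'
#' @param records All records of the dataset, in generation order.
#' @param q A `chainlog_query` or query string.
#' @return Matching `log_records`.
#' @export
brute_force_query <- function(records, q) {
  q <- .as_query(q)
  res <- records[validate_records(records, q), , drop = FALSE]
  res <- res[order(res$node, res$id, method = "radix"), , drop = FALSE]
  if (!is.null(q$sort_by)) {
    ord <- order(res[[col_to_field(q$sort_by)]], method = "radix")
    res <- res[ord, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Engine-versus-oracle equivalence run
#'
#' Executes every query against both the indexed engine and the brute-force
#' oracle and compares results keyed on UID: as a multiset when the query has
#' no sort column, order-sensitively when it does. Tabulates per-query fetch
#' statistics and a histogram of discarded-record counts (the cost penalty of
#' the minimum-cardinality heuristic).
#'
#' @param ledger Ledger built from `records` via [insert_batch()].
#' @param records The same records, in generation order (the oracle input).
#' @param queries Character vector of query strings (or list of
#'   `chainlog_query`).
#' @return An `equivalence_report`: `queries_run`, `mismatches`,
#'   `first_counterexample` (`NULL` when clean), `stats` (per-query
#'   data.frame), `discard_histogram`.
#' @export
run_equivalence <- function(ledger, records, queries) {
  n <- length(queries)
  stats <- data.frame(query = character(n), n_results = integer(n),
                      stream_calls = integer(n), uid_candidates = integer(n),
                      records_fetched = integer(n),
                      records_discarded = integer(n), match = logical(n),
                      stringsAsFactors = FALSE)
  mismatches <- 0L
  first_counterexample <- NULL
  for (i in seq_len(n)) {
    q <- .as_query(queries[[i]])
    eng <- execute_query(ledger, q)
    orc <- brute_force_query(records, q)
    got <- record_uid(eng$records)
    want <- record_uid(orc)
    ok <- if (is.null(q$sort_by)) {
      identical(sort(got), sort(want))
    } else {
      identical(got, want)
    }
    if (!ok) {
      mismatches <- mismatches + 1L
      if (is.null(first_counterexample)) {
        first_counterexample <- list(query = format(q), expected = want,
                                     got = got)
      }
    }
    stats[i, ] <- list(format(q), nrow(eng$records),
                       eng$stats$stream_calls, eng$stats$uid_candidates,
                       eng$stats$records_fetched,
                       eng$stats$records_discarded, ok)
  }
  hist <- if (n) table(stats$records_discarded) else table(integer(0))
  structure(list(queries_run = n, mismatches = mismatches,
                 first_counterexample = first_counterexample,
                 stats = stats, discard_histogram = hist),
            class = "equivalence_report")
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat(sprintf("<equivalence_report: %d queries, %d mismatch%s>\n",
              x$queries_run, x$mismatches,
              if (x$mismatches == 1L) "" else "es"))
  if (x$queries_run) {
    cat(sprintf("  records discarded: median %g, max %g\n",
                stats::median(x$stats$records_discarded),
                max(x$stats$records_discarded)))
  }
  if (!is.null(x$first_counterexample)) {
    cat("  first counterexample:", x$first_counterexample$query, "\n")
  }
  invisible(x)
}
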