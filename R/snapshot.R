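# Optional flat-file persistence: one stream entry per line as JSON
# (NDJSON). Not required by the engine; lets the CLI insert once and query
# in later invocations.

#' Ledger snapshot persistence
#'
#' Writes every stream entry as one JSON line `{"stream":..,"key":..,
#' "value":..}`, streams in creation order, entries in publish order, so the
#' snapshot is byte-deterministic. `read_ledger_snapshot()` rebuilds an
#' identical ledger (same streams, positions, and counts).
#'
#' @param ledger A `ledger`.
#' @param path Snapshot file path.
#' @return `path` (write) / the rebuilt `ledger` (read).
#' @export
write_ledger_snapshot <- function(ledger, path) {
  entries <- lapply(stream_names(ledger), function(nm) {
    sl <- .stream_slice(ledger, nm, 0L, stream_item_count(ledger, nm))
    data.frame(stream = rep(nm, length(sl$keys)), key = sl$keys,
               value = sl$vals, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, entries)
  con <- file(path, "w")
  on.exit(close(con))
  # header line records stream creation order (empty streams included)
  writeLines(jsonlite::toJSON(list(streams = stream_names(ledger)),
                              auto_unbox = FALSE), con)
  if (!is.null(df) && nrow(df)) {
    jsonlite::stream_out(df, con, verbose = FALSE)
  }
  invisible(path)
}

#' @rdname write_ledger_snapshot
#' @export
read_ledger_snapshot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) .chainlog_error("empty snapshot", "chainlog_snapshot_error")
  header <- jsonlite::fromJSON(lines[[1L]])
  lg <- ledger()
  for (nm in header$streams) create_stream(lg, nm)
  if (length(lines) > 1L) {
    df <- jsonlite::stream_in(textConnection(lines[-1L]), verbose = FALSE)
    publish_atomic(lg, df)
  }
  lg
}
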