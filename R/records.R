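# Log-record domain type: the 7-field access-log line, its JSON payload, and
# the UID scheme linking index entries to their data-stream payload.

#' Audit-log column names
#'
#' The seven columns of an access-log record, in the canonical line order:
#' `timestamp`, `node`, `id`, `ref-id`, `user`, `activity`, `resource`.
#'
#' @return Character vector of length 7.
#' @export
log_columns <- function() {
  c("timestamp", "node", "id", "ref-id", "user", "activity", "resource")
}

# data.frame column names (syntactic): "ref-id" is stored as "ref_id"
.log_fields <- c("timestamp", "node", "id", "ref_id", "user",
                 "activity", "resource")

.numeric_columns <- c("timestamp", "node", "id", "ref-id", "user")

# column name (dialect, e.g. "ref-id") -> data.frame field name
col_to_field <- function(column) chartr("-", "_", column)

.chainlog_error <- function(msg, class, call = NULL) {
  stop(errorCondition(msg, class = c(class, "chainlog_error"),
                      call = call))
}

#' Construct a log record
#'
#' @param timestamp Integer milliseconds since epoch (stored as double; exact
#'   for the 13-digit values used in practice).
#' @param node Originating node number (>= 1).
#' @param id Per-node record id (>= 0).
#' @param ref_id,user Integer columns.
#' @param activity,resource Whitespace-free token strings, e.g.
#'   `"FILE_ACCESS"`, `"GTEx"`.
#' @return A one-row data.frame with class `log_records`.
#' @examples
#' log_record(1522000126703, 2, 28, 17, 3, "FILE_ACCESS", "GTEx")
#' @export
log_record <- function(timestamp, node, id, ref_id, user, activity, resource) {
  rec <- data.frame(timestamp = as.numeric(timestamp),
                    node = as.integer(node),
                    id = as.integer(id),
                    ref_id = as.integer(ref_id),
                    user = as.integer(user),
                    activity = as.character(activity),
                    resource = as.character(resource),
                    stringsAsFactors = FALSE)
  as_log_records(rec)
}

#' @export
as_log_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(.log_fields, names(records))
  if (length(missing)) {
    .chainlog_error(sprintf("missing record fields: %s",
                            paste(missing, collapse = ", ")),
                    "chainlog_bad_record")
  }
  records <- records[, .log_fields, drop = FALSE]
  class(records) <- c("log_records", "data.frame")
  records
}

empty_log_records <- function() {
  log_record(numeric(0), integer(0), integer(0), integer(0), integer(0),
             character(0), character(0))
}

.is_int_token <- function(x) grepl("^-?[0-9]+$", x)

#' Parse access-log lines
#'
#' A log line has exactly seven whitespace-separated fields in the order
#' `timestamp node id ref-id user activity resource`, e.g.
#' `"1522000126703 2 28 17 3 FILE_ACCESS GTEx"`. The first five must be
#' integers.
#'
#' @param lines Character vector of log lines.
#' @return `log_records` data.frame, one row per line.
#' @export
parse_log_lines <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_log_records())
  toks <- strsplit(lines, "[ \t]+")
  nfield <- lengths(toks)
  if (any(nfield != 7L)) {
    bad <- which(nfield != 7L)[1L]
    .chainlog_error(sprintf(
      "line %d has %d fields, expected 7: %s", bad, nfield[bad], lines[bad]),
      "chainlog_parse_error")
  }
  m <- matrix(unlist(toks, use.names = FALSE), ncol = 7L, byrow = TRUE)
  num <- m[, 1:5, drop = FALSE]
  ok <- matrix(.is_int_token(num), nrow = nrow(num))
  if (!all(ok)) {
    bad <- which(!apply(ok, 1L, all))[1L]
    .chainlog_error(sprintf(
      "line %d has a non-integer numeric field: %s", bad, lines[bad]),
      "chainlog_parse_error")
  }
  log_record(as.numeric(m[, 1L]), as.integer(m[, 2L]), as.integer(m[, 3L]),
             as.integer(m[, 4L]), as.integer(m[, 5L]), m[, 6L], m[, 7L])
}

#' @rdname parse_log_lines
#' @param line A single log line.
#' @export
parse_log_line <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  if (!nzchar(trimws(line))) {
    .chainlog_error("empty log line", "chainlog_parse_error")
  }
  parse_log_lines(line)
}

# exact decimal rendering of millisecond timestamps stored as doubles
format_ts <- function(ts) sprintf("%.0f", ts)

#' Render records as log lines
#'
#' Inverse of [parse_log_lines()]: one 7-field whitespace-separated line per
#' record.
#'
#' @param records `log_records` data.frame.
#' @return Character vector of lines.
#' @export
format_log_lines <- function(records) {
  if (!nrow(records)) return(character(0))
  sprintf("%s %d %d %d %d %s %s",
          format_ts(records$timestamp), records$node, records$id,
          records$ref_id, records$user, records$activity, records$resource)
}

#' Record identifiers
#'
#' Every record is identified by `UID_<node>_<id>`; `(node, id)` is unique
#' across a dataset, so the UID links each index entry to exactly one payload
#' in the data stream.
#'
#' @param records `log_records` data.frame.
#' @return Character vector of UIDs.
#' @examples
#' record_uid(log_record(1522000126703, 2, 28, 17, 3, "FILE_ACCESS", "GTEx"))
#' @export
record_uid <- function(records) {
  sprintf("UID_%d_%d", records$node, records$id)
}

# "UID_<node>_<id>" -> data.frame(node, id)
parse_uids <- function(uids) {
  m <- regmatches(uids, regexec("^UID_([0-9]+)_([0-9]+)$", uids))
  ok <- lengths(m) == 3L
  if (!all(ok)) {
    .chainlog_error(sprintf("malformed UID: %s", uids[!ok][1L]),
                    "chainlog_bad_uid")
  }
  m <- matrix(unlist(m, use.names = FALSE), ncol = 3L, byrow = TRUE)
  data.frame(node = as.integer(m[, 2L]), id = as.integer(m[, 3L]))
}

#' Record JSON payloads
#'
#' Serialises records to the data-stream payload: a JSON object with exactly
#' the seven keys `timestamp, node, id, ref-id, user, activity, resource`, in
#' that fixed order. String values are quoted (strict JSON); the reader
#' [payloads_to_records()] also tolerates the unquoted shorthand form
#' `{timestamp:...,activity:FILE_ACCESS,...}`.
#'
#' @param records `log_records` data.frame.
#' @return Character vector of JSON payload texts.
#' @export
records_to_payloads <- function(records) {
  if (!nrow(records)) return(character(0))
  sprintf(paste0('{"timestamp":%s,"node":%d,"id":%d,"ref-id":%d,',
                 '"user":%d,"activity":"%s","resource":"%s"}'),
          format_ts(records$timestamp), records$node, records$id,
          records$ref_id, records$user, records$activity, records$resource)
}

#' @rdname records_to_payloads
#' @param record A single-row `log_records` data.frame.
#' @export
record_to_payload <- function(record) {
  stopifnot(nrow(record) == 1L)
  records_to_payloads(record)
}

#' @rdname records_to_payloads
#' @param payloads Character vector of payload texts (strict JSON or unquoted
#'   shorthand).
#' @export
payloads_to_records <- function(payloads) {
  if (!length(payloads)) return(empty_log_records())
  body <- sub("^\\s*\\{", "", sub("\\}\\s*$", "", payloads))
  body <- gsub('"', "", body, fixed = TRUE)
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 7L)) {
    .chainlog_error("payload does not have exactly 7 fields",
                    "chainlog_parse_error")
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = 7L, byrow = TRUE)
  keys <- sub(":.*$", "", m)
  vals <- sub("^[^:]*:", "", m)
  canon <- log_columns()
  if (!all(keys == matrix(canon, nrow(m), 7L, byrow = TRUE))) {
    # keys present but out of canonical order: realign row-wise
    vals <- t(vapply(seq_len(nrow(m)), function(i) {
      v <- vals[i, ][match(canon, keys[i, ])]
      if (anyNA(v)) {
        .chainlog_error("payload is missing a canonical key",
                        "chainlog_parse_error")
      }
      v
    }, character(7L)))
  }
  log_record(as.numeric(vals[, 1L]), as.integer(vals[, 2L]),
             as.integer(vals[, 3L]), as.integer(vals[, 4L]),
             as.integer(vals[, 5L]), vals[, 6L], vals[, 7L])
}

#' @rdname records_to_payloads
#' @param payload A single payload text.
#' @export
payload_to_record <- function(payload) {
  stopifnot(is.character(payload), length(payload) == 1L)
  payloads_to_records(payload)
}

#' Read a node log file
#'
#' @param path Path to a plain-text log file, one 7-field record per line.
#' @return `log_records` data.frame.
#' @export
read_log_file <- function(path) {
  parse_log_lines(readLines(path, warn = FALSE))
}

#' @export
print.log_records <- function(x, ...) {
  cat(sprintf("<log_records: %d record%s>\n", nrow(x),
              if (nrow(x) == 1L) "" else "s"))
  if (nrow(x)) print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}
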