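# Query dialect: "QUERY <col>=<val> ... [timestamprange=[lo,hi]] [sortby=<Col>]"

.match_column <- function(name, what = "column") {
  cols <- log_columns()
  hit <- match(tolower(name), cols)
  if (is.na(hit)) {
    .chainlog_error(sprintf("unknown %s: %s", what, name),
                    "chainlog_query_parse_error")
  }
  cols[hit]
}

.parse_clause_value <- function(column, value) {
  if (!nzchar(value)) {
    .chainlog_error(sprintf("empty value for clause %s", column),
                    "chainlog_query_parse_error")
  }
  if (column %in% .numeric_columns) {
    if (!.is_int_token(value)) {
      .chainlog_error(sprintf("clause %s=%s: expected an integer",
                              column, value), "chainlog_query_parse_error")
    }
    return(as.numeric(value))
  }
  value
}

#' Construct a query
#'
#' @param clauses Named list of column=value equality constraints; names are
#'   canonical column names ([log_columns()]).
#' @param ts_range Optional inclusive `c(lo, hi)` millisecond timestamp range.
#'   `lo > hi` is well-formed and matches nothing.
#' @param sort_by Optional column to sort results by (ascending, stable).
#' @return A `chainlog_query`.
#' @export
query <- function(clauses = list(), ts_range = NULL, sort_by = NULL) {
  if (length(clauses)) {
    names(clauses) <- vapply(names(clauses), .match_column, character(1L))
    if (anyDuplicated(names(clauses))) {
      .chainlog_error("duplicate clause column", "chainlog_query_parse_error")
    }
    clauses <- Map(.parse_clause_value, names(clauses),
                   lapply(clauses, as.character))
  }
  if (!is.null(ts_range)) {
    stopifnot(is.numeric(ts_range), length(ts_range) == 2L, !anyNA(ts_range))
    ts_range <- as.numeric(ts_range)
  }
  if (!is.null(sort_by)) sort_by <- .match_column(sort_by, "sort column")
  if (!length(clauses) && is.null(ts_range)) {
    .chainlog_error("query has no constraints (need a clause or a range)",
                    "chainlog_query_parse_error")
  }
  structure(list(clauses = clauses, ts_range = ts_range, sort_by = sort_by),
            class = "chainlog_query")
}

#' Parse a query string
#'
#' Accepts the challenge dialect: a line starting with `QUERY` followed by
#' whitespace-separated terms, each `column=value`,
#' `timestamprange=[lo,hi]` (inclusive endpoints), or `sortby=<Column>`.
#' Column names match case-insensitively (`Ref-ID` and `ref-id` are the same
#' column); values are matched exactly.
#'
#' @param text Query string, e.g. `"QUERY user=5"`,
#'   `"QUERY user=6 timestamprange=[32226847,82574461] sortby=Ref-ID"`.
#' @return A `chainlog_query`.
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(trimws(text), "[ \t]+")[[1L]]
  if (!length(toks) || toks[1L] != "QUERY") {
    .chainlog_error("query must begin with the token QUERY",
                    "chainlog_query_parse_error")
  }
  clauses <- list()
  ts_range <- NULL
  sort_by <- NULL
  for (tok in toks[-1L]) {
    eq <- regexpr("=", tok, fixed = TRUE)
    if (eq < 0L) {
      .chainlog_error(sprintf("malformed query term: %s", tok),
                      "chainlog_query_parse_error")
    }
    k <- tolower(substr(tok, 1L, eq - 1L))
    v <- substr(tok, eq + 1L, nchar(tok))
    if (k == "timestamprange") {
      m <- regmatches(v, regexec("^\\[(-?[0-9]+),(-?[0-9]+)\\]$", v))[[1L]]
      if (length(m) != 3L) {
        .chainlog_error(sprintf("malformed timestamprange: %s", v),
                        "chainlog_query_parse_error")
      }
      if (!is.null(ts_range)) {
        .chainlog_error("duplicate timestamprange",
                        "chainlog_query_parse_error")
      }
      ts_range <- c(as.numeric(m[2L]), as.numeric(m[3L]))
    } else if (k == "sortby") {
      if (!is.null(sort_by)) {
        .chainlog_error("duplicate sortby", "chainlog_query_parse_error")
      }
      sort_by <- .match_column(v, "sort column")
    } else {
      col <- .match_column(k)
      if (col %in% names(clauses)) {
        .chainlog_error(sprintf("duplicate clause for column %s", col),
                        "chainlog_query_parse_error")
      }
      clauses[[col]] <- .parse_clause_value(col, v)
    }
  }
  query(clauses, ts_range, sort_by)
}

.as_query <- function(q) {
  if (is.character(q)) parse_query(q) else {
    stopifnot(inherits(q, "chainlog_query"))
    q
  }
}

#' @export
format.chainlog_query <- function(x, ...) {
  parts <- "QUERY"
  if (length(x$clauses)) {
    vals <- vapply(x$clauses, function(v) {
      if (is.numeric(v)) format_ts(v) else v
    }, character(1L))
    parts <- c(parts, sprintf("%s=%s", names(x$clauses), vals))
  }
  if (!is.null(x$ts_range)) {
    parts <- c(parts, sprintf("timestamprange=[%s,%s]",
                              format_ts(x$ts_range[1L]),
                              format_ts(x$ts_range[2L])))
  }
  if (!is.null(x$sort_by)) parts <- c(parts, sprintf("sortby=%s", x$sort_by))
  paste(parts, collapse = " ")
}

#' @export
print.chainlog_query <- function(x, ...) {
  cat("<chainlog_query>", format(x), "\n")
  invisible(x)
}

#' Validate records against a query
#'
#' True for records matching every equality clause and, when present, falling
#' inside the inclusive timestamp range.
#'
#' @param records `log_records` data.frame.
#' @param q A `chainlog_query` or query string.
#' @return Logical vector, one element per record.
#' @export
validate_records <- function(records, q) {
  q <- .as_query(q)
  keep <- rep(TRUE, nrow(records))
  for (col in names(q$clauses)) {
    v <- records[[col_to_field(col)]]
    keep <- keep & (v == q$clauses[[col]])
  }
  if (!is.null(q$ts_range)) {
    keep <- keep & records$timestamp >= q$ts_range[1L] &
      records$timestamp <= q$ts_range[2L]
  }
  keep
}

#' @rdname validate_records
#' @param record One-row `log_records` data.frame.
#' @export
validate_record <- function(record, q) {
  stopifnot(nrow(record) == 1L)
  validate_records(record, q)
}

#' Sort records by a column
#'
#' Ascending, stable: numeric columns compare numerically, token columns
#' byte-lexicographically (C locale); ties keep their pre-sort order.
#'
#' @param records `log_records` data.frame.
#' @param column One of [log_columns()].
#' @export
sort_records <- function(records, column) {
  column <- .match_column(column, "sort column")
  ord <- order(records[[col_to_field(column)]], method = "radix")
  records[ord, , drop = FALSE]
}
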