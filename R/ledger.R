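# In-memory append-only stream ledger: the reference backend for the stream
# API contract the indexer and query engine depend on. Semantics mirror a
# permissioned-ledger stream store: named streams of (key, value) items,
# append-only, per-key item lists in publish order, cached per-key counts,
# and positional access in publish ("local") order.

#' Create an empty stream ledger
#'
#' An append-only store of named streams. Each stream is an ordered sequence
#' of (key, value) items; items are never mutated or deleted, per-key counts
#' are maintained incrementally at publish time (count lookups never enumerate
#' item lists), and items can be addressed by 0-based publish position.
#'
#' @return A `ledger` object (environment-backed; modified in place).
#' @examples
#' lg <- ledger()
#' create_stream(lg, "logdata")
#' publish_atomic(lg, data.frame(stream = "logdata", key = "UID_1_0",
#'                               value = "{}"))
#' stream_item_count(lg, "logdata")
#' @export
ledger <- function() {
  lg <- new.env(parent = emptyenv())
  lg$streams <- new.env(parent = emptyenv())
  lg$stream_order <- character(0)
  class(lg) <- "ledger"
  lg
}

.new_stream <- function() {
  s <- new.env(parent = emptyenv())
  s$n <- 0L
  s$cap <- 0L
  s$keys <- character(0)
  s$vals <- character(0)
  s$index <- new.env(parent = emptyenv())  # key -> integer positions (0-based)
  s$key_order <- character(0)              # keys in first-publish order
  s
}

.get_stream <- function(ledger, name) {
  s <- ledger$streams[[name]]
  if (is.null(s)) {
    .chainlog_error(sprintf("unknown stream: %s", name),
                    "chainlog_unknown_stream")
  }
  s
}

#' @rdname ledger
#' @param ledger A `ledger`.
#' @param name Stream name (nonempty string). Stream keys and names are exact
#'   byte strings: lookup is case-sensitive.
#' @export
create_stream <- function(ledger, name) {
  stopifnot(inherits(ledger, "ledger"), is.character(name), length(name) == 1L)
  if (!nzchar(name)) {
    .chainlog_error("stream name must be nonempty", "chainlog_bad_stream_name")
  }
  if (!is.null(ledger$streams[[name]])) {
    .chainlog_error(sprintf("stream already exists: %s", name),
                    "chainlog_duplicate_stream")
  }
  ledger$streams[[name]] <- .new_stream()
  ledger$stream_order <- c(ledger$stream_order, name)
  invisible(name)
}

#' @rdname ledger
#' @export
stream_exists <- function(ledger, name) {
  !is.null(ledger$streams[[name]])
}

#' @rdname ledger
#' @export
stream_names <- function(ledger) {
  ledger$stream_order
}

.stream_append <- function(s, key, value) {
  n <- s$n + 1L
  if (n > s$cap) {
    newcap <- max(32L, s$cap * 2L)
    length(s$keys) <- newcap
    length(s$vals) <- newcap
    s$cap <- newcap
  }
  s$keys[n] <- key
  s$vals[n] <- value
  s$n <- n
  pos <- n - 1L
  existing <- s$index[[key]]
  if (is.null(existing)) {
    s$index[[key]] <- pos
    s$key_order <- c(s$key_order, key)
  } else {
    s$index[[key]] <- c(existing, pos)
  }
  pos
}

#' Publish entries atomically
#'
#' Appends a nonempty set of (stream, key, value) entries in one call,
#' all-or-nothing: if any named stream does not exist, no entry is written.
#' Mirrors a raw multi-stream send, the primitive that lets one log record's
#' full index-entry set land in a single ledger transaction.
#'
#' @param ledger A `ledger`.
#' @param entries data.frame with character columns `stream`, `key`, `value`.
#' @return Integer vector of 0-based positions, one per entry, in append
#'   order within each entry's stream.
#' @export
publish_atomic <- function(ledger, entries) {
  stopifnot(inherits(ledger, "ledger"), is.data.frame(entries))
  if (!nrow(entries)) {
    .chainlog_error("publish_atomic requires at least one entry",
                    "chainlog_empty_publish")
  }
  stream <- as.character(entries$stream)
  key <- as.character(entries$key)
  value <- as.character(entries$value)
  # validate every stream before touching any of them (atomicity)
  for (nm in unique(stream)) .get_stream(ledger, nm)
  pos <- integer(length(stream))
  for (i in seq_along(stream)) {
    pos[i] <- .stream_append(ledger$streams[[stream[i]]], key[i], value[i])
  }
  pos
}

#' List stream keys with cached counts
#'
#' @param ledger A `ledger`.
#' @param stream Stream name.
#' @param key Optional single key: restrict the listing to that key (count 0
#'   if absent). The cost of a single-key count lookup is independent of the
#'   key's item-list length.
#' @return data.frame with columns `key`, `count`, keys in first-publish
#'   order.
#' @export
list_stream_keys <- function(ledger, stream, key = NULL) {
  s <- .get_stream(ledger, stream)
  if (!is.null(key)) {
    idx <- s$index[[key]]
    return(data.frame(key = key, count = length(idx),
                      stringsAsFactors = FALSE))
  }
  ks <- s$key_order
  counts <- if (length(ks)) {
    vapply(ks, function(k) length(s$index[[k]]), integer(1L),
           USE.NAMES = FALSE)
  } else integer(0)
  data.frame(key = ks, count = counts, stringsAsFactors = FALSE)
}

#' Stream key count
#'
#' Constant-time count of items published under one key (0 if absent).
#'
#' @inheritParams list_stream_keys
#' @export
stream_key_count <- function(ledger, stream, key) {
  s <- .get_stream(ledger, stream)
  length(s$index[[key]])
}

#' List a key's items
#'
#' All payload values ever published to `stream` under `key`, in publish
#' order; an absent key yields an empty vector.
#'
#' @inheritParams list_stream_keys
#' @return Character vector of values.
#' @export
list_stream_key_items <- function(ledger, stream, key) {
  s <- .get_stream(ledger, stream)
  idx <- s$index[[key]]
  if (is.null(idx)) return(character(0))
  s$vals[idx + 1L]
}

#' Positional access
#'
#' Returns the `position`-th published item of a stream (0-based). Publish
#' order is the stream's local ordering, so positional access over the
#' per-node timestamp streams iterates items in timestamp-sorted order.
#'
#' @inheritParams list_stream_keys
#' @param position 0-based publish index.
#' @return List with `stream`, `key`, `value`, `position`.
#' @export
get_item_at_position <- function(ledger, stream, position) {
  s <- .get_stream(ledger, stream)
  position <- as.integer(position)
  if (length(position) != 1L || is.na(position) ||
      position < 0L || position >= s$n) {
    .chainlog_error(sprintf(
      "position %s out of range for stream %s (count %d)",
      as.character(position), stream, s$n), "chainlog_position_error")
  }
  list(stream = stream, key = s$keys[position + 1L],
       value = s$vals[position + 1L], position = position)
}

# contiguous positional slice [from, to) of a stream's (key, value) items;
# internal fast path used by range queries and snapshots
.stream_slice <- function(ledger, stream, from, to) {
  s <- .get_stream(ledger, stream)
  if (to <= from) {
    return(list(keys = character(0), vals = character(0)))
  }
  stopifnot(from >= 0L, to <= s$n)
  sel <- (from + 1L):to
  list(keys = s$keys[sel], vals = s$vals[sel])
}

#' @rdname get_item_at_position
#' @export
stream_item_count <- function(ledger, stream) {
  .get_stream(ledger, stream)$n
}

#' @export
print.ledger <- function(x, ...) {
  nms <- stream_names(x)
  total <- sum(vapply(nms, function(n) stream_item_count(x, n), integer(1L)))
  cat(sprintf("<ledger: %d stream%s, %d entries>\n", length(nms),
              if (length(nms) == 1L) "" else "s", total))
  for (n in utils::head(nms, 12L)) {
    cat(sprintf("  %s: %d\n", n, stream_item_count(x, n)))
  }
  if (length(nms) > 12L) cat(sprintf("  ... and %d more\n", length(nms) - 12L))
  invisible(x)
}
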