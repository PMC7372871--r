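# Synthetic audit-log generator: per-node log files with the structural
# properties the engine assumes (per-node non-decreasing timestamps with
# configurable duplication, sequential per-node record ids, uniform draws
# from fixed column-value pools), plus seeded nine-query benchmark suites.

#' Seed of the standard test fixture
#'
#' The documented seed constant of the "standard fixture" (4 nodes x 2,000
#' lines, duplicate-timestamp probability 0.2) used across the test suite.
#'
#' @export
standard_fixture_seed <- function() 20180618L

#' Dataset generation parameters
#'
#' Defines a reproducible synthetic audit-log workload. Column values are
#' drawn uniformly from fixed pools: users and ref-ids are integers
#' `1..cardinality`; activities and resources are labelled tokens
#' (`"activityA"`, ..., `"resA"`, ...). Within a node, timestamps start at
#' `start_timestamp` and advance by a uniform step of 1..`max_step_ms`
#' milliseconds, except that with probability `duplicate_ts_prob` a record
#' repeats its predecessor's timestamp. Record ids count from 0 per node, so
#' per-node id order coincides with timestamp order — the invariant the
#' range-query binary search relies on.
#'
#' @param lines_per_node Records generated per node (>= 0).
#' @param n_nodes Number of nodes (default 4).
#' @param seed RNG seed; the same spec and seed reproduce the dataset and its
#'   rendered log files byte for byte.
#' @param start_timestamp First timestamp per node, ms since epoch.
#' @param max_step_ms Maximum timestamp increment between consecutive records
#'   of a node.
#' @param duplicate_ts_prob Probability in `[0, 1]` that a record repeats the
#'   previous timestamp of its node.
#' @param n_users,n_ref_ids,n_activities,n_resources Column-value pool sizes.
#' @return A `dataset_spec`.
#' @export
dataset_spec <- function(lines_per_node, n_nodes = 4L,
                         seed = standard_fixture_seed(),
                         start_timestamp = 1522000000000,
                         max_step_ms = 1000L, duplicate_ts_prob = 0.2,
                         n_users = 10L, n_ref_ids = 100L,
                         n_activities = 5L, n_resources = 4L) {
  spec <- list(lines_per_node = as.integer(lines_per_node),
               n_nodes = as.integer(n_nodes), seed = as.integer(seed),
               start_timestamp = as.numeric(start_timestamp),
               max_step_ms = as.integer(max_step_ms),
               duplicate_ts_prob = as.numeric(duplicate_ts_prob),
               n_users = as.integer(n_users),
               n_ref_ids = as.integer(n_ref_ids),
               n_activities = as.integer(n_activities),
               n_resources = as.integer(n_resources))
  bad <- function(msg) .chainlog_error(msg, "chainlog_bad_spec")
  if (is.na(spec$lines_per_node) || spec$lines_per_node < 0L) {
    bad("lines_per_node must be >= 0")
  }
  if (is.na(spec$n_nodes) || spec$n_nodes < 1L) bad("n_nodes must be >= 1")
  if (is.na(spec$duplicate_ts_prob) || spec$duplicate_ts_prob < 0 ||
      spec$duplicate_ts_prob > 1) {
    bad("duplicate_ts_prob must be in [0, 1]")
  }
  if (spec$max_step_ms < 1L) bad("max_step_ms must be >= 1")
  for (f in c("n_users", "n_ref_ids", "n_activities", "n_resources")) {
    if (is.na(spec[[f]]) || spec[[f]] < 1L) bad(sprintf("%s must be >= 1", f))
  }
  structure(spec, class = "dataset_spec")
}

token_pool <- function(prefix, n) {
  if (n <= 26L) paste0(prefix, LETTERS[seq_len(n)]) else paste0(prefix,
                                                                seq_len(n))
}

# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a synthetic dataset
#'
#' @param spec A [dataset_spec()].
#' @return `log_records` data.frame: node 1's records in insertion order,
#'   then node 2's, and so on. Satisfies every insertion precondition by
#'   construction, so `insert_batch()` on generated data never errors.
#' @examples
#' generate_dataset(dataset_spec(lines_per_node = 5, n_nodes = 2, seed = 1))
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  n <- spec$lines_per_node
  if (n == 0L) return(empty_log_records())
  activities <- token_pool("activity", spec$n_activities)
  resources <- token_pool("res", spec$n_resources)
  .with_seed(spec$seed, {
    per_node <- lapply(seq_len(spec$n_nodes), function(nd) {
      dup <- stats::runif(n) < spec$duplicate_ts_prob
      step <- ifelse(dup, 0L, sample.int(spec$max_step_ms, n, replace = TRUE))
      step[1L] <- 0L  # first record sits at the start timestamp
      log_record(
        timestamp = spec$start_timestamp + cumsum(as.numeric(step)),
        node = rep(nd, n),
        id = 0:(n - 1L),
        ref_id = sample.int(spec$n_ref_ids, n, replace = TRUE),
        user = sample.int(spec$n_users, n, replace = TRUE),
        activity = sample(activities, n, replace = TRUE),
        resource = sample(resources, n, replace = TRUE))
    })
    as_log_records(do.call(rbind, per_node))
  })
}

#' Generate a nine-query benchmark suite
#'
#' A fixed template of nine queries covering the three modalities — three
#' single-clause, three conjunctive, one bare timestamp range, and two
#' range-plus-clause queries with sorting — with constraint values drawn at
#' random from the dataset spec's value pools and timestamp span.
#'
#' @param spec A [dataset_spec()] (defines the pools and time span).
#' @param seed Suite seed; the same seed yields the identical suite.
#' @return Character vector of nine query strings, each parseable by
#'   [parse_query()].
#' @export
generate_query_suite <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "dataset_spec"))
  activities <- token_pool("activity", spec$n_activities)
  resources <- token_pool("res", spec$n_resources)
  ts_lo <- spec$start_timestamp
  ts_hi <- spec$start_timestamp +
    as.numeric(spec$lines_per_node) * spec$max_step_ms
  .with_seed(seed, {
    u <- function() sample.int(spec$n_users, 1L)
    ri <- function() sample.int(spec$n_ref_ids, 1L)
    act <- function() sample(activities, 1L)
    res <- function() sample(resources, 1L)
    rng <- function() {
      r <- sort(round(stats::runif(2L, ts_lo, ts_hi)))
      sprintf("timestamprange=[%s,%s]", format_ts(r[1L]), format_ts(r[2L]))
    }
    c(sprintf("QUERY user=%d", u()),
      sprintf("QUERY activity=%s", act()),
      sprintf("QUERY resource=%s", res()),
      sprintf("QUERY resource=%s activity=%s", res(), act()),
      sprintf("QUERY user=%d ref-id=%d", u(), ri()),
      sprintf("QUERY user=%d activity=%s resource=%s", u(), act(), res()),
      sprintf("QUERY %s", rng()),
      sprintf("QUERY user=%d %s sortby=Ref-ID", u(), rng()),
      sprintf("QUERY activity=%s %s sortby=User", act(), rng()))
  })
}

#' Write per-node log files
#'
#' One plain-text file `node<X>.log` per node, in the 7-field line format;
#' parsing the lines back restores the records exactly.
#'
#' @param records `log_records` data.frame.
#' @param directory Writable output directory.
#' @param nodes Nodes to write (default: the nodes present in `records`); a
#'   node with no records yields an empty file.
#' @return Named character vector of file paths.
#' @export
write_node_log_files <- function(records, directory,
                                 nodes = sort(unique(records$node))) {
  stopifnot(dir.exists(directory))
  paths <- character(0)
  for (nd in nodes) {
    path <- file.path(directory, sprintf("node%d.log", nd))
    sub <- records[records$node == nd, , drop = FALSE]
    writeLines(format_log_lines(sub), path)
    paths[[as.character(nd)]] <- path
  }
  paths
}

#' Build a ledger from a dataset in one call
#'
#' Convenience wrapper: creates the index streams for `spec$n_nodes` nodes
#' and inserts the records.
#'
#' @param records `log_records` data.frame.
#' @param n_nodes Number of node ordering streams to create.
#' @return The populated `ledger`.
#' @export
build_ledger <- function(records, n_nodes = max(records$node, 1L)) {
  lg <- ledger()
  setup_streams(lg, n_nodes)
  if (nrow(records)) insert_batch(lg, records)
  lg
}
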