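# Shared fixtures, built in code at test time.

table1_line <- "1522000126703 2 28 17 3 FILE_ACCESS GTEx"

table1_record <- function() parse_log_line(table1_line)

# small fixture: generated dataset + populated ledger
small_fixture <- function(lines_per_node = 100L, n_nodes = 4L, seed = 42L,
                          dup = 0.2, ...) {
  spec <- dataset_spec(lines_per_node = lines_per_node, n_nodes = n_nodes,
                       seed = seed, duplicate_ts_prob = dup, ...)
  records <- generate_dataset(spec)
  list(spec = spec, records = records,
       ledger = build_ledger(records, n_nodes))
}

# independent per-key tally of a column's values (oracle for index counts)
column_value_tally <- function(records, column) {
  v <- records[[chartr("-", "_", column)]]
  table(as.character(v))
}

# count of records matching a single clause, by linear scan
clause_count <- function(records, column, value) {
  sum(records[[chartr("-", "_", column)]] == value)
}
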