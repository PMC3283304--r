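# shared test helpers: tiny sequence generators and match-set keys

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# canonical comparison key of a match table
match_keys <- function(df) {
  sort(paste(df$db_begin, df$db_end, df$q_begin, df$q_end, df$errors))
}

# a hit row covering two whole sequences with a generous diagonal band
full_hit <- function(db, query) {
  list(db_begin = 1L, db_end = nchar(db), q_begin = 1L, q_end = nchar(query),
       diag_min = -nchar(query), diag_max = nchar(db))
}
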