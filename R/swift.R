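#' Build a q-gram index of a sequence
#'
#' Lists every start position of every length-`q` substring over
#' \{A,C,G,T\}; windows containing an ambiguous base (N) are skipped.
#' This small R-level index backs inspection and tests; the hit scan in
#' [swift_hits()] builds its own packed index in compiled code.
#'
#' @param seq A DNA string.
#' @param q q-gram length.
#' @return A list with elements `q` and `directory`, the latter a named
#'   list mapping each q-gram to its sorted 1-based start positions.
#' @examples
#' qgram_index("ACGTACGT", 4)$directory
#' @export
qgram_index <- function(seq, q) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (q > n) {
    warning("q = ", q, " exceeds sequence length ", n, "; empty index")
    return(list(q = as.integer(q), directory = list()))
  }
  starts <- seq_len(n - q + 1L)
  grams <- substring(seq, starts, starts + q - 1L)
  ok <- !grepl("[^ACGT]", grams)
  directory <- split(starts[ok], grams[ok])
  list(q = as.integer(q), directory = directory[order(names(directory))])
}

#' SWIFT filtration: find candidate parallelograms
#'
#' Streams the q-grams of `query` against a q-gram index of `db` and
#' counts q-hits in overlapping bins of `delta + e` consecutive diagonals
#' (diagonal = db position - query position). A bin whose counter reaches
#' `tau` with inter-hit column gaps of at most `w - q` is emitted as a
#' SWIFT hit: a parallelogram of the dotplot guaranteed (for `q = s_min`)
#' to intersect every epsilon-match in at least one epsilon-core.
#' Emitted windows are widened by `e` columns and diagonals on each side
#' (then clipped to the sequences) so that the banded verification can
#' realize alignments touching the parallelogram border.
#'
#' @param db,query DNA strings.
#' @param params An `eps_params` object from [derive_params()].
#' @return A data.frame with one row per hit: `db_begin`, `db_end`,
#'   `q_begin`, `q_end` (1-based inclusive), `diag_min`, `diag_max`,
#'   `count` (q-hits counted). Rows are ordered by non-decreasing query
#'   end column.
#' @export
swift_hits <- function(db, query, params) {
  stopifnot(inherits(params, "eps_params"))
  h <- cpp_swift_hits(ensure_upper(db), ensure_upper(query),
                      params$q, params$tau, params$e, params$w, params$delta)
  h$db_begin <- h$db_begin + 1L
  h$q_begin <- h$q_begin + 1L
  h
}

# brute-force q-hit recount used by tests: common q-grams of the hit's
# windows restricted to its diagonal band
count_qhits_in_hit <- function(db, query, hit, q) {
  dbw <- substr(db, hit$db_begin, hit$db_end)
  qw <- substr(query, hit$q_begin, hit$q_end)
  idx <- qgram_index(dbw, q)$directory
  qidx <- qgram_index(qw, q)$directory
  total <- 0L
  for (g in intersect(names(idx), names(qidx))) {
    for (i in idx[[g]]) for (j in qidx[[g]]) {
      d <- (hit$db_begin - 1L + i - 1L) - (hit$q_begin - 1L + j - 1L)
      if (d >= hit$diag_min && d <= hit$diag_max) total <- total + 1L
    }
  }
  total
}
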