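# Planted-alignment simulation, the 10%-coverage sensitivity metric, and
# the brute-force reference enumerator.

BASES <- c("A", "C", "G", "T")

# one planted alignment: column sequence of length L with exactly k error
# columns at interior positions, types drawn uniformly from mismatch /
# insertion / deletion, rejecting adjacent insertion+deletion pairs
# (which would silently cancel and change the realized error rate)
plant_columns <- function(L, k) {
  if (k == 0) return(rep("=", L))
  stopifnot(L - 2 >= k)
  repeat {
    pos <- sort(sample(2:(L - 1), k))
    v <- rep("=", L)
    v[pos] <- sample(c("X", "I", "D"), k, replace = TRUE)
    bad <- any((v[-L] == "I" & v[-1] == "D") |
               (v[-L] == "D" & v[-1] == "I"))
    if (!bad) return(v)
  }
}

# non-overlapping placement of n segments of the given lengths into a
# sequence of length total, separated by at least `gap` positions:
# random composition of the slack into n + 1 inter-segment spacers
place_segments <- function(total, lens, gap) {
  n <- length(lens)
  slack <- total - sum(lens) - (n - 1) * gap
  if (slack < 0)
    stop("cannot place ", n, " planted segments of total length ",
         sum(lens), " (plus ", gap, " bp spacing) into ", total, " bp",
         call. = FALSE)
  extras <- tabulate(sample.int(n + 1, slack, replace = TRUE), nbins = n + 1)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + extras[i]
    starts[i] <- pos + 1L
    pos <- pos + lens[i] + gap
  }
  starts
}

#' Simulate a sequence pair with planted local alignments
#'
#' Generates two uniform i.i.d. random DNA sequences and plants
#' `n_planted` local alignments: for each, a random column sequence of a
#' length drawn from `len_range` with exactly `floor(rate * length)`
#' error columns (mismatches, insertions, deletions in equal proportion,
#' never an adjacent insertion+deletion pair) is realized as a segment
#' pair written into both sequences. Planted segments are non-overlapping
#' and separated by at least `n0_gap` random positions in each sequence,
#' so the planted matches are unambiguously maximal. Fully reproducible
#' from `seed`.
#'
#' @param db_len,q_len Sequence lengths.
#' @param n_planted Number of planted alignments.
#' @param len_range Two integers: alignment length bounds (columns).
#' @param rate Planted error rate: a single value, or a vector from which
#'   one rate is drawn uniformly per planted alignment.
#' @param seed Integer RNG seed.
#' @param n0_gap Minimal random spacing between planted segments
#'   (default 50).
#' @return A list with `db`, `query` (DNA strings) and `truth`, a
#'   data.frame of planted records: 1-based inclusive intervals in both
#'   sequences, `length` (columns), `errors`, `rate`, and the realized
#'   `columns` string.
#' @examples
#' sim <- simulate_pair(2000, 2000, 3, c(50, 100), 0.1, seed = 7)
#' sim$truth[, 1:6]
#' @export
simulate_pair <- function(db_len, q_len, n_planted, len_range = c(50, 200),
                          rate = 0.1, seed = 1, n0_gap = 50) {
  set.seed(seed)
  db <- sample(BASES, db_len, replace = TRUE)
  query <- sample(BASES, q_len, replace = TRUE)

  if (n_planted == 0) {
    return(list(db = paste(db, collapse = ""),
                query = paste(query, collapse = ""),
                truth = data.frame(db_begin = integer(0), db_end = integer(0),
                                   q_begin = integer(0), q_end = integer(0),
                                   length = integer(0), errors = integer(0),
                                   rate = numeric(0),
                                   columns = character(0))))
  }

  L <- len_range[1] - 1L +
    sample.int(len_range[2] - len_range[1] + 1L, n_planted, replace = TRUE)
  r <- if (length(rate) > 1) sample(rate, n_planted, replace = TRUE)
       else rep(rate, n_planted)
  cols <- lapply(seq_len(n_planted), function(i) {
    plant_columns(L[i], as.integer(floor(r[i] * L[i] + 1e-9)))
  })
  db_lens <- vapply(cols, function(v) sum(v != "I"), integer(1))
  q_lens <- vapply(cols, function(v) sum(v != "D"), integer(1))
  db_starts <- place_segments(db_len, db_lens, n0_gap)
  q_starts <- place_segments(q_len, q_lens, n0_gap)

  for (i in seq_len(n_planted)) {
    v <- cols[[i]]
    seg_db <- sample(BASES, db_lens[i], replace = TRUE)
    seg_q <- character(q_lens[i])
    di <- 0L; qi <- 0L
    for (cv in v) {
      if (cv == "=") {
        di <- di + 1L; qi <- qi + 1L
        seg_q[qi] <- seg_db[di]
      } else if (cv == "X") {
        di <- di + 1L; qi <- qi + 1L
        seg_q[qi] <- sample(setdiff(BASES, seg_db[di]), 1)
      } else if (cv == "D") {
        di <- di + 1L
      } else {
        qi <- qi + 1L
        seg_q[qi] <- sample(BASES, 1)
      }
    }
    db[db_starts[i]:(db_starts[i] + db_lens[i] - 1L)] <- seg_db
    query[q_starts[i]:(q_starts[i] + q_lens[i] - 1L)] <- seg_q
  }

  truth <- data.frame(
    db_begin = db_starts, db_end = db_starts + db_lens - 1L,
    q_begin = q_starts, q_end = q_starts + q_lens - 1L,
    length = L, errors = vapply(cols, function(v) sum(v != "="), integer(1)),
    rate = r,
    columns = vapply(cols, paste, character(1), collapse = ""))
  stopifnot(truth$errors <= floor(truth$rate * truth$length + 1e-9),
            substr(truth$columns, 1, 1) == "=",
            substr(truth$columns, truth$length, truth$length) == "=")
  list(db = paste(db, collapse = ""), query = paste(query, collapse = ""),
       truth = truth)
}

#' Coverage-based sensitivity of a reported match set
#'
#' For each planted truth record, the fraction of its alignment columns
#' whose (db, query) coordinate pair lies inside some reported match's db
#' and query intervals. A record covered by less than 10% of its columns
#' counts as missed.
#'
#' @param reported A data.frame of reported matches (1-based inclusive
#'   `db_begin`, `db_end`, `q_begin`, `q_end`).
#' @param truth The `truth` data.frame from [simulate_pair()].
#' @return A list with `per_match` (data.frame of `covered` fractions and
#'   `missed` flags), `missed_pct` (percentage of missed records; `NA`
#'   for empty truth), and `n_truth`.
#' @export
coverage <- function(reported, truth) {
  n <- nrow(truth)
  if (n == 0)
    return(list(per_match = data.frame(covered = numeric(0),
                                       missed = logical(0)),
                missed_pct = NA_real_, n_truth = 0L))
  covered <- numeric(n)
  for (i in seq_len(n)) {
    v <- strsplit(truth$columns[i], "")[[1]]
    dbpos <- truth$db_begin[i] - 1L + cumsum(v != "I")
    qpos <- truth$q_begin[i] - 1L + cumsum(v != "D")
    dbpos <- pmax(dbpos, truth$db_begin[i])
    qpos <- pmax(qpos, truth$q_begin[i])
    inside <- rep(FALSE, length(v))
    for (j in seq_len(nrow(reported))) {
      inside <- inside |
        (dbpos >= reported$db_begin[j] & dbpos <= reported$db_end[j] &
         qpos >= reported$q_begin[j] & qpos <= reported$q_end[j])
    }
    covered[i] <- mean(inside)
  }
  missed <- covered < 0.1
  list(per_match = data.frame(covered = covered, missed = missed),
       missed_pct = 100 * mean(missed), n_truth = n)
}

#' Brute-force enumeration of maximal epsilon-matches
#'
#' Independent reference for the full pipeline: one banded DP per
#' match-character start cell enumerates, for every end cell, the
#' canonical score-optimal alignment (score, length, errors, X-drop
#' state); every alignment with non-negative scaled score, length at
#' least `n0`, match-bounded ends and no epsilon-X-drop is a candidate,
#' and candidates are reduced to the maximal set by the overlap rule
#' (drop a shorter overlapping match without a unique part of length
#' `n0`). Quadratic in the sequence lengths per start cell: refuses
#' inputs with `|db| * |query| > 1e5`.
#'
#' @param db,query DNA strings.
#' @param params An `eps_params` object.
#' @return A data.frame of matches with 1-based inclusive coordinates,
#'   `length` and `errors`, sorted by `(db_begin, q_begin)`.
#' @export
bruteforce_eps_matches <- function(db, query, params) {
  if (nchar(db) * as.numeric(nchar(query)) > 1e5)
    stop("brute-force oracle refuses |db| * |query| > 1e5", call. = FALSE)
  out <- cpp_bruteforce(ensure_upper(db), ensure_upper(query),
                        params$match_scaled, params$eps$b, params$n0,
                        params$xdrop_scaled)
  out$db_begin <- out$db_begin + 1L
  out$q_begin <- out$q_begin + 1L
  out
}

#' Run a planted-alignment sensitivity benchmark
#'
#' For each setting, simulates a sequence pair with planted alignments,
#' runs the aligner, and reports the missed percentage under the
#' 10%-coverage criterion.
#'
#' @param config A list of settings; each setting is a list with fields
#'   `name`, `db_len`, `q_len`, `n_planted`, `len_range`, `rate` (single
#'   value or vector for per-match sampling), `eps`, `n0`, `x_drop`,
#'   `seed`.
#' @param csv Optional path: write the table as CSV.
#' @return A data.frame with columns `setting`, `n_truth`, `n_reported`,
#'   `missed_pct`.
#' @export
run_benchmark <- function(config, csv = NULL) {
  if (length(config) == 0) {
    out <- data.frame(setting = character(0), n_truth = integer(0),
                      n_reported = integer(0), missed_pct = numeric(0))
    if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
    return(out)
  }
  rows <- lapply(config, function(cf) {
    sim <- simulate_pair(cf$db_len, cf$q_len, cf$n_planted, cf$len_range,
                         cf$rate, cf$seed,
                         n0_gap = cf$n0)
    params <- derive_params(cf$eps, cf$n0, cf$x_drop)
    matches <- eps_align(sim$db, sim$query, params)
    cov <- coverage(matches, sim$truth)
    data.frame(setting = cf$name, n_truth = cov$n_truth,
               n_reported = nrow(matches), missed_pct = cov$missed_pct)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(setting = character(0),
                                      n_truth = integer(0),
                                      n_reported = integer(0),
                                      missed_pct = numeric(0))
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
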