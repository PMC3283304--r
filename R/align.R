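#' Find all maximal epsilon-matches between two sequences
#'
#' The full pipeline: SWIFT q-gram filtration ([swift_hits()]) followed
#' by the five-step exact verification per hit ([verify_hit()]) and a
#' global overlap removal ([remove_overlaps()]). Reports every local
#' alignment of length at least `n0` with error rate at most epsilon
#' under edit distance that contains no epsilon-X-drop and is maximal
#' (not overlapped by a longer match unless its unique part has length
#' `n0`).
#'
#' @param db,query DNA strings over \{A,C,G,T,N\}.
#' @param params An `eps_params` object from [derive_params()].
#' @param both_strands Also search `db` against the reverse complement of
#'   `query` (default `FALSE`); minus-strand matches are reported on
#'   forward query coordinates with `strand == "-"` and their `columns`
#'   in reverse-complement orientation.
#' @return A data.frame with one row per match: 1-based inclusive
#'   `db_begin`, `db_end`, `q_begin`, `q_end`, `strand`, `length`
#'   (columns), `errors`, `score` (scaled), `identity` (percent), and
#'   the `columns` string ('=' match, 'X' mismatch, 'I'/'D' indels).
#' @examples
#' p <- derive_params("0.1", 20, x_drop = 10)
#' s <- paste(rep("ACGTTGCAAC", 5), collapse = "")
#' eps_align(s, s, p)[, 1:8]
#' @export
eps_align <- function(db, query, params, both_strands = FALSE) {
  db <- prep_seq(db)
  query <- prep_seq(query)
  fwd <- align_one_strand(db, query, params)
  fwd$strand <- rep("+", nrow(fwd))
  out <- fwd
  if (both_strands) {
    qrc <- prep_seq(revcomp(query))
    rev <- align_one_strand(db, qrc, params)
    if (nrow(rev) > 0) {
      qlen <- nchar(query)
      qb <- qlen - rev$q_end + 1L
      qe <- qlen - rev$q_begin + 1L
      rev$q_begin <- qb
      rev$q_end <- qe
      rev$strand <- "-"
      out <- rbind(fwd, rev)
    }
  }
  out <- out[order(out$db_begin, out$q_begin, out$db_end, out$q_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("db_begin", "db_end", "q_begin", "q_end", "strand", "length",
          "errors", "score", "identity", "columns")]
}

align_one_strand <- function(db, query, params) {
  db <- prep_seq(db)
  query <- prep_seq(query)
  hits <- unique(swift_hits(db, query, params))
  seen <- new.env(parent = emptyenv())
  matches <- list()
  for (k in seq_len(nrow(hits))) {
    found <- verify_hit(hits[k, ], db, query, params, seen = seen)
    matches <- c(matches, found)
  }

  # Global overlap removal with chain resolution: dropping a match that
  # is dominated by a longer one can expose a shorter co-located match
  # from the same core (maximal in the final set although dominated by
  # the dropped intermediate). Re-search the cores of dominated matches
  # under the constraint that candidates must survive against the kept
  # set, until the reduction is stable.
  mkey <- function(m) paste(m$db_begin, m$db_end, m$q_begin, m$q_end)
  searched <- character(0)
  for (round in 1:8) {
    red <- remove_overlaps(matches_to_df(matches), params)
    kept_keys <- paste(red$db_begin, red$db_end, red$q_begin, red$q_end)
    kept_sig <- paste(sort(kept_keys), collapse = ";")
    keys <- vapply(matches, mkey, character(1))
    todo <- which(!(keys %in% kept_keys) &
                    !vapply(matches, function(m) is.null(m$ctx), logical(1)) &
                    !(paste(keys, kept_sig) %in% searched))
    if (length(todo) == 0) break
    constraint <- function(dbb, dbe, qb, qe) {
      ovd <- pmin(red$db_end, dbe) - pmax(red$db_begin, dbb) + 1L
      ovq <- pmin(red$q_end, qe) - pmax(red$q_begin, qb) + 1L
      dom <- ovd > 0 & ovq > 0 &
        pmax((dbe - dbb + 1L) - ovd, (qe - qb + 1L) - ovq) < params$n0
      !any(dom)
    }
    have <- keys
    added <- FALSE
    for (i in todo) {
      searched <- c(searched, paste(keys[i], kept_sig))
      ctx <- matches[[i]]$ctx
      res <- longest_eps_match(ctx$core, ctx$bands, db, query, params,
                               constraint = constraint)
      for (r in res) {
        if (!(mkey(r) %in% have)) {
          r$ctx <- ctx
          matches[[length(matches) + 1L]] <- r
          have <- c(have, mkey(r))
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  remove_overlaps(matches_to_df(matches), params)
}

matches_to_df <- function(matches) {
  if (length(matches) == 0) {
    return(data.frame(db_begin = integer(0), db_end = integer(0),
                      q_begin = integer(0), q_end = integer(0),
                      length = integer(0), errors = integer(0),
                      score = numeric(0), identity = numeric(0),
                      columns = character(0)))
  }
  df <- data.frame(
    db_begin = vapply(matches, `[[`, integer(1), "db_begin"),
    db_end = vapply(matches, `[[`, integer(1), "db_end"),
    q_begin = vapply(matches, `[[`, integer(1), "q_begin"),
    q_end = vapply(matches, `[[`, integer(1), "q_end"),
    length = vapply(matches, `[[`, integer(1), "length"),
    errors = vapply(matches, `[[`, integer(1), "errors"),
    score = vapply(matches, `[[`, numeric(1), "score"),
    columns = vapply(matches, `[[`, character(1), "columns"))
  df$identity <- 100 * (df$length - df$errors) / df$length
  df
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Align all record pairs of two FASTA sets
#'
#' Runs [eps_align()] for every (db record, query record) pair and binds
#' the results with `db_id` and `q_id` columns.
#'
#' @param db_records,query_records Named character vectors as returned by
#'   [read_fasta()].
#' @inheritParams eps_align
#' @return A data.frame as [eps_align()] plus `db_id` and `q_id`.
#' @export
eps_align_sets <- function(db_records, query_records, params,
                           both_strands = TRUE) {
  out <- list()
  for (di in names(db_records)) {
    for (qi in names(query_records)) {
      m <- eps_align(db_records[[di]], query_records[[qi]], params,
                     both_strands = both_strands)
      if (nrow(m) > 0) {
        m$db_id <- di
        m$q_id <- qi
        out[[length(out) + 1L]] <- m
      }
    }
  }
  if (length(out) == 0) {
    empty <- matches_to_df(list())
    empty$strand <- character(0)
    empty$db_id <- character(0)
    empty$q_id <- character(0)
    return(empty)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
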