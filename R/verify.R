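# Verification of SWIFT hits: epsilon-core identification (banded
# Waterman-Eggert), X-drop core splitting, gapped X-drop extension,
# maximal-match cutting via bestEnds, and overlap removal.
#
# Alignment columns are encoded as a string over
#   '='  match
#   'X'  mismatch
#   'D'  consumes db only (deletion in the query)
#   'I'  consumes query only (insertion in the query)

# uppercase exactly once per pipeline run: eps_align() marks prepared
# strings with an attribute so the per-hit module calls skip the scan
prep_seq <- function(s) structure(toupper(s), prepared = TRUE)
ensure_upper <- function(s) if (isTRUE(attr(s, "prepared"))) s else toupper(s)

db_span <- function(columns) nchar(columns) - lengths(regmatches(columns, gregexpr("I", columns, fixed = TRUE)))
q_span <- function(columns) nchar(columns) - lengths(regmatches(columns, gregexpr("D", columns, fixed = TRUE)))
n_errors <- function(columns) nchar(columns) - lengths(regmatches(columns, gregexpr("=", columns, fixed = TRUE)))

# longest run of consecutive match columns
max_match_run <- function(columns) {
  vapply(columns, function(s) {
    r <- regmatches(s, gregexpr("=+", s))[[1]]
    if (length(r) == 0) 0L else max(nchar(r))
  }, integer(1), USE.NAMES = FALSE)
}

scaled_score <- function(columns, params) {
  k <- n_errors(columns)
  (nchar(columns) - k) * params$match_scaled + k * params$error_scaled
}

# TRUE if the column string contains a run scoring <= -xdrop_scaled
has_eps_xdrop <- function(columns, params) {
  if (nchar(columns) == 0) return(FALSE)
  v <- strsplit(columns, "")[[1]]
  sc <- ifelse(v == "=", params$match_scaled, params$error_scaled)
  p <- cumsum(sc)
  mx <- cummax(c(0, p[-length(p)]))
  any(p - mx <= -params$xdrop_scaled)
}

#' Step 1: identify epsilon-cores in a SWIFT hit
#'
#' Runs a banded Waterman-Eggert search inside the hit's parallelogram:
#' all non-overlapping local alignments with scaled score at least
#' `a * s_min` under the epsilon-scoring (match `+a`, error `a - b`) are
#' returned as cores. Iterated best-alignment with trace clearing and
#' recomputation; the DP is restricted to the hit's diagonal band.
#'
#' @param hit One row of [swift_hits()] output (or an equivalent list
#'   with 1-based inclusive `db_begin`, `db_end`, `q_begin`, `q_end` and
#'   `diag_min`, `diag_max`).
#' @param db,query DNA strings.
#' @param params An `eps_params` object.
#' @return A list of cores, each a list with `db_begin`, `q_begin`
#'   (1-based), `columns`, `score` (scaled), `errors`. May be empty
#'   (false-positive hit).
#' @export
find_cores <- function(hit, db, query, params) {
  cores <- cpp_find_cores(ensure_upper(db), ensure_upper(query),
                          hit$db_begin - 1L, hit$db_end,
                          hit$q_begin - 1L, hit$q_end,
                          hit$diag_min, hit$diag_max,
                          params$match_scaled, params$eps$b,
                          params$min_score_scaled)
  lapply(cores, function(co) {
    co$db_begin <- co$db_begin + 1L
    co$q_begin <- co$q_begin + 1L
    co
  })
}

#' Step 2: split a core at epsilon-X-drops
#'
#' Decomposes a core's column sequence so that no piece contains a run of
#' columns with scaled score at most `-X*(b - a)`. Pieces inherit their
#' coordinates and are trimmed to begin and end with match columns. Only
#' the leftmost piece is flagged for left extension and only the
#' rightmost for right extension; middle pieces skip the extension step
#' (it would immediately run into the detected drops).
#'
#' @param core A core as returned by [find_cores()].
#' @param params An `eps_params` object.
#' @return A list of `list(core =, extend_left =, extend_right =)`.
#' @export
split_core_at_xdrops <- function(core, params) {
  v <- strsplit(core$columns, "")[[1]]
  L <- length(v)
  sc <- ifelse(v == "=", params$match_scaled, params$error_scaled)
  p <- c(0, cumsum(sc))  # p[i+1] = score after column i
  DT <- params$xdrop_scaled

  pieces <- list()
  start <- 1L
  while (start <= L) {
    while (start <= L && v[start] != "=") start <- start + 1L
    if (start > L) break
    mx <- p[start]; mxpos <- start - 1L
    i <- start
    cut <- 0L
    while (i <= L) {
      if (p[i + 1L] <= mx - DT) { cut <- i; break }
      if (p[i + 1L] > mx) { mx <- p[i + 1L]; mxpos <- i }
      i <- i + 1L
    }
    end <- if (cut > 0L) mxpos else L
    while (end >= start && v[end] != "=") end <- end - 1L
    if (end >= start) pieces[[length(pieces) + 1L]] <- c(start, end)
    if (cut == 0L) break
    start <- cut + 1L
  }

  out <- vector("list", length(pieces))
  for (k in seq_along(pieces)) {
    s <- pieces[[k]][1]; e <- pieces[[k]][2]
    lead <- if (s > 1) paste(v[1:(s - 1)], collapse = "") else ""
    cols <- paste(v[s:e], collapse = "")
    out[[k]] <- list(
      core = list(db_begin = core$db_begin + db_span(lead),
                  q_begin = core$q_begin + q_span(lead),
                  columns = cols,
                  score = scaled_score(cols, params),
                  errors = n_errors(cols)),
      extend_left = k == 1L,
      extend_right = k == length(pieces))
  }
  out
}

# A match whose alignment begins or ends with an indel block that merely
# re-pairs a repeated subsequence is a padded variant of a shorter match
# with the same number of match columns (the extra columns are all
# errors). Such degenerate boundary inflations are excluded from the
# maximal set, here and in the brute-force reference.
is_boundary_padded <- function(m, db, query, n0) {
  v <- strsplit(m$columns, "")[[1]]
  L <- length(v)
  chars <- function(s, pos) substring(s, pos, pos)
  # trailing pattern [ID]^t =^r
  i <- L
  while (i >= 1 && v[i] == "=") i <- i - 1L
  r <- L - i
  if (r >= 1 && i >= 1 && v[i] != "X") {
    type <- v[i]
    j <- i
    while (j >= 1 && v[j] == type) j <- j - 1L
    t <- i - j
    if (L - t >= n0) {
      idx <- 0:(r - 1L)
      eq <- if (type == "I")
        chars(db, m$db_end - idx) == chars(query, m$q_end - t - idx)
      else
        chars(db, m$db_end - t - idx) == chars(query, m$q_end - idx)
      if (all(eq)) return(TRUE)
    }
  }
  # leading pattern =^r [ID]^t
  i <- 1L
  while (i <= L && v[i] == "=") i <- i + 1L
  r <- i - 1L
  if (r >= 1 && i <= L && v[i] != "X") {
    type <- v[i]
    j <- i
    while (j <= L && v[j] == type) j <- j + 1L
    t <- j - i
    if (L - t >= n0) {
      idx <- 0:(r - 1L)
      eq <- if (type == "I")
        chars(db, m$db_begin + idx) == chars(query, m$q_begin + t + idx)
      else
        chars(db, m$db_begin + t + idx) == chars(query, m$q_begin + idx)
      if (all(eq)) return(TRUE)
    }
  }
  FALSE
}

empty_extension <- function() {
  list(best_score = 0, best_di = 0, best_dj = 0,
       diag_lo = 0, diag_hi = 0, max_di = 0, max_dj = 0)
}

#' Step 3: gapped X-drop extension of a core
#'
#' Score-only banded extension from the core ends by anti-diagonals with
#' the epsilon-adjusted scoring; cells whose score falls `X*(b - a)` or
#' more below the running best are pruned, and the sweep stops when a
#' whole anti-diagonal is dead. Per direction the best end cell and the
#' band of diagonals that was ever alive are reported; the band delimits
#' the Step-4 DP. If the core is part of an epsilon-match without
#' epsilon-X-drop, the extended region spans that match.
#'
#' @param core A core (one piece from [split_core_at_xdrops()]).
#' @param db,query DNA strings.
#' @param params An `eps_params` object.
#' @param extend_left,extend_right Direction flags from Step 2.
#' @return `list(left =, right =)`, each with `best_score`, `best_di`,
#'   `best_dj`, `diag_lo`, `diag_hi`, `max_di`, `max_dj` in the
#'   direction-local frame (`di` = characters consumed in db outward
#'   from the core end).
#' @export
xdrop_extend <- function(core, db, query, params,
                         extend_left = TRUE, extend_right = TRUE) {
  db <- ensure_upper(db); query <- ensure_upper(query)
  a <- params$match_scaled; b <- params$eps$b
  right <- if (extend_right) {
    cpp_xdrop_extend(db, query,
                     core$db_begin - 1L + db_span(core$columns),
                     core$q_begin - 1L + q_span(core$columns),
                     1L, a, b, params$xdrop_scaled)
  } else empty_extension()
  left <- if (extend_left) {
    cpp_xdrop_extend(db, query, core$db_begin - 1L, core$q_begin - 1L,
                     -1L, a, b, params$xdrop_scaled)
  } else empty_extension()
  list(left = left, right = right)
}

# Reduce raw end cells to one bestEnds entry per extension length, then
# apply the maximality pruning: an entry for length l survives only if
# the next existing entry gains less than a full match over it (a gain of
# a full match means the end is followed by a match column, so no maximal
# match ends there). The last entry and the empty extension always stay.
# Equal-score ties keep the cell that yields the lexicographically
# smallest final match coordinates (left side: the farther cell; right
# side: the nearer cell), so that ties resolve identically no matter
# which core seeded the match.
build_best_ends <- function(cells, a, dir = 1L) {
  entries <- data.frame(len = 0L, score = 0, di = 0L, dj = 0L)
  if (nrow(cells) > 0) {
    cells <- cells[order(cells$len, -cells$score,
                         dir * cells$di, dir * cells$dj), , drop = FALSE]
    first <- !duplicated(cells$len)
    entries <- rbind(entries, cells[first, c("len", "score", "di", "dj")])
  }
  # equally-scoring alternate end cells are looked up lazily from the
  # full sorted cell table when a chosen trace proves inadmissible
  attr(entries, "cells") <- cells
  entries
}

# alternate end cells for one entry: all cells of that length with the
# same (maximal) score, in canonical preference order
alt_cells <- function(entries, entry) {
  if (entry$len == 0) return(entry)
  cells <- attr(entries, "cells")
  alt <- cells[cells$len == entry$len & cells$score == entry$score, ,
               drop = FALSE]
  if (nrow(alt) == 0) entry else alt
}

# Exhaustive start/end combination search: the longest total alignment
# (left extension + core + right extension) with non-negative scaled
# score and length >= max(n0, lower_bound). Among equal-length optima the
# higher-scoring (fewer-error) combination wins, then the one with the
# larger left extension (leftmost start) - the same order in which the
# overlap-removal step ranks tied matches.
combine_extensions <- function(leftE, rightE, core_len, core_score, n0,
                               lower_bound = 0L, exclude = character(0),
                               coord_ok = NULL, core_coords = NULL) {
  lo <- order(-leftE$len)
  llen <- leftE$len[lo]; lscore <- leftE$score[lo]
  ldi <- leftE$di[lo]; ldj <- leftE$dj[lo]
  ro <- order(-rightE$len)
  rlen <- rightE$len[ro]; rscore <- rightE$score[ro]
  rdi <- rightE$di[ro]; rdj <- rightE$dj[ro]

  best <- NULL
  need <- max(n0, lower_bound + 1L)
  for (i in seq_along(llen)) {
    if (length(rlen) == 0) break
    if (llen[i] + core_len + rlen[1] < need) break
    totals <- llen[i] + core_len + rlen
    scs <- lscore[i] + core_score + rscore
    cand <- which(totals >= need & scs >= 0)
    if (length(exclude) > 0 && length(cand) > 0)
      cand <- cand[!(paste(llen[i], rlen[cand]) %in% exclude)]
    for (j in cand) {
      if (!is.null(coord_ok) &&
          !coord_ok(core_coords[1] - ldi[i], core_coords[2] + rdi[j],
                    core_coords[3] - ldj[i], core_coords[4] + rdj[j])) next
      if (is.null(best) || totals[j] > best$length || scs[j] > best$score) {
        best <- list(left = data.frame(len = llen[i], score = lscore[i],
                                       di = ldi[i], dj = ldj[i]),
                     right = data.frame(len = rlen[j], score = rscore[j],
                                        di = rdi[j], dj = rdj[j]),
                     length = totals[j], score = scs[j])
      }
      need <- totals[j]  # equal lengths accepted only on score improvement
      break
    }
  }
  best
}

#' Step 4: cut the maximal epsilon-matches out of an extended core
#'
#' Builds, per flagged direction, a `bestEnds` list (for each extension
#' length the best-scoring end cell of the banded DP, with unnormalized
#' scores), prunes it by the flanked-by-errors rule, and exhaustively
#' combines start and end candidates to find the longest alignment with
#' error rate at most epsilon and length at least `n0`. Further
#' co-located maximal matches (sharing the core but with a unique part of
#' length `n0` to the left or right) are found by recursing on reduced
#' lists. Tracebacks of the chosen extensions produce full column
#' sequences.
#'
#' @param core A core piece.
#' @param bands The result of [xdrop_extend()] for that piece.
#' @param db,query DNA strings.
#' @param params An `eps_params` object.
#' @return A list of epsilon-matches, each a list with 1-based inclusive
#'   `db_begin`, `db_end`, `q_begin`, `q_end`, plus `columns`, `length`,
#'   `errors`, `score`. Empty if the extended region is shorter than
#'   `n0`.
#' @export
longest_eps_match <- function(core, bands, db, query, params,
                              constraint = NULL) {
  db <- ensure_upper(db); query <- ensure_upper(query)
  a <- params$match_scaled; b <- params$eps$b
  core_len <- nchar(core$columns)
  core_coords <- c(core$db_begin, core$db_begin - 1L + db_span(core$columns),
                   core$q_begin, core$q_begin - 1L + q_span(core$columns))
  if (core_len + bands$left$max_di + bands$left$max_dj +
      bands$right$max_di + bands$right$max_dj < params$n0) return(list())

  r_origin <- c(core$db_begin - 1L + db_span(core$columns),
                core$q_begin - 1L + q_span(core$columns))
  l_origin <- c(core$db_begin - 1L, core$q_begin - 1L)

  # the Step-4 band is the Step-3 alive band widened by a safety margin:
  # a drop-free trace can step a few diagonals beyond the cells the
  # score-only extension kept alive
  margin <- params$e + min(params$x_drop, 10)
  widen <- function(ext) {
    if (ext$max_di == 0 && ext$max_dj == 0) return(ext)
    ext$diag_lo <- ext$diag_lo - margin
    ext$diag_hi <- ext$diag_hi + margin
    ext$max_di <- ext$max_di + margin
    ext$max_dj <- ext$max_dj + margin
    ext
  }
  bands <- list(left = widen(bands$left), right = widen(bands$right))

  side_entries <- function(ext, origin, dir) {
    if (ext$max_di == 0 && ext$max_dj == 0)
      return(build_best_ends(data.frame(len = integer(0), score = numeric(0),
                                        di = integer(0), dj = integer(0)), a))
    cells <- cpp_best_ends(db, query, origin[1], origin[2], dir,
                           ext$diag_lo, ext$diag_hi,
                           ext$max_di, ext$max_dj, a, b)
    build_best_ends(cells, a, dir)
  }
  leftE <- side_entries(bands$left, l_origin, -1L)
  rightE <- side_entries(bands$right, r_origin, 1L)

  trace_side <- function(ext, origin, dir, entry) {
    if (entry$len == 0) return("")
    cpp_extension_traceback(db, query, origin[1], origin[2], dir,
                            ext$diag_lo, ext$diag_hi,
                            ext$max_di, ext$max_dj,
                            entry$di, entry$dj, a, b)
  }

  results <- list()
  recurse <- function(lE, rE, depth) {
    if (depth > 16L) {
      warning("co-located match recursion depth cap reached", call. = FALSE)
      return(invisible())
    }
    # assemble the combined trace, then re-derive the canonical alignment
    # of the resulting substring pair (max score, then minimal length,
    # ties diagonal > deletion > insertion, first column fixed as the
    # boundary match) - the same canonical form the reference enumerator
    # evaluates, so that padding/X-drop admissibility and error counts
    # are judged on identical paths
    assemble <- function(lentry, rentry) {
      lcols <- trace_side(bands$left, l_origin, -1L, lentry)
      rcols <- trace_side(bands$right, r_origin, 1L, rentry)
      db_begin <- core$db_begin - db_span(lcols)
      db_end <- core$db_begin - 1L + db_span(core$columns) + db_span(rcols)
      q_begin <- core$q_begin - q_span(lcols)
      q_end <- core$q_begin - 1L + q_span(core$columns) + q_span(rcols)
      ui <- db_end - db_begin
      vi <- q_end - q_begin
      cols <- if (ui == 0 && vi == 0) "=" else {
        dd <- ui - vi
        bw <- ((ui + vi) * a) %/% b + 2L
        paste0("=", cpp_extension_traceback(
          db, query, db_begin, q_begin, 1L,
          min(0L, dd) - bw, max(0L, dd) + bw, ui, vi, ui, vi, a, b))
      }
      list(db_begin = db_begin, db_end = db_end,
           q_begin = q_begin, q_end = q_end,
           columns = cols, length = nchar(cols),
           errors = n_errors(cols),
           score = scaled_score(cols, params))
    }
    excl <- character(0)
    m <- NULL
    repeat {
      hit <- combine_extensions(lE, rE, core_len, core$score, params$n0,
                                exclude = excl, coord_ok = constraint,
                                core_coords = core_coords)
      if (is.null(hit)) return(invisible())
      # evaluate the chosen cells and every equally-scoring alternate end
      # cell; among the admissible traces keep the one the overlap
      # reduction would rank first (fewest errors, then longest exact
      # segment, then lexicographically smallest coordinates), so that
      # tied variants resolve here exactly as they do globally
      la <- alt_cells(leftE, hit$left)
      ra <- alt_cells(rightE, hit$right)
      for (li in seq_len(nrow(la))) {
        for (ri in seq_len(nrow(ra))) {
          cand <- assemble(la[li, ], ra[ri, ])
          ok <- substr(cand$columns, nchar(cand$columns),
                       nchar(cand$columns)) == "=" &&
            cand$length >= params$n0 && cand$score >= 0 &&
            !is_boundary_padded(cand, db, query, params$n0) &&
            !has_eps_xdrop(cand$columns, params)
          if (ok) {
            if (is.null(m)) m <- cand
            else {
              ra_m <- max_match_run(m$columns)
              ra_c <- max_match_run(cand$columns)
              ka <- c(-cand$length, cand$errors, -ra_c, cand$db_begin,
                      cand$q_begin, cand$db_end, cand$q_end)
              kb <- c(-m$length, m$errors, -ra_m, m$db_begin,
                      m$q_begin, m$db_end, m$q_end)
              d <- ka - kb
              first <- which(d != 0)[1]
              if (!is.na(first) && d[first] < 0) m <- cand
            }
          }
        }
      }
      if (!is.null(m)) break
      excl <- c(excl, paste(hit$left$len, hit$right$len))
    }
    results[[length(results) + 1L]] <<- m
    # co-located matches with a unique part >= n0 beyond either end
    recurse(lE[lE$len <= hit$left$len, , drop = FALSE],
            rE[rE$len >= hit$right$len + params$n0, , drop = FALSE],
            depth + 1L)
    recurse(lE[lE$len >= hit$left$len + params$n0, , drop = FALSE],
            rE[rE$len <= hit$right$len, , drop = FALSE],
            depth + 1L)
    invisible()
  }
  recurse(leftE, rightE, 1L)
  results
}

#' Step 5: remove duplicate and largely overlapping matches
#'
#' Canonical maximality reduction: matches are processed in order of
#' decreasing length (ties: fewer errors, then coordinates); a match is
#' discarded if it is identical to a kept match, or if it overlaps a kept
#' match in both sequences without a unique span of at least `n0` in
#' either. The result is sorted by `(db_begin, q_begin)`.
#'
#' @param matches A data.frame of matches (columns `db_begin`, `db_end`,
#'   `q_begin`, `q_end`, `length`, `errors`, ...).
#' @param params An `eps_params` object.
#' @return The reduced, sorted data.frame.
#' @export
remove_overlaps <- function(matches, params) {
  if (nrow(matches) == 0) return(matches)
  # intervals are handed over half-open, as the reducer expects
  mr <- if ("columns" %in% names(matches)) max_match_run(matches$columns)
        else matches$length - matches$errors
  keep <- cpp_reduce_overlaps(matches$db_begin, matches$db_end + 1L,
                              matches$q_begin, matches$q_end + 1L,
                              matches$length, matches$errors, mr,
                              params$n0)$keep
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Verify one SWIFT hit
#'
#' Orchestrates Steps 1-4 for a single hit with early exits (no cores;
#' all pieces too short even after extension; extended region shorter
#' than `n0`). Step 5 is applied globally over all hits by [eps_align()].
#'
#' @param hit One row of [swift_hits()] output.
#' @param db,query DNA strings.
#' @param params An `eps_params` object.
#' @param seen Optional environment used across hits to skip re-verifying
#'   a core already seen in an overlapping hit.
#' @return A list of epsilon-matches (see [longest_eps_match()]).
#' @export
verify_hit <- function(hit, db, query, params, seen = NULL) {
  matches <- list()
  for (core in find_cores(hit, db, query, params)) {
    if (!is.null(seen)) {
      key <- paste(core$db_begin, core$q_begin, core$columns, sep = "/")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
    }
    for (piece in split_core_at_xdrops(core, params)) {
      bands <- xdrop_extend(piece$core, db, query, params,
                            piece$extend_left, piece$extend_right)
      found <- longest_eps_match(piece$core, bands, db, query, params)
      # each match remembers its seeding piece so that a match dominated
      # in the global reduction can be re-searched under constraints
      found <- lapply(found, function(m) {
        m$ctx <- list(core = piece$core, bands = bands)
        m
      })
      matches <- c(matches, found)
    }
  }
  matches
}
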