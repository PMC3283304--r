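# FASTA input, GFF/text output, Karlin-Altschul E-values.

#' Read DNA sequences from a FASTA file
#'
#' Sequences are uppercased; characters outside \{A,C,G,T,N\} are mapped
#' to `N` with a warning reporting the count.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector (names = record ids, values = DNA
#'   strings).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("cannot parse FASTA file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0)
    stop("FASTA file ", path, " contains no records", call. = FALSE)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  bad <- vapply(gregexpr("[^ACGTN]", seqs), function(g)
    if (g[1] == -1L) 0L else length(g), integer(1))
  if (any(bad > 0)) {
    warning(sum(bad), " non-ACGTN character(s) in ", path,
            " mapped to N", call. = FALSE)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  empty <- !nzchar(seqs) | !nzchar(ids)
  if (any(empty))
    stop("FASTA file ", path, ": record '", ids[which(empty)[1]],
         "' has an empty id or sequence", call. = FALSE)
  names(seqs) <- ids
  seqs
}

#' Karlin-Altschul model for E-value annotation
#'
#' An ungapped Karlin-Altschul model with BLASTN-like unit scores
#' (match +1, mismatch -2; gap columns are scored as mismatches) and
#' uniform base frequencies. `lambda` is the positive root of
#' \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1}, found by uniroot; `K`
#' is fixed at 0.34, an approximation (the exact constants of the
#' original E-value computation are not recoverable).
#'
#' @return A list with `lambda`, `K`, `match`, `mismatch`.
#' @export
evalue_model <- function() {
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  lambda <- stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  list(lambda = lambda, K = 0.34, match = 1, mismatch = -2)
}

#' E-values for reported matches
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the database length, `n`
#' the total query length, and `S` the unit-scale score
#' `matches * 1 + errors * (-2)` of the alignment.
#'
#' @param matches A data.frame with `length` and `errors` columns.
#' @param db_len,query_len Sequence lengths m and n.
#' @param model A model from [evalue_model()].
#' @return Numeric vector of E-values.
#' @export
evalue <- function(matches, db_len, query_len, model = evalue_model()) {
  S <- (matches$length - matches$errors) * model$match +
    matches$errors * model$mismatch
  model$K * db_len * query_len * exp(-model$lambda * S)
}

#' Minimal E-value of the search parameters
#'
#' The E-value of the least significant match the parameters accept: a
#' length-`n0` alignment with `floor(eps*n0)` errors on the given
#' sequence lengths. Every reported match has an E-value at most this
#' large.
#'
#' @param params An `eps_params` object.
#' @inheritParams evalue
#' @return A single E-value.
#' @export
min_evalue <- function(params, db_len, query_len, model = evalue_model()) {
  evalue(data.frame(length = params$n0, errors = params$e),
         db_len, query_len, model)
}

columns_to_cigar <- function(columns) {
  v <- strsplit(columns, "")[[1]]
  op <- ifelse(v == "=" | v == "X", "M", v)
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

mutation_positions <- function(columns, q_begin) {
  v <- strsplit(columns, "")[[1]]
  qpos <- q_begin - 1L + cumsum(v != "D")
  qpos[v != "="]
}

#' Write matches as GFF
#'
#' One GFF v2 line per match: database id, source `epsaligner`, feature
#' `eps-matches`, 1-based inclusive database coordinates, percent
#' identity as score, strand, and an attribute column with the query id,
#' query range, E-value, CIGAR, error count and error positions.
#' Byte-deterministic for identical match lists.
#'
#' @param matches A data.frame from [eps_align()]/[eps_align_sets()];
#'   optional columns `db_id`, `q_id`, `evalue` default to `"db"`,
#'   `"query"`, `NA`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_gff <- function(matches, path) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write ", path, call. = FALSE))
  on.exit(close(con))
  lines <- "##gff-version 2"
  if (nrow(matches) > 0) {
    db_id <- if ("db_id" %in% names(matches)) matches$db_id else "db"
    q_id <- if ("q_id" %in% names(matches)) matches$q_id else "query"
    ev <- if ("evalue" %in% names(matches)) {
      sprintf("%.6g", matches$evalue)
    } else rep(".", nrow(matches))
    strand <- if ("strand" %in% names(matches)) matches$strand else "+"
    for (i in seq_len(nrow(matches))) {
      mut <- mutation_positions(matches$columns[i], matches$q_begin[i])
      attrs <- sprintf(
        "ID=%s;seq2Range=%d,%d;eValue=%s;cigar=%s;errors=%d;mutations=%s",
        q_id[i], matches$q_begin[i], matches$q_end[i], ev[i],
        columns_to_cigar(matches$columns[i]), matches$errors[i],
        paste(mut, collapse = ","))
      lines <- c(lines, paste(
        db_id[i], "epsaligner", "eps-matches",
        matches$db_begin[i], matches$db_end[i],
        sprintf("%.2f", matches$identity[i]),
        strand[i], ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a GFF file written by [write_gff()]
#'
#' @param path Path to the GFF file.
#' @return A data.frame with coordinates, identity, errors, strand, ids.
#' @export
read_gff_matches <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0)
    return(data.frame(db_id = character(0), db_begin = integer(0),
                      db_end = integer(0), q_id = character(0),
                      q_begin = integer(0), q_end = integer(0),
                      identity = numeric(0), errors = integer(0),
                      strand = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  attr1 <- function(a, key) sub(paste0(".*", key, "=([^;]*).*"), "\\1", a)
  a <- vapply(f, `[`, character(1), 9)
  rng <- strsplit(attr1(a, "seq2Range"), ",", fixed = TRUE)
  data.frame(
    db_id = vapply(f, `[`, character(1), 1),
    db_begin = as.integer(vapply(f, `[`, character(1), 4)),
    db_end = as.integer(vapply(f, `[`, character(1), 5)),
    q_id = attr1(a, "ID"),
    q_begin = as.integer(vapply(rng, `[`, character(1), 1)),
    q_end = as.integer(vapply(rng, `[`, character(1), 2)),
    identity = as.numeric(vapply(f, `[`, character(1), 6)),
    errors = as.integer(attr1(a, "errors")),
    strand = vapply(f, `[`, character(1), 7))
}

#' Write matches as human-readable text
#'
#' A coordinate header per match and, when the sequences are supplied,
#' the aligned rows with a midline. Byte-deterministic.
#'
#' @inheritParams write_gff
#' @param db,query Optional DNA strings used to render aligned rows
#'   (plus-strand matches only).
#' @export
write_text <- function(matches, path, db = NULL, query = NULL) {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write ", path, call. = FALSE))
  on.exit(close(con))
  out <- character(0)
  for (i in seq_len(nrow(matches))) {
    out <- c(out, sprintf(
      "match %d: db %d..%d query %d..%d strand %s length %d errors %d identity %.2f",
      i, matches$db_begin[i], matches$db_end[i],
      matches$q_begin[i], matches$q_end[i],
      if ("strand" %in% names(matches)) matches$strand[i] else "+",
      matches$length[i], matches$errors[i], matches$identity[i]))
    if (!is.null(db) && !is.null(query) &&
        (!"strand" %in% names(matches) || matches$strand[i] == "+")) {
      v <- strsplit(matches$columns[i], "")[[1]]
      di <- matches$db_begin[i] - 1L
      qi <- matches$q_begin[i] - 1L
      top <- mid <- bot <- character(length(v))
      for (k in seq_along(v)) {
        if (v[k] != "I") { di <- di + 1L; top[k] <- substr(db, di, di) }
        else top[k] <- "-"
        if (v[k] != "D") { qi <- qi + 1L; bot[k] <- substr(query, qi, qi) }
        else bot[k] <- "-"
        mid[k] <- if (v[k] == "=") "|" else " "
      }
      out <- c(out, paste0("  ", paste(top, collapse = "")),
               paste0("  ", paste(mid, collapse = "")),
               paste0("  ", paste(bot, collapse = "")), "")
    }
  }
  writeLines(out, con)
  invisible(path)
}

#' Dump SWIFT hits in BED-like form
#'
#' Six tab-separated columns: db id, 0-based half-open db interval, query
#' id, q-hit count, and the query interval. Debug aid.
#' @param hits Output of [swift_hits()].
#' @param path Output path.
#' @param db_id,q_id Record ids.
#' @export
write_swift_hits <- function(hits, path, db_id = "db", q_id = "query") {
  lines <- vapply(seq_len(nrow(hits)), function(i) {
    paste(db_id, hits$db_begin[i] - 1L, hits$db_end[i],
          q_id, hits$count[i],
          paste0(hits$q_begin[i] - 1L, "-", hits$q_end[i]), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
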