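# Five-step verification: cores, X-drop splitting, extension, maximal
# match cutting, overlap removal.

P10 <- derive_params("0.1", 20, x_drop = 3)

test_that("a shared exact 20-mer yields one all-match core", {
  set.seed(31)
  word <- random_dna(20)
  db <- paste0(random_dna(15), word, random_dna(15))
  qu <- paste0(random_dna(9), word, random_dna(21))
  cores <- find_cores(full_hit(db, qu), db, qu, P10)
  expect_gte(length(cores), 1)
  top <- cores[[1]]
  expect_gte(top$score, 20)
  expect_true(grepl("^=+$", substr(top$columns, 1, 20)) ||
                grepl(strrep("=", 20), top$columns))
})

test_that("windows below the core score threshold yield no cores", {
  # best local alignment here is a shared 5-mer: score 5 < s_min = 6
  db <- paste0("ACGTC", strrep("A", 30))
  qu <- paste0("ACGTC", strrep("T", 30))
  expect_length(find_cores(full_hit(db, qu), db, qu, P10), 0)
})

test_that("error-split segments become cores and rejoin at extension", {
  # 7 matches, one mismatch, 11 matches: under the epsilon-scoring the
  # 11-run (score 11) outscores the joined 19-column alignment (score
  # 18 - 9 = 9), so Waterman-Eggert reports the runs as separate cores;
  # the 19-column alignment is recovered by the extension step
  set.seed(32)
  seg <- random_dna(18)
  db <- paste0(substr(seg, 1, 7), "A", substr(seg, 8, 18))
  qu <- paste0(substr(seg, 1, 7), "C", substr(seg, 8, 18))
  p <- derive_params("0.1", 15, x_drop = 10)
  cores <- find_cores(full_hit(db, qu), db, qu, p)
  expect_equal(length(cores), 2)
  expect_equal(sort(nchar(vapply(cores, `[[`, character(1), "columns"))),
               c(7L, 11L))
  m <- eps_align(db, qu, p)
  expect_equal(nrow(m), 1)
  expect_equal(m$length, 19L)
  expect_equal(m$errors, 1L)
  expect_equal(m$score, 9)
})

test_that("a run of four error columns splits a core in two", {
  core <- list(db_begin = 10L, q_begin = 10L,
               columns = paste0(strrep("=", 12), "XXXX", strrep("=", 12)),
               score = 24 - 36, errors = 4L)
  pieces <- split_core_at_xdrops(core, P10)
  expect_length(pieces, 2)
  expect_true(pieces[[1]]$extend_left && !pieces[[1]]$extend_right)
  expect_true(!pieces[[2]]$extend_left && pieces[[2]]$extend_right)
  expect_equal(pieces[[1]]$core$columns, strrep("=", 12))
  expect_equal(pieces[[2]]$core$db_begin, 10L + 16L)
})

test_that("an error-free core passes Step 2 unchanged with both flags", {
  core <- list(db_begin = 1L, q_begin = 1L, columns = strrep("=", 20),
               score = 20, errors = 0L)
  pieces <- split_core_at_xdrops(core, P10)
  expect_length(pieces, 1)
  expect_true(pieces[[1]]$extend_left && pieces[[1]]$extend_right)
  expect_equal(pieces[[1]]$core$columns, core$columns)
})

test_that("two disjoint drops give three pieces, the middle unflagged", {
  core <- list(db_begin = 1L, q_begin = 1L,
               columns = paste0(strrep("=", 10), "XXXX", strrep("=", 10),
                                "XXXX", strrep("=", 10)),
               score = 30 - 72, errors = 8L)
  pieces <- split_core_at_xdrops(core, P10)
  expect_length(pieces, 3)
  expect_false(pieces[[2]]$extend_left || pieces[[2]]$extend_right)
})

test_that("no piece retains an epsilon-X-drop", {
  set.seed(33)
  for (i in 1:50) {
    cols <- paste(sample(c("=", "=", "=", "X", "I", "D"), 60, replace = TRUE),
                  collapse = "")
    s <- regmatches(cols, regexpr("=.*=", cols))
    if (length(s) == 0) next
    core <- list(db_begin = 5L, q_begin = 5L, columns = s,
                 score = epsaligner:::scaled_score(s, P10),
                 errors = epsaligner:::n_errors(s))
    for (pc in split_core_at_xdrops(core, P10)) {
      expect_false(epsaligner:::has_eps_xdrop(pc$core$columns, P10))
    }
  }
})

test_that("extension at the sequence boundary is empty", {
  s <- strrep("ACGT", 10)
  core <- list(db_begin = 1L, q_begin = 1L, columns = strrep("=", 20),
               score = 20, errors = 0L)
  ext <- xdrop_extend(core, s, s, P10)
  expect_equal(ext$left$max_di, 0)
  expect_equal(ext$left$diag_lo, 0)
  expect_equal(ext$left$diag_hi, 0)
})

test_that("extension spans a planted drop-free match around the core", {
  p <- derive_params("0.1", 20, x_drop = 10)
  set.seed(34)
  sim <- simulate_pair(400, 400, 1, c(100, 100), 0.1, seed = 77, n0_gap = 20)
  tr <- sim$truth[1, ]
  # seed a core from the longest exact run of the planted alignment
  runs <- gregexpr("=+", tr$columns)[[1]]
  k <- which.max(attr(runs, "match.length"))
  off <- runs[k] - 1L
  v <- strsplit(tr$columns, "")[[1]]
  pre <- if (off > 0) v[1:off] else character(0)
  core <- list(db_begin = tr$db_begin + sum(pre != "I"),
               q_begin = tr$q_begin + sum(pre != "D"),
               columns = strrep("=", attr(runs, "match.length")[k]),
               score = attr(runs, "match.length")[k], errors = 0L)
  ext <- xdrop_extend(core, sim$db, sim$query, p)
  # the extended region (not necessarily the best-scoring end cell)
  # spans the planted match
  db_lo <- core$db_begin - ext$left$max_di
  db_hi <- core$db_begin - 1 + nchar(core$columns) + ext$right$max_di
  expect_lte(db_lo, tr$db_begin)
  expect_gte(db_hi, tr$db_end)
})

test_that("extension into unrelated sequence stops near the core", {
  set.seed(35)
  word <- random_dna(30)
  db <- paste0(random_dna(150), word, random_dna(150))
  qu <- paste0(random_dna(150), word, random_dna(150))
  core <- list(db_begin = 151L, q_begin = 151L, columns = strrep("=", 30),
               score = 30, errors = 0L)
  ext <- xdrop_extend(core, db, qu, P10)   # X = 3
  # expected random-column score is far below zero: the extension dies
  # within a few columns of the core end
  expect_lte(ext$right$best_di, 12)
  expect_lte(ext$left$best_di, 12)
})

test_that("Step 4 cuts the longest rate-valid alignment", {
  # core of 18 matches, right flank continuing with one error then four
  # matches: the maximal match takes all 23 columns (1 error, rate 1/23)
  set.seed(36)
  seg <- random_dna(18); tail4 <- random_dna(4)
  db <- paste0(strrep("G", 5), seg, "A", tail4, strrep("G", 5))
  qu <- paste0(strrep("C", 5), seg, "T", tail4, strrep("C", 5))
  m <- eps_align(db, qu, derive_params("0.1", 20, 10))
  expect_equal(nrow(m), 1)
  expect_equal(m$length, 23L)
  expect_equal(m$errors, 1L)
})

test_that("an extended region shorter than n0 yields nothing", {
  word <- "ACGTACGTACGTACG"   # 15 < n0 = 20 and nothing to extend into
  m <- eps_align(word, word, P10)
  expect_equal(nrow(m), 0)
})

test_that("co-located maximal matches are both reported", {
  # two overlapping matches sharing a core: left arm + core and core +
  # right arm, joined across a high-error junction that forbids the union
  set.seed(37)
  arm1 <- random_dna(30); core <- random_dna(30); arm2 <- random_dna(30)
  junk1 <- random_dna(12); junk2 <- random_dna(12)
  db <- paste0(arm1, junk1, core, junk2, arm2)
  qu <- paste0(arm1, strrep("A", 12), core, strrep("C", 12), arm2)
  p <- derive_params("0.1", 30, x_drop = 1e6)
  m <- eps_align(db, qu, p)
  o <- bruteforce_eps_matches(db, qu, p)
  expect_identical(match_keys(m), match_keys(o))
  expect_gte(nrow(m), 2)
})

test_that("duplicate and engulfed matches are removed", {
  base <- data.frame(db_begin = c(1L, 1L), db_end = c(200L, 200L),
                     q_begin = c(1L, 1L), q_end = c(200L, 200L),
                     length = c(200L, 200L), errors = c(0L, 0L),
                     columns = strrep("=", 200))
  p <- derive_params("0.1", 50, 5)
  expect_equal(nrow(remove_overlaps(base, p)), 1)

  two <- data.frame(db_begin = c(1L, 140L), db_end = c(200L, 199L),
                    q_begin = c(1L, 140L), q_end = c(200L, 199L),
                    length = c(200L, 60L), errors = c(0L, 0L),
                    columns = c(strrep("=", 200), strrep("=", 60)))
  expect_equal(nrow(remove_overlaps(two, p)), 1)   # unique part 5 < 50

  disjoint <- data.frame(db_begin = c(300L, 1L), db_end = c(400L, 100L),
                         q_begin = c(300L, 1L), q_end = c(400L, 100L),
                         length = c(101L, 100L), errors = c(0L, 0L),
                         columns = c(strrep("=", 101), strrep("=", 100)))
  out <- remove_overlaps(disjoint, p)
  expect_equal(nrow(out), 2)
  expect_equal(out$db_begin, c(1L, 300L))   # sorted by begin
})

test_that("overlap removal is idempotent", {
  set.seed(38)
  sim <- simulate_pair(500, 500, 3, c(50, 80), 0.1, seed = 3, n0_gap = 20)
  p <- derive_params("0.1", 20, 10)
  m <- eps_align(sim$db, sim$query, p)
  expect_identical(remove_overlaps(m, p), m)
})

test_that("self-comparison reports the full identity match", {
  set.seed(39)
  s <- random_dna(120)
  m <- eps_align(s, s, derive_params("0.1", 50, 5))
  expect_true(any(m$db_begin == 1 & m$db_end == 120 &
                  m$q_begin == 1 & m$q_end == 120 & m$errors == 0))
})

test_that("reported matches satisfy all match invariants", {
  set.seed(40)
  sim <- simulate_pair(600, 600, 3, c(50, 100), 0.1, seed = 8, n0_gap = 50)
  p <- derive_params("0.1", 50, 30)
  m <- eps_align(sim$db, sim$query, p)
  expect_gt(nrow(m), 0)
  for (i in seq_len(nrow(m))) {
    cols <- m$columns[i]
    expect_gte(m$length[i], p$n0)
    expect_lte(m$errors[i] * p$eps$b, m$length[i] * p$eps$a)
    expect_equal(substr(cols, 1, 1), "=")
    expect_equal(substr(cols, nchar(cols), nchar(cols)), "=")
    expect_false(epsaligner:::has_eps_xdrop(cols, p))
    expect_equal(m$length[i], nchar(cols))
    expect_equal(m$errors[i], epsaligner:::n_errors(cols))
    # column spans agree with coordinates
    expect_equal(m$db_end[i] - m$db_begin[i] + 1L,
                 epsaligner:::db_span(cols))
    expect_equal(m$q_end[i] - m$q_begin[i] + 1L,
                 epsaligner:::q_span(cols))
  }
})

test_that("maximality: no flanking column could extend a reported match", {
  set.seed(41)
  sim <- simulate_pair(500, 500, 2, c(60, 90), 0.075, seed = 12, n0_gap = 50)
  p <- derive_params("0.1", 50, 1e6)
  m <- eps_align(sim$db, sim$query, p)
  expect_gt(nrow(m), 0)
  ch <- function(s, i) substring(s, i, i)
  for (i in seq_len(nrow(m))) {
    # a diagonal match column just beyond either end would lengthen the
    # match at a better rate: maximality forbids it
    if (m$db_begin[i] > 1 && m$q_begin[i] > 1) {
      expect_false(ch(sim$db, m$db_begin[i] - 1) ==
                     ch(sim$query, m$q_begin[i] - 1))
    }
    if (m$db_end[i] < nchar(sim$db) && m$q_end[i] < nchar(sim$query)) {
      expect_false(ch(sim$db, m$db_end[i] + 1) ==
                     ch(sim$query, m$q_end[i] + 1))
    }
  }
})

test_that("verify_hit rejects a false-positive hit", {
  p <- derive_params("0.1", 20, 3)
  g <- c("ACGTCA", "TTGACC", "GCATGC")
  db <- paste0(g[1], "AA", g[2], "CC", g[3], strrep("G", 20))
  qu <- paste0(g[1], "TT", g[2], "GG", g[3], strrep("C", 20))
  h <- swift_hits(db, qu, p)
  out <- list()
  for (k in seq_len(nrow(h))) out <- c(out, verify_hit(h[k, ], db, qu, p))
  expect_length(out, 0)
})
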