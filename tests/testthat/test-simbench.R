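# Planted-alignment simulator, coverage metric, brute-force reference,
# benchmark table.

test_that("zero planted alignments give independent sequences, empty truth", {
  sim <- simulate_pair(500, 400, 0, c(50, 100), 0.1, seed = 4)
  expect_equal(nchar(sim$db), 500)
  expect_equal(nchar(sim$query), 400)
  expect_equal(nrow(sim$truth), 0)
})

test_that("rate 0 plants all-match columns", {
  sim <- simulate_pair(2000, 2000, 5, c(50, 100), 0, seed = 5)
  expect_true(all(grepl("^=+$", sim$truth$columns)))
  expect_true(all(sim$truth$errors == 0))
})

test_that("every planted record is an eps-match for its planted rate", {
  sim <- simulate_pair(5000, 5000, 10, c(50, 200),
                       c(0, 0.025, 0.05, 0.075, 0.1), seed = 6)
  tr <- sim$truth
  expect_true(all(tr$errors <= tr$rate * tr$length + 1e-9))
  expect_true(all(substr(tr$columns, 1, 1) == "="))
  # realized segments really align as recorded: recount spans
  expect_equal(tr$db_end - tr$db_begin + 1L,
               epsaligner:::db_span(tr$columns))
  expect_equal(tr$q_end - tr$q_begin + 1L,
               epsaligner:::q_span(tr$columns))
})

test_that("no planted error columns form a cancelling indel pair", {
  sim <- simulate_pair(5000, 5000, 10, c(50, 200), 0.1, seed = 7)
  expect_false(any(grepl("ID|DI", sim$truth$columns)))
})

test_that("simulation is reproducible from the seed", {
  a <- simulate_pair(1000, 1000, 3, c(50, 100), 0.05, seed = 11)
  b <- simulate_pair(1000, 1000, 3, c(50, 100), 0.05, seed = 11)
  expect_identical(a, b)
  c <- simulate_pair(1000, 1000, 3, c(50, 100), 0.05, seed = 12)
  expect_false(identical(a$db, c$db))
})

test_that("infeasible packing is rejected with a clear error", {
  expect_error(simulate_pair(100, 100, 5, c(50, 50), 0, seed = 1),
               "cannot place")
})

test_that("planted alignments respect the q-gram lemma count", {
  sim <- simulate_pair(2000, 2000, 5, c(50, 150), 0.1, seed = 13, n0_gap = 50)
  p <- derive_params("0.1", 50, 10)
  for (t in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[t, ]
    hit <- list(db_begin = tr$db_begin, db_end = tr$db_end,
                q_begin = tr$q_begin, q_end = tr$q_end,
                diag_min = -(tr$q_end - tr$q_begin + 1L),
                diag_max = tr$db_end - tr$db_begin + 1L)
    n_hits <- epsaligner:::count_qhits_in_hit(sim$db, sim$query, hit, p$q)
    expect_gte(n_hits, qgram_threshold(tr$length, tr$errors, p$q))
  }
})

test_that("coverage flags records by the 10% criterion", {
  truth <- data.frame(db_begin = 1L, db_end = 100L, q_begin = 1L,
                      q_end = 100L, length = 100L, errors = 0L,
                      rate = 0, columns = strrep("=", 100))
  # reported identical to truth
  rep_full <- data.frame(db_begin = 1L, db_end = 100L,
                         q_begin = 1L, q_end = 100L)
  expect_equal(coverage(rep_full, truth)$missed_pct, 0)
  # a reported match covering only 5% of the columns
  rep_5 <- data.frame(db_begin = 1L, db_end = 5L, q_begin = 1L, q_end = 5L)
  cov <- coverage(rep_5, truth)
  expect_equal(cov$per_match$covered, 0.05)
  expect_true(cov$per_match$missed)
  expect_equal(cov$missed_pct, 100)
  # nothing reported
  none <- rep_full[0, ]
  expect_equal(coverage(none, truth)$missed_pct, 100)
  # empty truth
  expect_true(is.na(coverage(rep_full, truth[0, ])$missed_pct))
})

test_that("coverage is monotone in the reported set", {
  set.seed(51)
  sim <- simulate_pair(2000, 2000, 4, c(50, 100), 0.1, seed = 14, n0_gap = 50)
  p <- derive_params("0.1", 50, 50)
  m <- eps_align(sim$db, sim$query, p)
  part <- coverage(m[1, , drop = FALSE], sim$truth)$per_match$covered
  full <- coverage(m, sim$truth)$per_match$covered
  expect_true(all(full >= part))
})

test_that("brute force finds the identity self-match", {
  set.seed(52)
  s <- random_dna(60)
  p <- derive_params("0.1", 20, 1e6)
  o <- bruteforce_eps_matches(s, s, p)
  expect_true(any(o$db_begin == 1 & o$db_end == 60 & o$errors == 0))
})

test_that("brute force returns nothing for unrelated homopolymers", {
  p <- derive_params("0.1", 20, 1e6)
  o <- bruteforce_eps_matches(strrep("A", 60), strrep("C", 60), p)
  expect_equal(nrow(o), 0)
})

test_that("brute force recovers a planted 30 bp match with one error", {
  sim <- simulate_pair(60, 60, 1, c(30, 30), 1 / 30, seed = 15, n0_gap = 20)
  p <- derive_params("0.1", 20, 1e6)
  o <- bruteforce_eps_matches(sim$db, sim$query, p)
  expect_equal(nrow(o), 1)
  tr <- sim$truth[1, ]
  expect_lte(o$db_begin, tr$db_begin)
  expect_gte(o$db_end, tr$db_end)
})

test_that("brute force refuses oversized inputs", {
  p <- derive_params("0.1", 20, 5)
  expect_error(bruteforce_eps_matches(strrep("A", 400), strrep("A", 400), p),
               "refuses")
})

test_that("the benchmark table mirrors its config", {
  expect_equal(nrow(run_benchmark(list())), 0)
  cfg <- list(list(name = "tiny", db_len = 3000, q_len = 3000,
                   n_planted = 3, len_range = c(50, 100), rate = 0.05,
                   eps = "0.05", n0 = 50, x_drop = 50, seed = 17))
  tab <- run_benchmark(cfg)
  expect_equal(tab$setting, "tiny")
  expect_equal(tab$n_truth, 3L)
  expect_equal(tab$missed_pct, 0)
})
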