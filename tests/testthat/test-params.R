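# Exact rational error rates, epsilon-scoring, and derived filter constants.

test_that("error rates parse exactly into lowest-term rationals", {
  e <- error_rate("0.1")
  expect_equal(c(e$a, e$b), c(1L, 10L))
  expect_equal(unlist(error_rate("0.025")[c("a", "b")]), c(a = 1L, b = 40L))
  expect_equal(unlist(error_rate("1/20")[c("a", "b")]), c(a = 1L, b = 20L))
  expect_equal(unlist(error_rate(0.075)[c("a", "b")]), c(a = 3L, b = 40L))
  expect_error(error_rate("1.5"), "between 0 and 1")
  expect_error(error_rate("0"), "between 0 and 1")
})

test_that("error penalty p = 1 - 1/eps in exact and scaled form", {
  expect_equal(error_penalty("0.1")$p, -9)
  expect_equal(error_penalty("0.5")$p, -1)
  expect_equal(error_penalty("0.05")$p, -19)
  expect_equal(error_penalty("0.1")$error_scaled, -9L)
  expect_equal(error_penalty("0.1")$match_scaled, 1L)
})

test_that("guaranteed error-free segment length l(n, eps)", {
  expect_equal(min_corefree_length(20, "0.1"), 6L)
  expect_equal(min_corefree_length(30, "0.1"), 7L)
  expect_equal(min_corefree_length(10, "0.01"), 10L)
})

test_that("next length admitting one more error", {
  expect_equal(next_error_length(20, "0.1"), 30L)
  expect_equal(next_error_length(50, "0.05"), 60L)
  expect_equal(next_error_length(9, "0.1"), 10L)
})

test_that("s_min is the minimum of l at n0 and at the next error plateau", {
  expect_equal(compute_smin(20, "0.1"), 6L)
  expect_equal(compute_smin(50, "0.1"), 8L)
  expect_equal(compute_smin(50, "0.05"), 15L)
})

test_that("s_min equals the sweep minimum of l(n, eps) over n >= n0", {
  for (eps in c("0.1", "0.05", "0.025")) {
    er <- error_rate(eps)
    for (n0 in c(15, 20, 37, 50)) {
      sweep <- min(vapply(n0:(n0 + 10 * er$b), min_corefree_length,
                          integer(1), eps = er))
      expect_equal(compute_smin(n0, er), sweep,
                   info = paste(eps, n0))
    }
  }
})

test_that("q-gram lemma threshold T(n, k, q)", {
  expect_equal(qgram_threshold(20, 2, 6), 3L)
  expect_equal(qgram_threshold(20, 0, 6), 15L)
  expect_equal(qgram_threshold(20, 2, 8), -3L)
})

test_that("T is monotone: non-increasing in k and q, non-decreasing in n", {
  for (n in c(20, 35, 50)) for (k in 0:3) for (q in c(4, 6, 8)) {
    t0 <- qgram_threshold(n, k, q)
    expect_lte(qgram_threshold(n, k + 1, q), t0)
    expect_lte(qgram_threshold(n, k, q + 1), t0)
    expect_gte(qgram_threshold(n + 1, k, q), t0)
  }
})

test_that("scaled score sign is exactly the error-rate test", {
  for (eps in list(c(1, 10), c(1, 20), c(3, 40))) {
    a <- eps[1]; b <- eps[2]
    for (m in seq(0, 500, by = 29)) for (k in 0:12) {
      if (m + k == 0) next
      expect_equal(m * a + k * (a - b) >= 0, k * b <= (m + k) * a,
                   info = paste(a, b, m, k))
    }
  }
})

test_that("derived parameters reproduce the worked constants", {
  p <- derive_params("0.1", 20, x_drop = 3)
  expect_equal(p$q, 6L)
  expect_equal(p$smin, 6L)
  expect_equal(p$tau, 3L)
  expect_equal(p$e, 2L)
  expect_equal(p$w, 20L)
  expect_equal(p$delta, 32L)
  expect_equal(p$xdrop_scaled, 27)
  expect_equal(derive_params("0.1", 20, x_drop = 0)$xdrop_scaled, 0)
})

test_that("derive_params rejects infeasible and out-of-range settings", {
  expect_error(suppressWarnings(derive_params("0.1", 20, q = 8)),
               "infeasible")
  expect_warning(derive_params("0.1", 20, q = 5), "exactness")
  expect_error(derive_params("0.3", 50), "0.25")
  expect_error(derive_params("0.1", 5), "at least 10")
})

test_that("the q-hit threshold is lossless across error plateaus", {
  # T(n, floor(eps*n), q) dips at the next plateau; tau must be <= every
  # plateau value so that longer matches still reach the counter
  for (cfg in list(c(0.1, 20), c(0.05, 15), c(0.05, 50), c(0.025, 50))) {
    p <- derive_params(as.character(cfg[1]), cfg[2], 5)
    er <- p$eps
    for (n in p$n0:(p$n0 + 3 * er$b)) {
      k <- (n * er$a) %/% er$b
      expect_lte(p$tau, qgram_threshold(n, k, p$q))
    }
  }
})

test_that("derive_params is pure and deterministic", {
  expect_identical(derive_params("0.1", 50, 7), derive_params("0.1", 50, 7))
})
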