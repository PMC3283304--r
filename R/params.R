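#' Exact error rates as rationals
#'
#' An error rate \eqn{\epsilon = a/b} is stored as a pair of integers in
#' lowest terms so that every comparison "k errors over n columns is at most
#' \eqn{\epsilon}" can be evaluated exactly as `k*b <= n*a`, without floating
#' point. Decimal strings such as `"0.1"` or `"0.025"` are parsed digit by
#' digit into a fraction over a power of ten and then reduced.
#'
#' @param x A decimal string (`"0.1"`), a fraction string (`"1/10"`), a
#'   single numeric, or an existing `error_rate` object.
#' @return An object of class `error_rate` with integer fields `a`
#'   (numerator) and `b` (denominator), `0 < a < b`.
#' @examples
#' error_rate("0.1")    # 1/10
#' error_rate("0.025")  # 1/40
#' error_rate(1/20)
#' @export
error_rate <- function(x) {
  if (inherits(x, "error_rate")) return(x)
  if (is.character(x)) {
    x <- trimws(x)
    if (grepl("^[0-9]+/[0-9]+$", x)) {
      parts <- as.numeric(strsplit(x, "/", fixed = TRUE)[[1]])
      a <- parts[1]; b <- parts[2]
    } else if (grepl("^[0-9]*\\.?[0-9]+$", x)) {
      dot <- regexpr(".", x, fixed = TRUE)
      if (dot < 0) {
        a <- as.numeric(x); b <- 1
      } else {
        frac <- sub("^[0-9]*\\.", "", x)
        intp <- sub("\\..*$", "", x)
        if (intp == "") intp <- "0"
        b <- 10^nchar(frac)
        a <- as.numeric(intp) * b + as.numeric(frac)
      }
    } else {
      stop("cannot parse error rate from '", x, "'", call. = FALSE)
    }
  } else if (is.numeric(x) && length(x) == 1L) {
    # exact continued-fraction reconstruction for doubles that came from
    # short decimals / small fractions
    b <- 1
    while (b < 1e7 && abs(x * b - round(x * b)) > 1e-9) b <- b + 1
    a <- round(x * b)
  } else {
    stop("cannot parse error rate", call. = FALSE)
  }
  if (is.na(a) || is.na(b) || a <= 0 || a >= b)
    stop("error rate must lie strictly between 0 and 1", call. = FALSE)
  g <- gcd_int(a, b)
  structure(list(a = as.integer(a / g), b = as.integer(b / g)),
            class = "error_rate")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' @export
print.error_rate <- function(x, ...) {
  cat(sprintf("error rate %d/%d (= %g)\n", x$a, x$b, x$a / x$b))
  invisible(x)
}

#' @export
as.numeric.error_rate <- function(x, ...) x$a / x$b

#' Error penalty of the epsilon-scoring scheme
#'
#' Under the error-rate scoring scheme a match scores +1 and every error
#' column (mismatch, insertion, deletion) scores \eqn{p = 1 - 1/\epsilon},
#' so that an alignment has non-negative score exactly when its error rate
#' is at most \eqn{\epsilon}. All internal arithmetic scales these scores by
#' the numerator `a`, giving integer scores `+a` for a match and `a - b` for
#' an error.
#'
#' @param eps An [error_rate()] (or something coercible to one).
#' @return A list with the exact penalty as a fraction (`numer`/`denom`),
#'   its numeric value `p`, and the integer-scaled scores `match_scaled`
#'   (= a) and `error_scaled` (= a - b).
#' @examples
#' error_penalty("0.1")$p   # -9
#' @export
error_penalty <- function(eps) {
  eps <- error_rate(eps)
  list(numer = eps$a - eps$b, denom = eps$a,
       p = (eps$a - eps$b) / eps$a,
       match_scaled = eps$a, error_scaled = eps$a - eps$b)
}

#' Guaranteed error-free segment length l(n, eps)
#'
#' Any local alignment of length `n` with error rate at most `eps` contains
#' at most `floor(eps*n)` errors, which split its matching positions into at
#' most `floor(eps*n) + 1` error-free segments; the longest of these has
#' length at least `ceiling((n - floor(eps*n)) / (floor(eps*n) + 1))`.
#'
#' @param n Alignment length in columns (>= 1).
#' @param eps An [error_rate()].
#' @return Integer l(n, eps).
#' @export
min_corefree_length <- function(n, eps) {
  eps <- error_rate(eps)
  stopifnot(all(n >= 1))
  k <- (n * eps$a) %/% eps$b
  as.integer(-((n - k) %/% -(k + 1)))  # ceiling division
}

#' Next length that admits one more error
#'
#' The smallest alignment length `n > n0` for which the maximal error count
#' `floor(eps*n)` exceeds `floor(eps*n0)`.
#'
#' @param n0 Minimal match length.
#' @param eps An [error_rate()].
#' @return Integer n1.
#' @export
next_error_length <- function(n0, eps) {
  eps <- error_rate(eps)
  stopifnot(n0 >= 1)
  k0 <- (n0 * eps$a) %/% eps$b
  n1 <- -((eps$b * (k0 + 1)) %/% -eps$a)  # ceiling(b*(k0+1)/a)
  as.integer(n1)
}

#' Minimal epsilon-core length s_min
#'
#' The shortest error-free segment guaranteed to occur in *every* local
#' alignment of length >= n0 with error rate <= eps. Because l(n, eps) is a
#' sawtooth in n whose minima increase, the minimum over all n >= n0 is
#' attained at n0 itself or at the next length n1 that admits one more
#' error: `s_min = min(l(n0, eps), l(n1, eps))`. This is also the default
#' q-gram length of the filter, the value for which the filtration +
#' verification pipeline is provably exact.
#'
#' @inheritParams next_error_length
#' @return Integer s_min.
#' @examples
#' compute_smin(20, "0.1")  # 6
#' compute_smin(50, "0.1")  # 8
#' @export
compute_smin <- function(n0, eps) {
  eps <- error_rate(eps)
  min(min_corefree_length(n0, eps),
      min_corefree_length(next_error_length(n0, eps), eps))
}

#' q-gram lemma threshold T(n, k, q)
#'
#' Every alignment of length `n` with `k` error columns contains at least
#' `n + 1 - q*(k + 1)` q-hits (diagonal runs of q consecutive match
#' columns). A non-positive value signals an infeasible filter setting.
#'
#' @param n Alignment length. @param k Error count. @param q q-gram length.
#' @return Integer threshold (may be <= 0).
#' @export
qgram_threshold <- function(n, k, q) {
  stopifnot(n >= 1, k >= 0, q >= 1)
  as.integer(n + 1 - q * (k + 1))
}

#' Derive all filter and verification constants
#'
#' Computes, from the user-level parameters (error rate `eps`, minimal
#' length `n0`, X-drop bound `x_drop`), every constant the filtration and
#' verification phases need:
#' \describe{
#'   \item{q}{q-gram length; defaults to `s_min` (required for exactness).}
#'   \item{smin}{minimal epsilon-core length, [compute_smin()].}
#'   \item{e}{`floor(eps*n0)`, the diagonal band width = the maximal error
#'     count of a minimal-length match.}
#'   \item{tau}{q-hit counter threshold `T(n0, e, q)`.}
#'   \item{w}{parallelogram column span, = n0.}
#'   \item{delta}{diagonal bin stride, smallest power of two >= w.}
#'   \item{xdrop_scaled}{`x_drop * (b - a)`, the integer-scaled score drop
#'     that constitutes an epsilon-X-drop.}
#' }
#'
#' @param eps Error rate in (0, 0.25]; an [error_rate()] or coercible.
#' @param n0 Minimal match length in columns (>= 10).
#' @param x_drop X-drop bound in errors (>= 0). Default 5.
#' @param q Optional q-gram length override. Overriding away from `s_min`
#'   voids the exactness guarantee; a warning is emitted.
#' @return An object of class `eps_params`.
#' @examples
#' derive_params("0.1", 20, x_drop = 3)
#' @export
derive_params <- function(eps, n0, x_drop = 5, q = NULL) {
  eps <- error_rate(eps)
  if (4 * eps$a > eps$b)
    stop("error rate ", eps$a, "/", eps$b,
         " outside the accepted range (0, 0.25]: the q-gram filter loses ",
         "its guarantees at high error rates", call. = FALSE)
  if (n0 < 10) stop("minimal match length n0 must be at least 10", call. = FALSE)
  if (x_drop < 0) stop("x_drop must be non-negative", call. = FALSE)
  smin <- compute_smin(n0, eps)
  if (is.null(q)) {
    q <- smin
  } else if (q != smin) {
    warning("q = ", q, " differs from s_min = ", smin,
            ": the exactness guarantee no longer applies", call. = FALSE)
  }
  # Lossless q-hit threshold: the q-gram lemma bound T(n, floor(eps*n), q)
  # is a sawtooth in the match length n - just above each length that
  # admits one more error it drops before growing again. The counter
  # threshold must be the minimum over all lengths >= n0, attained at a
  # plateau start; the bin width e follows the attaining plateau so that
  # the hits of such a match still share a bin. (For the classic worked
  # setting eps = 0.1, n0 = 20 this reproduces tau = 3, e = 2.)
  e0 <- as.integer((n0 * eps$a) %/% eps$b)
  js <- e0:(e0 + 8L)
  njs <- pmax(n0, -((eps$b * js) %/% -eps$a))  # ceiling(j*b/a), floored at n0
  tjs <- as.integer(njs + 1L - q * (js + 1L))
  e <- as.integer(js[which.min(tjs)])
  tau <- min(tjs)
  if (tau < 1)
    stop("infeasible parameter combination: eps = ", eps$a, "/", eps$b,
         ", n0 = ", n0, ", q = ", q, " give q-hit threshold tau = ", tau,
         " < 1", call. = FALSE)
  w <- as.integer(n0)
  delta <- 1L
  while (delta < w) delta <- delta * 2L
  structure(list(
    eps = eps, n0 = as.integer(n0), x_drop = x_drop,
    q = as.integer(q), smin = as.integer(smin),
    n1 = next_error_length(n0, eps),
    tau = tau, e = e, w = w, delta = delta,
    match_scaled = eps$a, error_scaled = eps$a - eps$b,
    min_score_scaled = as.integer(eps$a * smin),
    xdrop_scaled = x_drop * (eps$b - eps$a)
  ), class = "eps_params")
}

#' @export
print.eps_params <- function(x, ...) {
  cat("epsilon-match search parameters\n")
  cat(sprintf("  eps     = %d/%d (%g)\n", x$eps$a, x$eps$b, x$eps$a / x$eps$b))
  cat(sprintf("  n0      = %d    X = %g\n", x$n0, x$x_drop))
  cat(sprintf("  scoring = match +%d, error %+d (scaled by %d)\n",
              x$match_scaled, x$error_scaled, x$eps$a))
  cat(sprintf("  s_min   = %d    q = %d\n", x$smin, x$q))
  cat(sprintf("  tau     = %d    e = %d    w = %d    delta = %d\n",
              x$tau, x$e, x$w, x$delta))
  invisible(x)
}
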