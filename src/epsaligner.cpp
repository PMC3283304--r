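// Compiled kernels: SWIFT q-gram filtration, banded Waterman-Eggert,
// X-drop extension, bestEnds DP + traceback, and the exhaustive
// reference enumerator. All coordinates here are 0-based half-open;
// the R wrappers convert to 1-based inclusive.
//
// Scoring is integer-scaled by the error-rate numerator a: a match
// scores +a, an error a-b, so "score >= 0" is exactly "error rate <= a/b".
// Column codes: '=' match, 'X' mismatch, 'D' consumes db only (deletion
// in the query), 'I' consumes query only.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>

using namespace Rcpp;

static const long long NEG_INF = LLONG_MIN / 4;

static inline long long floor_div(long long x, long long y) {
  long long q = x / y, r = x % y;
  return (r != 0 && ((r < 0) != (y < 0))) ? q - 1 : q;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;  // N and friends: never part of a q-gram
  }
}

// ------------------------------------------------------------------
// SWIFT filtration
// ------------------------------------------------------------------

struct BinState {
  int count = 0;
  int first_col = 0, last_col = 0;   // query columns of counted q-hits
  long long dmin = 0, dmax = 0;      // observed hit diagonals
};

struct RawHit {
  long long db_begin, db_end, q_begin, q_end, dmin, dmax;
  int count;
};

// q-gram index over db; for q <= 31 a 2-bit packed code, else string keys
// (exactness never requires changing q, only the hashing).
// [[Rcpp::export]]
DataFrame cpp_swift_hits(std::string db, std::string query,
                         int q, int tau, int e, int w, int delta) {
  const long long n = (long long)db.size(), m = (long long)query.size();
  std::vector<RawHit> hits;
  if (q > (int)n || q > (int)m) {
    return DataFrame::create(_["db_begin"] = IntegerVector(0),
                             _["db_end"] = IntegerVector(0),
                             _["q_begin"] = IntegerVector(0),
                             _["q_end"] = IntegerVector(0),
                             _["diag_min"] = IntegerVector(0),
                             _["diag_max"] = IntegerVector(0),
                             _["count"] = IntegerVector(0));
  }

  const bool packed = q <= 31;
  std::unordered_map<uint64_t, std::vector<int> > dir64;
  std::map<std::string, std::vector<int> > dirS;
  if (packed) {
    uint64_t code = 0, mask = (q >= 32) ? ~0ULL : ((1ULL << (2 * q)) - 1);
    int valid = 0;
    for (long long i = 0; i < n; ++i) {
      int c = base_code(db[i]);
      if (c < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (++valid >= q) dir64[code].push_back((int)(i - q + 1));
    }
  } else {
    for (long long i = 0; i + q <= n; ++i) {
      bool ok = true;
      for (int t = 0; t < q; ++t) if (base_code(db[i + t]) < 0) { ok = false; break; }
      if (ok) dirS[db.substr(i, q)].push_back((int)i);
    }
  }

  std::unordered_map<long long, BinState> bins;
  std::vector<RawHit> out;

  auto emit = [&](long long bin_id, const BinState &bs) {
    if (bs.count < tau) return;
    RawHit h;
    h.q_begin = std::max(0LL, (long long)bs.first_col - e);
    h.q_end   = std::min(m, (long long)bs.last_col + q + e);
    h.dmin    = std::min(bin_id, bs.dmin) - e;
    h.dmax    = std::max(bin_id + delta + e - 1, bs.dmax) + e;
    h.db_begin = std::max(0LL, h.q_begin + h.dmin);
    h.db_end   = std::min(n, h.q_end + h.dmax);
    h.count = bs.count;
    if (h.db_end > h.db_begin && h.q_end > h.q_begin) out.push_back(h);
  };

  auto feed = [&](long long bin_id, int j, long long d) {
    BinState &bs = bins[bin_id];
    if (bs.count > 0 && j - bs.last_col > w - q) {
      emit(bin_id, bs);
      bs = BinState();
    }
    if (bs.count == 0) { bs.first_col = j; bs.dmin = bs.dmax = d; }
    bs.count++;
    bs.last_col = j;
    bs.dmin = std::min(bs.dmin, d);
    bs.dmax = std::max(bs.dmax, d);
  };

  // stream the query
  if (packed) {
    uint64_t code = 0, mask = (q >= 32) ? ~0ULL : ((1ULL << (2 * q)) - 1);
    int valid = 0;
    for (long long j = 0; j < m; ++j) {
      int c = base_code(query[j]);
      if (c < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)c) & mask;
      if (valid + 1 >= q) {
        ++valid;
        long long col = j - q + 1;
        auto it = dir64.find(code);
        if (it != dir64.end()) {
          for (int i : it->second) {
            long long d = (long long)i - col;
            long long f0 = floor_div(d, delta) * delta;
            for (long long f : {f0, f0 - delta})
              if (f <= d && d <= f + delta + e - 1) feed(f, (int)col, d);
          }
        }
      } else ++valid;
    }
  } else {
    for (long long j = 0; j + q <= m; ++j) {
      bool ok = true;
      for (int t = 0; t < q; ++t) if (base_code(query[j + t]) < 0) { ok = false; break; }
      if (!ok) continue;
      auto it = dirS.find(query.substr(j, q));
      if (it == dirS.end()) continue;
      for (int i : it->second) {
        long long d = (long long)i - j;
        long long f0 = floor_div(d, delta) * delta;
        for (long long f : {f0, f0 - delta})
          if (f <= d && d <= f + delta + e - 1) feed(f, (int)j, d);
      }
    }
  }
  for (auto &kv : bins) emit(kv.first, kv.second);

  std::sort(out.begin(), out.end(), [](const RawHit &x, const RawHit &y) {
    if (x.q_end != y.q_end) return x.q_end < y.q_end;
    if (x.q_begin != y.q_begin) return x.q_begin < y.q_begin;
    if (x.dmin != y.dmin) return x.dmin < y.dmin;
    return x.db_begin < y.db_begin;
  });

  int N = (int)out.size();
  IntegerVector db0(N), db1(N), q0(N), q1(N), dm(N), dM(N), ct(N);
  for (int k = 0; k < N; ++k) {
    db0[k] = (int)out[k].db_begin; db1[k] = (int)out[k].db_end;
    q0[k] = (int)out[k].q_begin;   q1[k] = (int)out[k].q_end;
    dm[k] = (int)out[k].dmin;      dM[k] = (int)out[k].dmax;
    ct[k] = out[k].count;
  }
  return DataFrame::create(_["db_begin"] = db0, _["db_end"] = db1,
                           _["q_begin"] = q0, _["q_end"] = q1,
                           _["diag_min"] = dm, _["diag_max"] = dM,
                           _["count"] = ct);
}

// ------------------------------------------------------------------
// Step 1: banded Waterman-Eggert
// ------------------------------------------------------------------

// All non-overlapping local alignments with score >= min_score inside the
// window [db_lo,db_hi) x [q_lo,q_hi) restricted to diagonals
// diag_min <= i - j <= diag_max. Iterated best alignment + cell masking
// + full recompute (windows are small).
// [[Rcpp::export]]
List cpp_find_cores(std::string db, std::string query,
                    int db_lo, int db_hi, int q_lo, int q_hi,
                    int diag_min, int diag_max,
                    int a, int b, int min_score, int max_cores = 64) {
  const int nr = db_hi - db_lo, nc = q_hi - q_lo;
  const long long err = (long long)a - b;
  // H is (nr+1) x (nc+1); mask marks consumed cells (1-based in window)
  std::vector<long long> H((size_t)(nr + 1) * (nc + 1), 0);
  std::vector<uint8_t> mask((size_t)(nr + 1) * (nc + 1), 0);
  auto idx = [&](int i, int j) { return (size_t)i * (nc + 1) + j; };
  auto inband = [&](int i, int j) {
    long long d = (long long)(db_lo + i - 1) - (q_lo + j - 1);
    return d >= diag_min && d <= diag_max;
  };

  List cores;
  for (int iter = 0; iter < max_cores; ++iter) {
    long long best = 0; int bi = -1, bj = -1;
    for (int i = 0; i <= nr; ++i)
      for (int j = 0; j <= nc; ++j) {
        size_t p = idx(i, j);
        if (i == 0 || j == 0) { H[p] = 0; continue; }
        if (mask[p] || !inband(i, j)) { H[p] = 0; continue; }
        bool mt = db[db_lo + i - 1] == query[q_lo + j - 1] &&
                  base_code(db[db_lo + i - 1]) >= 0;
        long long v = 0;
        v = std::max(v, H[idx(i - 1, j - 1)] + (mt ? (long long)a : err));
        v = std::max(v, H[idx(i - 1, j)] + err);
        v = std::max(v, H[idx(i, j - 1)] + err);
        H[p] = v;
        if (v > best || (v == best && (i < bi || (i == bi && j < bj)))) {
          best = v; bi = i; bj = j;
        }
      }
    if (best < min_score || bi < 0) break;

    // traceback with canonical preference: diagonal > up (D) > left (I)
    std::string cols;
    int i = bi, j = bj;
    std::vector<std::pair<int,int> > path;
    while (i > 0 && j > 0 && H[idx(i, j)] > 0) {
      long long v = H[idx(i, j)];
      bool mt = db[db_lo + i - 1] == query[q_lo + j - 1] &&
                base_code(db[db_lo + i - 1]) >= 0;
      path.push_back(std::make_pair(i, j));
      if (v == H[idx(i - 1, j - 1)] + (mt ? (long long)a : err)) {
        cols.push_back(mt ? '=' : 'X'); --i; --j;
      } else if (v == H[idx(i - 1, j)] + err) {
        cols.push_back('D'); --i;
      } else {
        cols.push_back('I'); --j;
      }
    }
    std::reverse(cols.begin(), cols.end());
    // trim to match-bounded ends (optimal local alignments are; defensive)
    size_t s = cols.find('='), t = cols.rfind('=');
    if (s == std::string::npos) break;
    for (size_t k = 0; k < s; ++k) {
      char c = cols[k];
      if (c != 'I') ++i;  // shift begin forward past trimmed db-consuming cols
      if (c != 'D') ++j;
    }
    long long sc = 0; int nerr = 0;
    std::string tcols = cols.substr(s, t - s + 1);
    for (char c : tcols) { if (c == '=') sc += a; else { sc += err; ++nerr; } }

    if (sc >= min_score)
      cores.push_back(List::create(
        _["db_begin"] = db_lo + i, _["q_begin"] = q_lo + j,
        _["columns"] = tcols, _["score"] = (double)sc, _["errors"] = nerr));

    for (auto &pc : path) mask[idx(pc.first, pc.second)] = 1;
  }
  return cores;
}

// ------------------------------------------------------------------
// Extension machinery (Steps 3 and 4)
// ------------------------------------------------------------------

// Direction-mapped character access: extension always walks "outward"
// from an origin. dir = +1: db[i0 + t], dir = -1: db[i0 - 1 - t].
struct Walker {
  const std::string *s; long long o; int dir; long long avail;
  Walker(const std::string &str, long long origin, int d)
    : s(&str), o(origin), dir(d) {
    avail = d > 0 ? (long long)str.size() - origin : origin;
  }
  char at(long long t) const { return dir > 0 ? (*s)[o + t] : (*s)[o - 1 - t]; }
};

static inline bool chars_match(char x, char y) {
  return x == y && base_code(x) >= 0;
}

// Step 3: score-only gapped X-drop extension with the epsilon-adjusted
// scores. Row sweep with a per-row alive window: a cell whose score
// falls DT or more below the running best is pruned (reaching it would
// require an epsilon-X-drop), and the sweep stops when a row's alive
// window is empty. Reports the best end cell and the band of diagonals
// that was ever alive.
// [[Rcpp::export]]
List cpp_xdrop_extend(std::string db, std::string query,
                      int db_origin, int q_origin, int dir,
                      int a, int b, double xdrop_scaled) {
  Walker wd(db, db_origin, dir), wq(query, q_origin, dir);
  const long long err = (long long)a - b;
  const long long DT = (xdrop_scaled > 4e17) ? (long long)4e17
                                             : (long long)xdrop_scaled;
  const long long maxdi = wd.avail, maxdj = wq.avail;

  long long best = 0, best_di = 0, best_dj = 0;
  long long dmin_alive = 0, dmax_alive = 0, max_di_alive = 0, max_dj_alive = 0;

  auto note = [&](long long di, long long dj, long long v) {
    long long d = di - dj;
    dmin_alive = std::min(dmin_alive, d);
    dmax_alive = std::max(dmax_alive, d);
    max_di_alive = std::max(max_di_alive, di);
    max_dj_alive = std::max(max_dj_alive, dj);
    if (v > best ||
        (v == best && (std::llabs(di - dj) < std::llabs(best_di - best_dj) ||
                       (std::llabs(di - dj) == std::llabs(best_di - best_dj) &&
                        di < best_di)))) {
      best = v; best_di = di; best_dj = dj;
    }
  };

  // previous row's alive window [plo, phi] and scores indexed from plo
  std::vector<long long> prev, cur;
  long long plo = 0, phi = 0;
  prev.assign(1, 0);           // row 0, cell (0,0)
  {                            // rest of row 0: pure insertion runs
    long long dj = 1, v = 0;
    while (dj <= maxdj) {
      v += err;
      if (best - v >= DT) break;
      prev.push_back(v);
      note(0, dj, v);
      ++phi; ++dj;
    }
  }

  for (long long di = 1; di <= maxdi && phi >= plo; ++di) {
    long long lo = -1, hi = -1;
    cur.clear();
    long long cstart = plo;    // dj index of cur[0]
    for (long long dj = plo; dj <= maxdj; ++dj) {
      long long v = NEG_INF;
      if (dj >= 1 && dj - 1 >= plo && dj - 1 <= phi) {   // diag
        long long p = prev[dj - 1 - plo];
        if (p > NEG_INF) {
          bool mt = chars_match(wd.at(di - 1), wq.at(dj - 1));
          v = std::max(v, p + (mt ? (long long)a : err));
        }
      }
      if (dj >= plo && dj <= phi) {                      // up (D)
        long long p = prev[dj - plo];
        if (p > NEG_INF) v = std::max(v, p + err);
      }
      if (dj - 1 >= cstart && (long long)cur.size() > dj - 1 - cstart) {
        long long p = cur[dj - 1 - cstart];              // left (I)
        if (p > NEG_INF) v = std::max(v, p + err);
      }
      if (v > NEG_INF && best - v >= DT) v = NEG_INF;    // prune
      if (v > NEG_INF) {
        if (lo < 0) lo = dj;
        hi = dj;
        note(di, dj, v);
      }
      cur.push_back(v);
      // nothing further right can become alive once past the previous
      // row's window and the left chain is dead
      if (dj > phi && v <= NEG_INF) break;
    }
    if (lo < 0) break;
    prev.assign(cur.begin() + (lo - cstart), cur.begin() + (hi - cstart + 1));
    plo = lo; phi = hi;
  }

  return List::create(_["best_score"] = (double)best,
                      _["best_di"] = (double)best_di,
                      _["best_dj"] = (double)best_dj,
                      _["diag_lo"] = (double)dmin_alive,
                      _["diag_hi"] = (double)dmax_alive,
                      _["max_di"] = (double)max_di_alive,
                      _["max_dj"] = (double)max_dj_alive);
}

// Banded global-from-origin DP used by Step 4. Tracks per cell the best
// score, the length of the canonical best path (minimal length among
// equal scores), and the canonical move. Shared by bestEnds collection
// and traceback.
struct BandDP {
  long long dmin, dmax, nrow, bandw;
  std::vector<long long> S;
  std::vector<int> L;
  std::vector<uint8_t> M;  // 0 none, 1 diag, 2 up(D), 3 left(I)
  long long at(long long di, long long dj) const {
    if (di < 0 || di > nrow) return NEG_INF;
    long long d = di - dj;
    if (d < dmin || d > dmax) return NEG_INF;
    return S[(size_t)(di * bandw + (d - dmin))];
  }
  size_t pos(long long di, long long dj) const {
    return (size_t)(di * bandw + (di - dj - dmin));
  }
};

static void fill_band_dp(BandDP &dp, const Walker &wd, const Walker &wq,
                         long long maxdi, long long maxdj,
                         long long dmin, long long dmax, int a, int b) {
  const long long err = (long long)a - b;
  dp.dmin = dmin; dp.dmax = dmax; dp.nrow = maxdi;
  dp.bandw = dmax - dmin + 1;
  size_t sz = (size_t)((maxdi + 1) * dp.bandw);
  dp.S.assign(sz, NEG_INF);
  dp.L.assign(sz, 0);
  dp.M.assign(sz, 0);
  if (dmin <= 0 && 0 <= dmax) dp.S[dp.pos(0, 0)] = 0;
  for (long long di = 0; di <= maxdi; ++di) {
    long long djlo = std::max(0LL, di - dmax), djhi = std::min(maxdj, di - dmin);
    for (long long dj = djlo; dj <= djhi; ++dj) {
      if (di == 0 && dj == 0) continue;
      long long bestv = NEG_INF; int bestl = 0; uint8_t bestm = 0;
      // canonical preference: higher score, then shorter path, then
      // diag > up > left
      if (di >= 1 && dj >= 1) {
        long long p = dp.at(di - 1, dj - 1);
        if (p > NEG_INF) {
          bool mt = chars_match(wd.at(di - 1), wq.at(dj - 1));
          long long v = p + (mt ? (long long)a : err);
          int l = dp.L[dp.pos(di - 1, dj - 1)] + 1;
          if (v > bestv || (v == bestv && l < bestl)) { bestv = v; bestl = l; bestm = 1; }
        }
      }
      if (di >= 1) {
        long long p = dp.at(di - 1, dj);
        if (p > NEG_INF) {
          long long v = p + err; int l = dp.L[dp.pos(di - 1, dj)] + 1;
          if (v > bestv || (v == bestv && l < bestl)) { bestv = v; bestl = l; bestm = 2; }
        }
      }
      if (dj >= 1) {
        long long p = dp.at(di, dj - 1);
        if (p > NEG_INF) {
          long long v = p + err; int l = dp.L[dp.pos(di, dj - 1)] + 1;
          if (v > bestv || (v == bestv && l < bestl)) { bestv = v; bestl = l; bestm = 3; }
        }
      }
      if (bestv > NEG_INF) {
        size_t p = dp.pos(di, dj);
        dp.S[p] = bestv; dp.L[p] = bestl; dp.M[p] = bestm;
      }
    }
  }
}

// Step 4 support: per-cell canonical optima whose last column is a match.
// Returns one row per admissible end cell: extension length, scaled
// score, di, dj. The per-length reduction and pruning happen in R.
// [[Rcpp::export]]
DataFrame cpp_best_ends(std::string db, std::string query,
                        int db_origin, int q_origin, int dir,
                        double diag_lo, double diag_hi,
                        double max_di, double max_dj, int a, int b) {
  Walker wd(db, db_origin, dir), wq(query, q_origin, dir);
  long long maxdi = std::min((long long)max_di, wd.avail);
  long long maxdj = std::min((long long)max_dj, wq.avail);
  long long dmin = (long long)diag_lo, dmax = (long long)diag_hi;
  BandDP dp;
  fill_band_dp(dp, wd, wq, maxdi, maxdj, dmin, dmax, a, b);
  std::vector<int> len, vdi, vdj; std::vector<double> sc;
  for (long long di = 1; di <= maxdi; ++di) {
    long long djlo = std::max(1LL, di - dmax), djhi = std::min(maxdj, di - dmin);
    for (long long dj = djlo; dj <= djhi; ++dj) {
      size_t p = dp.pos(di, dj);
      if (dp.S[p] <= NEG_INF) continue;
      if (dp.M[p] != 1) continue;
      if (!chars_match(wd.at(di - 1), wq.at(dj - 1))) continue;
      len.push_back(dp.L[p]); sc.push_back((double)dp.S[p]);
      vdi.push_back((int)di); vdj.push_back((int)dj);
    }
  }
  return DataFrame::create(_["len"] = wrap(len), _["score"] = wrap(sc),
                           _["di"] = wrap(vdi), _["dj"] = wrap(vdj));
}

// Traceback of the canonical best path to one chosen end cell. Returns
// the column string in outward order (the R side reverses it for the
// left extension).
// [[Rcpp::export]]
std::string cpp_extension_traceback(std::string db, std::string query,
                                    int db_origin, int q_origin, int dir,
                                    double diag_lo, double diag_hi,
                                    double max_di, double max_dj,
                                    int target_di, int target_dj,
                                    int a, int b) {
  Walker wd(db, db_origin, dir), wq(query, q_origin, dir);
  long long maxdi = std::min((long long)max_di, wd.avail);
  long long maxdj = std::min((long long)max_dj, wq.avail);
  BandDP dp;
  fill_band_dp(dp, wd, wq, maxdi, maxdj,
               (long long)diag_lo, (long long)diag_hi, a, b);
  std::string cols;
  long long di = target_di, dj = target_dj;
  while (di > 0 || dj > 0) {
    uint8_t mv = dp.M[dp.pos(di, dj)];
    if (mv == 1) {
      cols.push_back(chars_match(wd.at(di - 1), wq.at(dj - 1)) ? '=' : 'X');
      --di; --dj;
    } else if (mv == 2) { cols.push_back('D'); --di; }
    else if (mv == 3)   { cols.push_back('I'); --dj; }
    else break;
  }
  std::reverse(cols.begin(), cols.end());
  return cols;
}

// ------------------------------------------------------------------
// Brute-force reference enumerator
// ------------------------------------------------------------------

struct Cand {
  int db_begin, db_end, q_begin, q_end, len, errors, maxrun;
};

// ranking for the maximality reduction: longer first, then fewer
// errors; ties between equal-length equal-error co-located variants are
// broken toward the candidate containing the longest exact segment (the
// variant anchored by the maximal core), then lexicographically
static bool cand_order(const Cand &x, const Cand &y) {
  if (x.len != y.len) return x.len > y.len;
  if (x.errors != y.errors) return x.errors < y.errors;
  if (x.maxrun != y.maxrun) return x.maxrun > y.maxrun;
  if (x.db_begin != y.db_begin) return x.db_begin < y.db_begin;
  if (x.q_begin != y.q_begin) return x.q_begin < y.q_begin;
  if (x.db_end != y.db_end) return x.db_end < y.db_end;
  return x.q_end < y.q_end;
}

// Canonical maximality reduction: candidates in decreasing length; a
// candidate is dropped if it equals a kept match or overlaps one (in both
// sequences) without a unique span of length >= n0 in either sequence.
static std::vector<Cand> reduce_maximal(std::vector<Cand> cands, int n0) {
  std::sort(cands.begin(), cands.end(), cand_order);
  std::vector<Cand> kept;
  for (const Cand &c : cands) {
    bool drop = false;
    for (const Cand &k : kept) {
      if (k.db_begin == c.db_begin && k.db_end == c.db_end &&
          k.q_begin == c.q_begin && k.q_end == c.q_end) { drop = true; break; }
      long long ovd = std::min(k.db_end, c.db_end) - std::max(k.db_begin, c.db_begin);
      long long ovq = std::min(k.q_end, c.q_end) - std::max(k.q_begin, c.q_begin);
      if (ovd <= 0 || ovq <= 0) continue;
      long long uniq = std::max((c.db_end - c.db_begin) - ovd,
                                (c.q_end - c.q_begin) - ovq);
      if (uniq < n0) { drop = true; break; }
    }
    if (!drop) kept.push_back(c);
  }
  std::sort(kept.begin(), kept.end(), [](const Cand &x, const Cand &y) {
    if (x.db_begin != y.db_begin) return x.db_begin < y.db_begin;
    if (x.q_begin != y.q_begin) return x.q_begin < y.q_begin;
    if (x.db_end != y.db_end) return x.db_end < y.db_end;
    return x.q_end < y.q_end;
  });
  return kept;
}

// Exhaustive enumeration of maximal eps-matches without eps-X-drop: one
// banded DP per match-character start cell, tracking along the canonical
// optimal path (same tie-breaks as the pipeline: max score, then minimal
// length, then diagonal > up > left) the score, length, and the running
// deficit below the path maximum (the X-drop state).
// [[Rcpp::export]]
DataFrame cpp_bruteforce(std::string db, std::string query,
                         int a, int b, int n0, double xdrop_scaled) {
  const long long n = (long long)db.size(), m = (long long)query.size();
  if (n * m > 2000000)
    stop("brute-force oracle refuses |db|*|query| > 2e6");
  const long long err = (long long)a - b;
  const long long DT = (xdrop_scaled > 4e17) ? (long long)4e17
                                             : (long long)xdrop_scaled;
  // max diagonal drift of any eps-valid path
  long long band = ((n + m) * a) / b + 2;
  std::vector<Cand> cands;

  // One DP per match-character start cell. Arrays are allocated once at
  // the maximal band size and reused across starts via epoch stamps; a
  // cell is pruned once it can no longer reach a non-negative score even
  // if every remaining column were a match.
  const long long bwmax = 2 * band + 1;
  std::vector<long long> S((size_t)((n + 1) * bwmax), 0);
  std::vector<int> L((size_t)((n + 1) * bwmax), 0);
  std::vector<long long> D((size_t)((n + 1) * bwmax), 0);  // deficit
  std::vector<uint8_t> drop((size_t)((n + 1) * bwmax), 0);
  std::vector<uint32_t> stamp((size_t)((n + 1) * bwmax), 0);
  // boundary signatures of the canonical path, used to exclude padded
  // candidates (see the admissibility check below): trailing state
  // (length of the trailing match run, size/type of the indel block
  // right before it) and leading state (leading match run, following
  // indel block, frozen once a third block starts)
  std::vector<int> TR((size_t)((n + 1) * bwmax), 0),
                   TT((size_t)((n + 1) * bwmax), 0),
                   TY((size_t)((n + 1) * bwmax), 0),
                   LR((size_t)((n + 1) * bwmax), 0),
                   LT((size_t)((n + 1) * bwmax), 0),
                   LY((size_t)((n + 1) * bwmax), 0);
  std::vector<uint8_t> LF((size_t)((n + 1) * bwmax), 0);
  std::vector<int> MR((size_t)((n + 1) * bwmax), 0);  // longest match run
  uint32_t epoch = 0;

  for (long long i0 = 0; i0 < n; ++i0) {
    for (long long j0 = 0; j0 < m; ++j0) {
      if (!chars_match(db[i0], query[j0])) continue;
      ++epoch;
      long long maxdi = n - i0, maxdj = m - j0;
      long long dmin = -std::min(band, maxdj), dmax = std::min(band, maxdi);
      long long bw = dmax - dmin + 1;
      auto P = [&](long long di, long long dj) {
        return (size_t)(di * bw + (di - dj - dmin));
      };
      auto get = [&](long long di, long long dj) {
        if (di < 0 || di > maxdi || dj < 0 || dj > maxdj) return NEG_INF;
        long long d = di - dj;
        if (d < dmin || d > dmax) return NEG_INF;
        size_t p = P(di, dj);
        return stamp[p] == epoch ? S[p] : NEG_INF;
      };
      // first column is forced to be the match at the start cell
      size_t p11 = P(1, 1);
      S[p11] = a; L[p11] = 1; D[p11] = 0; drop[p11] = 0; stamp[p11] = epoch;
      TR[p11] = 1; TT[p11] = 0; TY[p11] = 0; MR[p11] = 1;
      LR[p11] = 1; LT[p11] = 0; LY[p11] = 0; LF[p11] = 0;
      for (long long di = 1; di <= maxdi; ++di) {
        long long djlo = std::max(1LL, di - dmax),
                  djhi = std::min(maxdj, di - dmin);
        bool row_alive = false;
        for (long long dj = djlo; dj <= djhi; ++dj) {
          if (di == 1 && dj == 1) { row_alive = true; continue; }
          long long bestv = NEG_INF; int bestl = 0; uint8_t bm = 0;
          bool mt = chars_match(db[i0 + di - 1], query[j0 + dj - 1]);
          long long p1 = get(di - 1, dj - 1);
          if (p1 > NEG_INF) {
            long long v = p1 + (mt ? (long long)a : err);
            int l = L[P(di - 1, dj - 1)] + 1;
            if (v > bestv || (v == bestv && l < bestl)) { bestv = v; bestl = l; bm = 1; }
          }
          long long p2 = get(di - 1, dj);
          if (p2 > NEG_INF) {
            long long v = p2 + err; int l = L[P(di - 1, dj)] + 1;
            if (v > bestv || (v == bestv && l < bestl)) { bestv = v; bestl = l; bm = 2; }
          }
          long long p3 = get(di, dj - 1);
          if (p3 > NEG_INF) {
            long long v = p3 + err; int l = L[P(di, dj - 1)] + 1;
            if (v > bestv || (v == bestv && l < bestl)) { bestv = v; bestl = l; bm = 3; }
          }
          if (bestv <= NEG_INF) continue;
          // unreachable-score pruning: all-match future gain cannot lift
          // this path back to a valid (score >= 0) end
          if (bestv + std::min(maxdi - di, maxdj - dj) * (long long)a < 0)
            continue;
          size_t pp = P(di, dj);
          size_t pr = (bm == 1) ? P(di - 1, dj - 1)
                    : (bm == 2) ? P(di - 1, dj) : P(di, dj - 1);
          long long c = (bm == 1 && mt) ? (long long)a : err;
          long long nd = std::max(0LL, D[pr] - c);
          S[pp] = bestv; L[pp] = bestl;
          D[pp] = std::min(nd, DT);
          drop[pp] = drop[pr] || (nd >= DT);
          stamp[pp] = epoch;
          row_alive = true;
          // boundary-signature update for the appended column:
          // col = 0 match, 1 mismatch, 2 D (up), 3 I (left)
          {
            int col = (bm == 1) ? (mt ? 0 : 1) : (int)bm;
            if (col == 0) {
              TR[pp] = TR[pr] > 0 ? TR[pr] + 1 : 1;
              TT[pp] = TT[pr]; TY[pp] = TY[pr];
            } else if (col == 1) {
              TR[pp] = 0; TT[pp] = 0; TY[pp] = 0;
            } else {
              int ty = (col == 2) ? 2 : 3;
              if (TR[pr] == 0 && TY[pr] == ty) TT[pp] = TT[pr] + 1;
              else TT[pp] = 1;
              TY[pp] = ty; TR[pp] = 0;
            }
            MR[pp] = std::max(MR[pr], TR[pp]);
            if (LF[pr]) {
              LR[pp] = LR[pr]; LT[pp] = LT[pr]; LY[pp] = LY[pr]; LF[pp] = 1;
            } else if (col == 0) {
              if (LT[pr] == 0) { LR[pp] = LR[pr] + 1; LT[pp] = 0; LY[pp] = 0; LF[pp] = 0; }
              else { LR[pp] = LR[pr]; LT[pp] = LT[pr]; LY[pp] = LY[pr]; LF[pp] = 1; }
            } else if (col == 1) {
              LR[pp] = LR[pr]; LT[pp] = LT[pr]; LY[pp] = LY[pr]; LF[pp] = 1;
            } else {
              int ty = (col == 2) ? 2 : 3;
              if (LT[pr] == 0 || LY[pr] == ty) {
                LR[pp] = LR[pr]; LT[pp] = LT[pr] + 1; LY[pp] = ty; LF[pp] = 0;
              } else {
                LR[pp] = LR[pr]; LT[pp] = LT[pr]; LY[pp] = LY[pr]; LF[pp] = 1;
              }
            }
          }
          // emit candidate if admissible: last column a match, no
          // epsilon-X-drop, valid rate and length, and not a padded
          // variant of a shorter candidate (a boundary indel block that
          // re-pairs a repeated subsequence adds only error columns)
          if (bm == 1 && mt && !drop[pp] && bestv >= 0 && bestl >= n0) {
            bool padded = false;
            long long x1 = i0, y1 = j0, x2 = i0 + di, y2 = j0 + dj;
            if (TT[pp] >= 1 && bestl - TT[pp] >= n0) {
              int t = TT[pp], r = TR[pp];
              bool all = true;
              for (int i = 0; i < r && all; ++i) {
                if (TY[pp] == 3) all = db[x2 - 1 - i] == query[y2 - 1 - t - i];
                else             all = db[x2 - 1 - t - i] == query[y2 - 1 - i];
              }
              if (all) padded = true;
            }
            if (!padded && LT[pp] >= 1 && bestl - LT[pp] >= n0) {
              int t = LT[pp], r = LR[pp];
              bool all = true;
              for (int i = 0; i < r && all; ++i) {
                if (LY[pp] == 3) all = db[x1 + i] == query[y1 + t + i];
                else             all = db[x1 + t + i] == query[y1 + i];
              }
              if (all) padded = true;
            }
            if (!padded) {
              Cand cd;
              cd.db_begin = (int)x1; cd.q_begin = (int)y1;
              cd.db_end = (int)x2; cd.q_end = (int)y2;
              cd.len = bestl; cd.errors = (int)(((long long)bestl * a - bestv) / b);
              cd.maxrun = MR[pp];
              cands.push_back(cd);
            }
          }
        }
        if (!row_alive) break;
      }
      if (cands.size() > 5000000)
        stop("brute-force oracle: candidate explosion");
    }
  }

  std::vector<Cand> kept = reduce_maximal(cands, n0);
  int N = (int)kept.size();
  IntegerVector db0(N), db1(N), q0(N), q1(N), ln(N), er(N);
  for (int k = 0; k < N; ++k) {
    db0[k] = kept[k].db_begin; db1[k] = kept[k].db_end;
    q0[k] = kept[k].q_begin; q1[k] = kept[k].q_end;
    ln[k] = kept[k].len; er[k] = kept[k].errors;
  }
  return DataFrame::create(_["db_begin"] = db0, _["db_end"] = db1,
                           _["q_begin"] = q0, _["q_end"] = q1,
                           _["length"] = ln, _["errors"] = er);
}

// Shared canonical overlap reduction for the pipeline's Step 5
// (separate entry point; same rule definition as the oracle's reducer,
// applied to pipeline matches).
// [[Rcpp::export]]
DataFrame cpp_reduce_overlaps(IntegerVector db_begin, IntegerVector db_end,
                              IntegerVector q_begin, IntegerVector q_end,
                              IntegerVector len, IntegerVector errors,
                              IntegerVector maxrun, int n0) {
  int N = db_begin.size();
  std::vector<Cand> cands(N);
  std::vector<int> ord;
  for (int k = 0; k < N; ++k) {
    cands[k].db_begin = db_begin[k]; cands[k].db_end = db_end[k];
    cands[k].q_begin = q_begin[k]; cands[k].q_end = q_end[k];
    cands[k].len = len[k]; cands[k].errors = errors[k];
    cands[k].maxrun = maxrun[k];
  }
  // keep original indices so R can carry full match records through
  std::vector<int> idx(N);
  for (int k = 0; k < N; ++k) idx[k] = k;
  std::sort(idx.begin(), idx.end(), [&](int x, int y) {
    return cand_order(cands[x], cands[y]);
  });
  std::vector<int> keptIdx;
  for (int id : idx) {
    const Cand &c = cands[id];
    bool dropf = false;
    for (int kid : keptIdx) {
      const Cand &k = cands[kid];
      if (k.db_begin == c.db_begin && k.db_end == c.db_end &&
          k.q_begin == c.q_begin && k.q_end == c.q_end) { dropf = true; break; }
      long long ovd = std::min(k.db_end, c.db_end) - std::max(k.db_begin, c.db_begin);
      long long ovq = std::min(k.q_end, c.q_end) - std::max(k.q_begin, c.q_begin);
      if (ovd <= 0 || ovq <= 0) continue;
      long long uniq = std::max((c.db_end - c.db_begin) - ovd,
                                (c.q_end - c.q_begin) - ovq);
      if (uniq < n0) { dropf = true; break; }
    }
    if (!dropf) keptIdx.push_back(id);
  }
  std::sort(keptIdx.begin(), keptIdx.end(), [&](int x, int y) {
    const Cand &cx = cands[x], &cy = cands[y];
    if (cx.db_begin != cy.db_begin) return cx.db_begin < cy.db_begin;
    if (cx.q_begin != cy.q_begin) return cx.q_begin < cy.q_begin;
    if (cx.db_end != cy.db_end) return cx.db_end < cy.db_end;
    return cx.q_end < cy.q_end;
  });
  IntegerVector keep(keptIdx.size());
  for (size_t k = 0; k < keptIdx.size(); ++k) keep[k] = keptIdx[k] + 1;
  return DataFrame::create(_["keep"] = keep);
}
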