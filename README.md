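# epsaligner

Exact pairwise local alignment of DNA sequences under an error-rate
threshold.

Heuristic local aligners are fast but miss matches. epsaligner instead
guarantees to report **all** maximal local alignments between two
sequences that have

* length at least `n0` columns, and
* error rate at most `eps` — edit distance (mismatches + indels)
  divided by alignment length,

excluding alignments that contain an *ε-X-drop* (a run of columns whose
score drops by `X·(1/eps − 1)` or more, i.e. local dissimilarity worth
`X` uninterrupted errors). Such alignments are called
**ε-matches**; of two overlapping ε-matches only the longer is
reported unless the shorter has a unique part of length `n0`.

The search runs in two phases:

1. **Lossless SWIFT filtration** — q-gram hits counted in overlapping
   diagonal bins; a counter reaching τ marks a parallelogram of the
   dotplot that provably intersects every ε-match in an error-free
   segment of length `s_min = min(l(n0, eps), l(n1, eps))`, where
   `l(n, eps) = ceil((n − floor(eps·n)) / (floor(eps·n) + 1))` and `n1`
   is the next length admitting one more error.
2. **Five-step exact verification** — banded Waterman–Eggert core
   search, ε-X-drop core splitting, gapped X-drop extension,
   maximal-match cutting over a `bestEnds` table, and global overlap
   removal.

All rate comparisons are integer-exact: `eps = a/b` is kept as a
rational, a match scores `+a`, an error `a − b`, and `score ≥ 0` is
exactly `errors·b ≤ length·a`. A brute-force enumerator
(`bruteforce_eps_matches()`) provides an independent reference
implementation of the same match definition, and the test suite
requires the two routes to agree exactly on randomized instances.

## Worked example

```r
library(epsaligner)

params <- derive_params("0.1", 50, x_drop = 5)
params
#> epsilon-match search parameters
#>   eps     = 1/10 (0.1)
#>   n0      = 50    X = 5
#>   scoring = match +1, error -9 (scaled by 1)
#>   s_min   = 8    q = 8
#>   tau     = 3    e = 5    w = 50    delta = 64

sim <- simulate_pair(5000, 5000, 3, c(80, 150), 0.075, seed = 11)
matches <- eps_align(sim$db, sim$query, params)
matches$evalue <- evalue(matches, 5000, 5000)
matches[, c("db_begin", "db_end", "q_begin", "q_end",
            "length", "errors", "identity", "evalue")]
#>   db_begin db_end q_begin q_end length errors identity   evalue
#> 1     1114   1218    1122  1225    108     10     90.7 6.08e-39
#> 2     2434   2556    2412  2537    127     12     90.6 1.82e-46
#> 3     3783   3921    3731  3863    141     13     90.8 7.82e-53

coverage(matches, sim$truth)$missed_pct
#> [1] 0
```

The parameter line says: with `eps = 0.1` and `n0 = 50`, every
acceptable match must contain an error-free segment of `s_min = 8`
columns, so the filter indexes 8-grams and demands `tau = 3` hits in a
diagonal bin. The three reported matches recover the three planted
alignments exactly — each at least 50 columns long, at most 10% errors,
coordinates 1-based inclusive. `identity` is the percentage of match
columns and `evalue` the Karlin–Altschul expectation for a match of
that score in a 5 kb × 5 kb search.

Sequences come in and out as plain strings or FASTA via
`read_fasta()`/`write_gff()`; a command-line interface is installed as
`exec/epsaligner`:

```sh
epsaligner db.fa query.fa -e 0.05 -l 100 -x 5 -o matches.gff
```

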