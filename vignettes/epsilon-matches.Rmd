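---
title: "Exact local alignment under an error-rate threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact local alignment under an error-rate threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epsaligner)
```

## The model

epsaligner reports **all** local alignments between two DNA sequences
that satisfy a simple, two-parameter quality definition under the edit
distance model:

* length $n \ge n_0$ columns, and
* **error rate** $\le \varepsilon$, where the error rate is the number
  of non-match columns (mismatches, insertions, deletions — all treated
  equally) divided by $n$.

Such an alignment is an **$\varepsilon$-match**. Two refinements make
the reported set finite and useful:

* **No $\varepsilon$-X-drop.** A run of columns whose score drops by
  $X \cdot (1/\varepsilon - 1)$ or more under the scoring below marks
  local dissimilarity; matches containing such a run are excluded (the
  parameter $X$ is expressed in *errors*, so it is easy to reason
  about: $X$ consecutive errors with no matches in between form a
  drop).
* **Maximality.** Of two overlapping matches only the longer is
  reported, unless the shorter has a unique part of length $n_0$ in one
  of the sequences.

All arithmetic is exact. The rate $\varepsilon = a/b$ is kept as a
rational in lowest terms; a match column scores $+a$ and an error
column $a - b$, so

$$ \text{score} \ge 0 \iff \text{errors} \cdot b \le n \cdot a \iff
   \text{error rate} \le \varepsilon, $$

with no floating point anywhere in a comparison. Boundary cases such as
$2/22$ versus $3/28$ at $\varepsilon = 0.1$ are therefore decided
exactly.

## Parameters and derived constants

```{r}
derive_params("0.1", 20, x_drop = 3)
```

| constant | meaning | default/derivation |
|---|---|---|
| $\varepsilon$ | maximal error rate | user; accepted range $(0, 0.25]$ |
| $n_0$ | minimal match length (columns) | user; $\ge 10$ |
| $X$ | X-drop bound, in errors | user; default 5 |
| $s^{\min}$ | guaranteed error-free segment length | $\min(l(n_0), l(n_1))$, see below |
| $q$ | q-gram length of the filter | $= s^{\min}$ (exactness requires it) |
| $\tau$ | q-hit counter threshold | sawtooth minimum, see below |
| $e$ | diagonal band width of a bin | error count of the plateau attaining $\tau$ |
| $w$ | parallelogram column span | $n_0$ |
| $\Delta$ | diagonal bin stride | smallest power of two $\ge w$ |

Every $\varepsilon$-match of length $n$ has at most
$\lfloor \varepsilon n \rfloor$ errors, which split it into error-free
segments; the longest one has length at least
$l(n, \varepsilon) = \lceil (n - \lfloor \varepsilon n \rfloor) /
(\lfloor \varepsilon n \rfloor + 1) \rceil$. This function is a
sawtooth in $n$: just above each length that admits one more error it
dips before growing again, and its minima increase. The minimum over
all $n \ge n_0$ is therefore attained at $n_0$ itself or at the next
error plateau $n_1$, giving $s^{\min}$ — both the seed length every
match must contain and the default q-gram length.

The q-gram lemma bounds the number of **q-hits** (diagonal runs of $q$
match columns) of an alignment of length $n$ with $k$ errors by
$T(n,k,q) = n + 1 - q(k+1)$. This bound is *also* a sawtooth in $n$
when $k = \lfloor \varepsilon n \rfloor$: the counter threshold $\tau$
must be its minimum over all lengths $\ge n_0$, not just
$T(n_0, \lfloor \varepsilon n_0 \rfloor, q)$. For the classic worked
setting ($\varepsilon = 0.1$, $n_0 = 20$) both give $\tau = 3$, $e=2$;
but for example at $\varepsilon = 0.05$, $n_0 = 15$, $q = 10$ the
closed formula would give 6 while a 21-column match with one central
error has only 2 q-hits — the sawtooth minimum (here 1) is what keeps
the filter lossless. The bin width $e$ follows the plateau that attains
the minimum so that the hits of such a match still share a bin.

## Filtration

A q-gram index of the database is scanned with the overlapping q-grams
of the query. Hits are counted in bins of $\Delta + e$ consecutive
diagonals whose first diagonal is a multiple of $\Delta$ (adjacent bins
share $e$ diagonals, so every relevant parallelogram lies wholly in
one bin). A bin whose counter reaches $\tau$ with inter-hit column gaps
of at most $w - q$ is emitted as a **SWIFT hit**. Emitted windows are
widened by $e$ columns and diagonals before verification, so the banded
dynamic programming can realize alignments touching the parallelogram
border; widening can only add candidate cores, never lose one. q-grams
containing `N` never hit, and `N` aligns only as a mismatch downstream.

## Verification

Each hit is verified in five steps; verification may stop early
whenever no new match can result.

1. **Core identification.** A banded Waterman–Eggert search inside the
   hit's parallelogram returns all non-overlapping local alignments
   with scaled score $\ge a \cdot s^{\min}$ ("cores"), by iterated
   best-alignment, trace clearing and recomputation.
2. **X-drop splitting.** A linear scan decomposes each core so that no
   piece contains a run scoring $\le -X(b-a)$; only the outermost
   pieces are flagged for extension (extension of middle pieces would
   immediately run back into the detected drops).
3. **Gapped X-drop extension.** Score-only DP from the flagged core
   ends; a cell falling $X(b-a)$ or more below the running best is
   pruned, and the sweep stops when a row's alive window empties. The
   sweep is organised by *rows*, not anti-diagonals: an anti-diagonal
   sweep has a parity artifact in which the gap-cells between two
   match-run cells can all fall below the bound and terminate a sweep
   whose path is still healthy. The surviving band of diagonals and the
   region extent delimit Step 4.
4. **Maximal-match cutting.** A banded DP over each extension region
   records, per extension length, the best (unnormalized-score) end
   cell whose canonical path ends in a match column — the `bestEnds`
   list — and an exhaustive combination search over (left cut, right
   cut) pairs finds the longest total alignment with non-negative
   scaled score and length $\ge n_0$. Further co-located maximal
   matches (a unique part of $n_0$ columns beyond either end) are found
   by recursing on reduced lists. Tracebacks produce full column
   strings.
5. **Overlap removal.** Candidates from all hits are reduced globally:
   processed in decreasing length (ties: fewer errors, then the longest
   exact segment, then coordinates), a match is dropped if it is
   identical to a kept one or overlaps a kept one in both sequences
   without a unique span of $n_0$.

## Design choices in Step 4 and the reduction

These were the genuinely open parts of the design; the choices and the
reasons:

* **Canonical alignments.** "The longest alignment with error rate
  $\le \varepsilon$" is degenerate if read over *all* paths: any match
  column can be inflated into an insertion+deletion pair, so length
  could be padded for as long as the error budget lasts. A match is
  therefore defined over a substring pair through its *canonical*
  alignment: maximum scaled score, then minimal length, ties broken by
  the fixed traceback preference diagonal > deletion > insertion, with
  first and last columns required to be matches. Every assembled
  candidate is re-canonicalized for its exact endpoints before any
  admissibility test, so judgments never depend on which core seeded
  the match.
* **Boundary-padding exclusion.** At a repeat boundary an alignment can
  be extended by one column per extra error by re-pairing the repeated
  bases across an indel — same number of match columns, strictly worse
  rate, "longer" only in the degenerate sense. Candidates whose
  canonical alignment starts or ends with an indel block that merely
  re-pairs a repeated subsequence are excluded (the trimmed variant,
  when itself reportable, represents the location).
* **No bestEnds pruning.** The classic per-length pruning rule ("drop
  length $l$ if length $l+1$ gains a full match") is an optimization
  that is redundant under an exhaustive combination search — a longer
  valid entry always dominates — and it can discard a length whose
  longer neighbour later proves inadmissible because its trace contains
  an $\varepsilon$-X-drop. The implementation keeps all lengths, plus
  equally-scoring alternate end cells per length, and picks among the
  admissible traces with the same comparator the global reduction uses.
* **Band widening.** The Step-4 band is the Step-3 alive band widened
  by $e + \min(X, 10)$ diagonals per side: a drop-free trace can step a
  few diagonals beyond the cells a score-only pruned sweep kept alive.
* **Chain resolution.** Dropping a match that is dominated by a longer
  one can expose a shorter co-located match from the same core that is
  maximal in the *final* set (domination is not transitive). After the
  global reduction, the cores of dominated matches are re-searched
  under the constraint that candidates must survive against the kept
  set, until the reduction is stable.

## The brute-force reference

`bruteforce_eps_matches()` is an independent enumerator used as the
correctness oracle: one banded DP per match-character start cell
computes, for every end cell, the canonical alignment (score, length,
X-drop deficit, boundary signatures), collects every admissible
candidate, and applies the same reduction rule. It shares the
*definitions* above with the pipeline but none of the filtration or
five-step machinery, and it is quadratic per start cell — hence the
guard $|db| \cdot |query| \le 10^5$. The package's central test runs
both routes over a grid of random planted instances
($\varepsilon \in \{0.05, 0.1\}$, $n_0 \in \{15, 20, 30\}$,
$X \in \{3, 10, 10^6\}$, sides up to 300 bp) and requires the match
sets to be identical in coordinates and error counts.

## The simulator, and what passing tests mean

`simulate_pair()` emulates the evaluation data the method is built for:
uniform i.i.d. DNA with planted local alignments of 50–200 bp whose
column sequences carry exactly $\lfloor \text{rate} \cdot L \rfloor$
errors, drawn uniformly among mismatch/insertion/deletion, with
adjacent insertion+deletion pairs rejected (they would silently cancel)
and error columns kept interior so planted coordinates are exact.
Planted segments are non-overlapping and separated by at least $n_0$
random positions in each sequence, which makes the planted matches
unambiguously maximal. A run is reproducible from its seed.

What the simulator does *not* emulate: repeat families, tandem
repeats, GC bias, indel length distributions of real genomes, or
low-complexity sequence. Full sensitivity on simulated data therefore
demonstrates the exactness of the machinery under the stated model; on
real genomes the guarantee still holds per the theorem, but runtime
and the number of reported matches are dominated by repeat structure
that these tests do not probe.

Sensitivity is scored with a deliberately loose coverage criterion: a
planted record counts as found if at least 10% of its alignment
columns (as coordinate pairs) lie inside some reported match's
intervals, and as **missed** otherwise. `run_benchmark()` wraps
simulate–align–score into a table.

Problem sizes used by the shipped tests: the benchmark blocks use
100 kb sequence pairs with 50 planted alignments (the exactness
argument is scale-free, and this keeps a full test run in minutes);
the oracle-equivalence block uses 216 instances with sides of 100–300
bp. The "large X" used in the benchmarks is $X = 50$ errors — large
enough that no planted alignment (at most 20 errors) can contain a
drop, small enough that extensions into random flanks terminate.

## E-values

The E-value annotation uses an ungapped Karlin–Altschul model with
BLASTN-like unit scores (+1 match, −2 mismatch; gap columns scored as
mismatches) and uniform base frequencies: $E = K m n e^{-\lambda S}$
with $\lambda$ the positive root of
$\frac14 e^{\lambda} + \frac34 e^{-2\lambda} = 1$ (for this grid,
$e^\lambda = (3+\sqrt{21})/2$) and $K$ fixed at 0.34 as an
approximation. The *minimal E-value* printed at startup is the E-value
of the least significant match the parameters accept — a length-$n_0$
alignment with $\lfloor \varepsilon n_0 \rfloor$ errors — and bounds
the E-value of every reported match. The constants are documented as
approximations; E-values annotate significance and are not part of the
match definition.

## Degenerate inputs and numerical corners

* `N` (and any non-ACGTN character, mapped to `N` on input) never
  matches and never seeds a q-gram.
* $X = 0$ makes every error column a drop: only error-free matches are
  reported. Very large $X$ disables splitting and extension pruning;
  the brute-force guard and the benchmark design keep that affordable.
* A `q` override away from $s^{\min}$ is accepted for experimentation
  but voids the exactness guarantee (a warning says so); an override
  that makes $\tau < 1$ is rejected.
* All integer scaling uses the numerator $a$; with $b \le 40$
  (\(\varepsilon \ge 0.025\)) and chromosome-scale lengths all scores
  fit comfortably in 64-bit integers.

## Known limitations

* The filter loses specificity as $\varepsilon$ grows; rates above
  0.25 are rejected, and runtimes grow noticeably already between 0.05
  and 0.1 on large inputs.
* The reverse strand is handled by aligning against the reverse
  complement and mirroring coordinates; minus-strand `columns` strings
  are reported in reverse-complement orientation.
* Affine gap costs, protein alphabets and match chaining are out of
  scope.
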