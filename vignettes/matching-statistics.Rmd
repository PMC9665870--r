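---
title: "Matching statistics: computation, compact encoding, lossy compression and range analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching statistics: computation, compact encoding, lossy compression and range analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchstat)
```

## The statistic and its encoding

Given a query $S$ of length $m$ and a text $T$ over an integer alphabet
$[1..\sigma]$, the matching statistics array $\mathrm{MS}[0..m-1]$ holds at
position $i$ the length of the longest prefix of $S[i..]$ that occurs
*anywhere* in $T$.  Because a match starting at $i+1$ can always be obtained
by chopping the first character off a match starting at $i$, the array obeys
the slope invariant $\mathrm{MS}[i+1] \ge \mathrm{MS}[i] - 1$.  This makes a
unary difference code compact: appending, for each $i$ in order,
$\mathrm{MS}[i]-\mathrm{MS}[i-1]+1$ zeros and a one (with
$\mathrm{MS}[-1]=1$) yields a bitvector of exactly $2m$ bits in which the
number of zeros before the $i$-th one equals $i + \mathrm{MS}[i]$, so

$$\mathrm{MS}[i] = \mathrm{select}_1(\mathit{ms}, i) - 2i .$$

`encodeMS()`, `decodeMS()` and `msAccess()` implement this container
(`MSBitvector`).  One boundary convention is ours: the final value of a true
matching statistics array is 0 or 1, so the emitted stream is $2m$ or $2m-1$
bits; we always right-pad with zeros to exactly $2m$ and make decoding ignore
bits after the $m$-th one.  Hand-built arrays ending above 1 are legal for
the encoder but longer than $2m$; the true pipeline never produces them.

## The two-phase scan

`matchingStatistics()` computes the array with backward search over the
Burrows–Wheeler transform, in two sweeps connected by the `runs` bitvector
($\mathrm{runs}[i]=1$ iff $\mathrm{MS}[i]=\mathrm{MS}[i-1]-1$):

* **Phase 1** scans $S$ right to left over the index of $T$.  It keeps the
  lexicographic interval of the current match and tries one backward step
  per position; on failure it climbs *parent intervals* until the step
  succeeds or the interval is the whole suffix array.
* **Phase 2** scans $S$ left to right over the index of *reversed* $T$,
  extending the current match one character at a time.  Each failure
  finalizes one zero run of the encoding, and the `runs` bitvector gives the
  length of the one run that follows, so the output is built in one pass.

The suffix-tree topology that usually backs the parent operation is replaced
here by LCP-interval navigation: the parent of an interval is the smallest
lcp-interval strictly containing it, computed in constant time from the LCP
array with previous/next-smaller-value tables.  The contract (the parent of
a locus, and nothing else) is identical, and it removes an entire balanced-
parentheses machinery.  Indexes are built by prefix doubling over base R's
radix sort and Kasai's algorithm; a naive full-suffix-sort oracle guards
them in the tests.

A supplementary extension (`msWithFrequencies()`) reports, for every
position, the occurrence count in $T$ of the exact matched string: the
width of its interval at the moment the value is finalized.  For positions
finalized implicitly through the `runs` bitvector we recover the width from
the depth brackets visited during the parent ascents.  When the match ends
in the middle of a suffix-tree edge the matched string and its locus have
the same interval, so reporting the exact string's count is well defined;
positions with $\mathrm{MS}[i]=0$ report 0, avoiding a convention for the
frequency of the empty string.

`computePLCPBitvector()` reuses the same encoding for the permuted LCP
array of a single text (LCP values in text order), which obeys the same
slope invariant; everything downstream (compression, range queries) applies
to it unchanged.

## Parallel construction by blocks

For long queries, `computeRunsParallel()` partitions $S$ into $t$
near-equal blocks.  Each block is scanned fresh from the root, so the bits
to the right of a block's first-from-right zero are provisional ones: a
fresh scan can only overestimate a match, and a failed backward step from a
shorter (truncated) match implies failure for the true match, after which
the two states coincide.  Blocks containing a zero, plus the last block,
are *marked*; a correction pass re-runs the scan leftward from each marked
block's stored state through the intervening all-ones blocks.  One design
choice is deliberate: we store the state *after* the block's last failure
(the match for the position left of the block boundary) rather than the
match at the boundary itself, because when a block's only zero sits at its
first bit the boundary state may still be the truncated one, while the
post-failure state is provably resynchronized.  The contract enforced by
the tests is bit-identity with the sequential scan for every block count,
including the adversarial $S=T$ case where only the last block is marked.

`computeMSParallel()` builds each block's encoding independently (phase 2
may read $S$ and `runs` arbitrarily far right) and fixes each block's
leading zero run during concatenation, using
$\mathrm{MS}[p_i-1] = |\mathit{ms}_{i-1}| - 2|S_{i-1}| + 1$.

Tasks run on a deterministic sequential scheduler.  The algorithmic content
of the scheme is the decomposition, marking and correction logic — which a
thread pool would execute unchanged — and a deterministic schedule keeps
the suite reproducible on any machine.

## Lossy thresholded compression

Applications that treat short matches as noise only need values
$\ge \tau$ exactly.  A thresholded bitvector must be a permutation of the
original in which every *anchor* (a one-bit whose value is $\ge \tau$)
keeps its position and rank; between consecutive anchors the zeros and ones
may be rearranged as long as every rewritten value stays below $\tau$ (and
above a floor, 0 by default).  `compressMS()` chooses, per window, the
arrangement whose run-length code is smallest, via a dynamic program over
cumulative run pairs $(Z_i, O_i)$: a pair is valid when the value
$\tau + Z_i - O_i$ at its last one-bit lies in $[\mathrm{minValue},
\tau-1]$, arcs additionally require the value at the *first* one-bit of the
new run to stay below $\tau$, and the DP minimizes the summed code length
over the topologically ordered pair DAG.  Ties prefer fewer runs, then the
smallest predecessor, so results are reproducible.

Window boundary conventions we had to fix ourselves:

* A window that ends at an anchor must end with at least one zero (a one
  adjacent to the anchor would carry a value above the anchor's), and with
  baseline $\tau$ it must begin with ones — both facts come out of the
  validity constraints rather than special cases.
* The prefix window before the first anchor has no left anchor; its
  baseline is the encoding convention $\mathrm{MS}[-1] = 1$, and the suffix
  window after the last anchor may end with ones (it is "free").
* Windows between anchors that are adjacent in the query contain no ones
  and are trivially kept (their anchor value may exceed $\tau$; with ones
  present the gap property forces the left anchor's value to be exactly
  $\tau$, which the code asserts by using the actual decoded value as the
  baseline).

Cost variants: **ND** codes every run in isolation with the Elias-delta
length $|\delta(n)| = \lfloor\log_2 n\rfloor +
2\lfloor\log_2(\lfloor\log_2 n\rfloor + 1)\rfloor + 1$ (the encoder is
pluggable; delta is the standard choice for run lengths).  **D** exploits
the empirical correlation between a zero run and the following one run by
coding the pair as $\delta(x) + \delta(g(y\,|\,x))$, where `gMap()` is a
bijection sending $y$ near $x$ to small integers.  **DL** applies the
paired code only when $x \ge \tau$.  For D and DL the boundary one-run
after an anchor and the zero run before the next anchor are kept fixed and
only the span from the first zero to the last one is permuted; we read the
underspecified "optimal permutation" of these variants as the same pair DAG
with the variant's arc costs, constrained to start with a zero run and end
with a one run.  When negative rewritten values are acceptable the ND
window is simply all ones followed by all zeros; D and DL run the DP with
the floor released.  Infeasible windows (possible when a positive floor is
requested) fall back to identity and are reported.

`buildWindowDAG()` precomputes the DP once up to caps on window size
(the interior table is query-independent), and `queryDAG()` answers any
in-cap window by a terminal minimization plus backtracking; out-of-cap
queries take greedy steps (largest progress, or largest progress per code
bit) until they reach a precomputed node.  If both greedy strategies stall
the query is reported infeasible and the caller keeps the window as
identity.

`rleSize()`/`sparseSizeA()`/`sparseSizeB()` provide the measured
representation and the store-only-the-big-values baselines;
`compressionReport()` tabulates them.  Sizes here are pure code lengths
(run codes plus one bit for the leading bit value), not an on-disk
container with rank/select directories, so ratios against container-based
measurements differ by a constant factor.

## Range queries

`buildBlockIndex()` cuts the bitvector into $B$-bit blocks (default 1024
bits, a size at which a query costs about two block scans plus one RMQ) and
stores per block the maximum value at a one-bit, the one count and a prefix
sum, plus a sparse-table RMQ over the block maxima.  `rangeMax()`,
`rangeSum()` and `reportGE()` (recursive RMQ descent, output-sensitive)
follow; `msHistogram()`, `longestCover()` and `maxWindows()` are scan-based
analytics.  Two scanning backends (`scanChunk()`) decode the value stream
either 8 bits at a time through a 256-entry table or run by run from an RLE
container, and must agree exactly.  Queries whose answers only involve
values $\ge \tau$ agree between the original and any $\tau$-thresholded
permutation, because anchors are fixed — so a compressed bitvector can be
swapped in for free.  Range indices are query positions, not bit positions;
with negative-value containers the prefix-sum monotonicity is simply not
assumed.  The succinct-space bound for the RMQ is out of scope: the
contract here is correct answers, guarded by full-decode oracles.

## The synthetic generator

`synthPair(n, rho, sigma, seed, mix)` draws $T$ uniformly over
$[1..\sigma]$ and derives $S$ by independent per-position edits at rate
$\rho$ (substitutions to a different uniform symbol by default; insertion
and deletion weights available).  It emulates the controlled-mutation-rate
string pairs used to study compression behaviour: long shared runs broken
by isolated edits, which produce the long zero-run/one-run structure the
lossy scheme exploits.  It does not emulate large-scale rearrangements,
repeat families, GC skew or indel clustering of real genomes, so passing
tests demonstrate algorithmic correctness and the *direction* of the
compression effects, not genome-calibrated ratios.  Defaults: $\sigma=4$
(DNA-like), substitutions only; rates are chosen per experiment
($\rho = 0.001$ for the similar-pair regime, i.e. one edit per thousand
positions, the regime where thresholding at $\tau = 32$ leaves a handful of
sub-threshold windows between long anchored matches).

## Problem sizes and numerical choices

The test suite and the acceptance script regenerate everything they check:
random query/text pairs up to length 200 across alphabets
$\sigma \in \{2, 4, 20\}$ (a thousand pairs for the oracle-equivalence
property), block counts $t \in \{1,2,3,4,7,8\}$ for bit-identity, the full
window-DP grid $z, o \le 6$, $\tau \le 4$, floors $\{0, 1\}$ against
exhaustive enumeration, and a similar pair of length 10\,000 at
$\rho = 0.001$ with $\tau = 32$ for the compression-direction checks.
These sizes are the package's own choices: large enough that every code
path (marked-block correction, window fallbacks, boundary blocks) is
exercised, small enough that the whole suite re-runs in a couple of
minutes.  All integer arithmetic stays well inside R's 32-bit integers
except range sums, which are returned as doubles.  Degenerate inputs are
defined rather than special-cased where possible: empty windows cost zero,
a query symbol absent from the text simply drives the scan to the root,
and the sentinel (appended, strictly smallest) can never participate in a
match because it occurs exactly once.

## Known limitations

* The indexes are plain in-memory R vectors; no compressed or on-disk
  index representation is provided (the MSBV serialization covers the
  encoding itself).
* The window DP with negative values released has a state space
  proportional to window area and is intended for the window sizes that
  thresholding actually produces, not for arbitrary large windows.
* Parallelism is a decomposition contract, not a wall-clock speedup: the
  scheduler is sequential by design.
* Frequencies are reported for the exact matched string; if a downstream
  consumer expects locus (node) frequencies the two differ when a match
  ends mid-edge.
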