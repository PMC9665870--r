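# matchstat

Matching statistics for alignment-free sequence comparison: fast
construction, a 2-bits-per-character encoding, lossy thresholded
compression, and range analytics — in one R package.

## The problem

Given a query `S` and a text `T` (two genomes, proteomes, or any byte
strings), the matching statistics array `MS[0..|S|-1]` records at every
query position the length of the longest prefix of `S[i..]` occurring
*anywhere* in `T`.  Because matches may come from anywhere, the statistic is
robust to rearrangements and horizontal transfer, and it underlies
alignment-free whole-genome phylogenies, substitution-rate estimators and
local-similarity screens.  The practical obstacles are size and speed: a
plain integer array for a mammalian genome is tens of gigabytes, and the
classical construction is sequential.

`matchstat` implements the toolkit around the compact encoding
`ms`, a bitvector of exactly `2|S|` bits built by appending
`MS[i] - MS[i-1] + 1` zeros and a one per position (`MS[-1] = 1`), from
which any value is recovered as

```
MS[i] = select1(ms, i) - 2i
```

The package provides:

* **Two-phase construction** over the Burrows–Wheeler transform of `T` and
  of reversed `T` (`matchingStatistics()`, `computeRuns()`,
  `computeMS()`), with LCP-interval parent navigation instead of an
  explicit suffix-tree topology, plus a per-position match-frequency
  extension (`msWithFrequencies()`) and the PLCP analogue
  (`computePLCPBitvector()`).
* **Block-parallel construction** (`computeRunsParallel()`,
  `computeMSParallel()`) — a marked-block correction scheme that is
  bit-identical to the sequential scan for every block count.
* **Lossy thresholded compression** (`compressMS()`): values `>= tau` and
  their bit positions are preserved exactly; everything below the
  threshold is rewritten by an optimal window permutation (a dynamic
  program over run-pair DAGs; ND/D/DL cost variants, optional negative
  values, precomputed DAG with greedy fallback), measured by Elias-delta
  run-length size against sparse baselines.
* **Range analytics** (`rangeMax()`, `rangeSum()`, `reportGE()`,
  `msHistogram()`, `longestCover()`, `maxWindows()`) over a block index
  with a sparse-table RMQ, with word-scan and run-scan backends.
* **Workbench**: FASTA I/O via Biostrings, record concatenation with
  non-matching separators, a seeded mutated-pair generator
  (`synthPair()`), and a CLI (`inst/scripts/msquery`) with
  `compute/compress/query/synth/dump` subcommands.

## Worked example

```r
library(matchstat)

bv <- matchingStatistics("bba", "abab")
bv
#> MSBitvector: m = 3, 6 bits
#>  bits: 010011
decodeMS(bv)
#> [1] 1 2 1
```

`"b"` is the longest prefix of `"bba"` in `"abab"` (length 1), `"ba"` of
`"ba"` (length 2), `"a"` of `"a"` (length 1); the 6-bit vector `010011` is
their unary-difference code.

A genome-like experiment — a 10 kb pair at mutation rate 0.001,
thresholded at `tau = 32`:

```r
p  <- synthPair(10000, 0.001, sigma = 4, seed = 1)
bv <- matchingStatistics(p$S, p$T)
mean(decodeMS(bv))
#> [1] 785.262                # long matches: one edit per ~1000 positions

sp <- thresholdSpec(32)
cb <- compressMS(bv, sp, "ND")
verifyThresholded(bv, cb, sp)
#> [1] TRUE                   # anchors fixed, big values intact
c(plain = length(bv@bits), rle = rleSize(cb@bits))
#> plain   rle
#> 20000   401                # 2 bits/char down to ~0.04 bits/char

idx <- buildBlockIndex(bv, 1024)
rangeMax(idx, bv, 0, 4999)
#> [1] 3161                   # longest match starting in the first half
rangeSum(idx, bv, 0, 4999) / 5000
#> [1] 1133.671               # average match length in the range
```

The mean MS value of ~785 says that a typical position sits inside a long
exact match (edits are ~1000 apart); after thresholding, run-length coding
shrinks the 20,000-bit vector to 401 bits because only the few windows
around mutations carry sub-threshold structure.

## Layout

| Path | Contents |
| --- | --- |
| `R/text-index.R` | suffix array, BWT, backward step, parent intervals |
| `R/ms-encoding.R` | the 2m-bit container, select/rank, serialization |
| `R/ms-core.R` | two-phase scans, naive oracle, frequencies, PLCP |
| `R/parallel.R` | block plans, marked-block correction, concatenation fix |
| `R/lossy.R` | thresholding, window DP, g-map, DAG, RLE, baselines |
| `R/range-query.R` | block index, RMQ, reporting, scan backends |
| `R/workbench.R` | FASTA, separators, synthetic pairs |
| `vignettes/matching-statistics.Rmd` | the methods vignette |
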