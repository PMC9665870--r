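#' @import methods
NULL

#' Sequence over a dense integer alphabet
#'
#' A finite sequence over the integer alphabet \code{[1..sigma]}.  Character
#' inputs (DNA, protein, arbitrary byte strings) are remapped to dense codes
#' at ingestion and the map is kept for round-tripping; see
#' \code{\link{asSequence}}.
#'
#' @slot symbols integer vector of codes, each in \code{[1..sigma]}.
#' @slot sigma alphabet size.
#' @slot alphabet character vector of length \code{sigma} mapping code k to
#'   its original single-character symbol, or \code{character(0)} when the
#'   input was already numeric.
#' @exportClass Sequence
setClass("Sequence",
  representation(symbols = "integer", sigma = "integer",
                 alphabet = "character"),
  validity = function(object) {
    if (length(object@symbols) < 1L) return("sequence must be non-empty")
    if (length(object@sigma) != 1L || object@sigma < 1L)
      return("sigma must be a positive scalar")
    if (anyNA(object@symbols)) return("symbols contain NA")
    if (min(object@symbols) < 1L || max(object@symbols) > object@sigma)
      return("symbols must lie in [1..sigma]")
    if (length(object@alphabet) &&
        length(object@alphabet) != object@sigma)
      return("alphabet map must have length sigma")
    TRUE
  })

#' BWT index of a text
#'
#' Suffix array, Burrows-Wheeler transform, rank/occurrence tables and
#' LCP-interval support over a text plus an appended sentinel (code 0,
#' lexicographically smaller than every alphabet symbol).  Rows are 0-based
#' and run over \code{[0..n]} where \code{n} is the text length.  Supports
#' the backward step and the parent operation used by the two-phase matching
#' statistics algorithm.
#'
#' @slot text integer vector, the indexed text (without sentinel).
#' @slot n text length.
#' @slot sigma alphabet size.
#' @slot alphabet original symbol map (possibly empty), as in
#'   \code{\link{Sequence}}.
#' @slot sa integer vector of length n+1; \code{sa[r+1]} is the 0-based
#'   starting position of the r-th lexicographically smallest suffix of
#'   text+sentinel.
#' @slot bwt integer vector of length n+1 over \code{[0..sigma]}; 0 encodes
#'   the sentinel.
#' @slot cumCount cumulative counts: \code{cumCount[a+1]} is the number of symbols in
#'   text+sentinel strictly smaller than a, for a in \code{[0..sigma]}.
#' @slot occPos list of length sigma; element a holds the sorted 0-based
#'   positions of symbol a in the BWT (rank by \code{findInterval}).
#' @slot lcp integer vector of length n+2 with boundary sentinels:
#'   \code{lcp[r+1]} is the LCP of the suffixes at rows r-1 and r for r in
#'   \code{[1..n]}; entries for r = 0 and r = n+1 are -1.
#' @slot plcp integer vector of length n+1: LCP values in text order
#'   (position i vs the lexicographic predecessor of suffix i).
#' @slot psv,nsv integer vectors of length n+2 over the same boundary
#'   indexing as \code{lcp}: previous/next position with a strictly smaller
#'   LCP value (used for O(1) parent intervals).
#' @seealso \code{\link{buildIndex}}, \code{\link{backwardStep}},
#'   \code{\link{parentInterval}}
#' @exportClass TextIndex
setClass("TextIndex",
  representation(text = "integer", n = "integer", sigma = "integer",
                 alphabet = "character", sa = "integer", bwt = "integer",
                 cumCount = "integer", occPos = "list", lcp = "integer",
                 plcp = "integer", psv = "integer", nsv = "integer"),
  validity = function(object) {
    n <- object@n
    if (length(object@sa) != n + 1L) return("suffix array must have n+1 rows")
    if (!setequal(object@sa, 0:n)) return("suffix array is not a permutation of [0..n]")
    if (length(object@bwt) != n + 1L) return("bwt must have n+1 rows")
    if (is.unsorted(object@cumCount)) return("cumulative counts must be non-decreasing")
    if (length(object@lcp) != n + 2L) return("lcp must carry n+2 boundary entries")
    TRUE
  })

#' Compact 2m-bit encoding of a matching statistics array
#'
#' For a query of length m, the encoding appends, for each position i in
#' increasing order, \code{MS[i] - MS[i-1] + 1} zeros followed by a one
#' (with the convention \code{MS[-1] = 1}), then right-pads with zeros to
#' exactly 2m bits.  The number of zeros preceding the i-th one equals
#' \code{i + MS[i]}, so \code{MS[i] = selectOne(bv, i) - 2*i}.
#'
#' @slot bits integer 0/1 vector, normally of length 2m.
#' @slot m query length (= number of one-bits).
#' @slot onePos 0-based positions of the one-bits (select table).
#' @slot allowNegative when TRUE the container holds a thresholded
#'   permutation in which decoded values below the threshold may be
#'   negative, and the non-negativity invariant is not enforced.
#' @seealso \code{\link{encodeMS}}, \code{\link{decodeMS}},
#'   \code{\link{msAccess}}
#' @exportClass MSBitvector
setClass("MSBitvector",
  representation(bits = "integer", m = "integer", onePos = "integer",
                 allowNegative = "logical"),
  validity = function(object) {
    if (!all(object@bits %in% c(0L, 1L))) return("bits must be 0/1")
    if (sum(object@bits) != object@m) return("one-count must equal m")
    if (length(object@onePos) != object@m) return("select table out of sync")
    if (length(object@bits) < 2L * object@m)
      return("bit-length must be at least 2m")
    if (!object@allowNegative) {
      vals <- object@onePos - 2L * (seq_len(object@m) - 1L)
      if (object@m && min(vals) < 0L) return("negative decoded value")
    }
    TRUE
  })

#' Phase-1 runs bitvector
#'
#' Length-m bitvector linking the two scans of the matching statistics
#' algorithm: \code{runs[i] = 1} iff \code{MS[i] = MS[i-1] - 1}, for i in
#' \code{[1..m-1]}; position 0 is unused and fixed to 0.
#'
#' @slot bits integer 0/1 vector of length m.
#' @seealso \code{\link{computeRuns}}
#' @exportClass RunsBitvector
setClass("RunsBitvector",
  representation(bits = "integer"),
  validity = function(object) {
    if (!all(object@bits %in% c(0L, 1L))) return("bits must be 0/1")
    if (length(object@bits) >= 1L && object@bits[1L] != 0L)
      return("position 0 must be 0")
    TRUE
  })

#' Block decomposition of an ms bitvector for range queries
#'
#' Fixed-size blocks of B bits with, per block, the maximum decoded MS
#' value at a one-bit, the one-count, and the prefix sum of MS values up to
#' the block's last one-bit, plus a sparse-table RMQ over the block maxima.
#'
#' @slot B block size in bits (multiple of 8, at least 8).
#' @slot nBlocks number of blocks.
#' @slot blockMax integer vector: per-block maximum decoded value
#'   (\code{NA} for blocks containing no one-bit).
#' @slot blockOnes per-block one-counts.
#' @slot blockPrefix cumulative sum of decoded values up to and including
#'   each block's last one-bit.
#' @slot rmq sparse table (list) answering range-maximum queries over
#'   \code{blockMax}.
#' @seealso \code{\link{buildBlockIndex}}, \code{\link{rangeMax}}
#' @exportClass BlockIndex
setClass("BlockIndex",
  representation(B = "integer", nBlocks = "integer", blockMax = "integer",
                 blockOnes = "integer", blockPrefix = "numeric",
                 rmq = "list"),
  validity = function(object) {
    if (object@B < 8L || object@B %% 8L != 0L)
      return("B must be a multiple of 8 and at least 8")
    if (length(object@blockMax) != object@nBlocks) return("blockMax length mismatch")
    if (length(object@blockOnes) != object@nBlocks) return("blockOnes length mismatch")
    TRUE
  })

setMethod("show", "Sequence", function(object) {
  cat(sprintf("Sequence of length %d over alphabet [1..%d]%s\n",
              length(object@symbols), object@sigma,
              if (length(object@alphabet))
                paste0(" (", paste(object@alphabet, collapse = ""), ")")
              else ""))
})

setMethod("show", "TextIndex", function(object) {
  cat(sprintf("TextIndex: n = %d, sigma = %d (BWT + SA + LCP intervals)\n",
              object@n, object@sigma))
})

setMethod("show", "MSBitvector", function(object) {
  cat(sprintf("MSBitvector: m = %d, %d bits%s\n", object@m,
              length(object@bits),
              if (object@allowNegative) " (negative values allowed)" else ""))
  if (object@m <= 32L)
    cat(" bits:", paste(object@bits, collapse = ""), "\n")
})

setMethod("show", "RunsBitvector", function(object) {
  cat(sprintf("RunsBitvector of length %d (%d ones)\n",
              length(object@bits), sum(object@bits)))
})

setMethod("show", "BlockIndex", function(object) {
  cat(sprintf("BlockIndex: %d blocks of %d bits\n", object@nBlocks, object@B))
})
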