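## ---- sparse-table RMQ ----------------------------------------------------

## argmax sparse table over a numeric vector (NA = minus infinity);
## ties resolved toward the smaller index
.rmqBuild <- function(v) {
  v[is.na(v)] <- -Inf
  n <- length(v)
  K <- max(0L, .ilog2(max(n, 1L)))
  tab <- vector("list", K + 1L)
  tab[[1L]] <- seq_len(n)
  if (K >= 1L) for (k in seq_len(K)) {
    half <- 2L^(k - 1L)
    prev <- tab[[k]]
    nn <- n - 2L^k + 1L
    if (nn < 1L) { tab[[k + 1L]] <- integer(0); next }
    a <- prev[seq_len(nn)]
    b <- prev[seq_len(nn) + half]
    tab[[k + 1L]] <- ifelse(v[b] > v[a], b, a)
  }
  list(v = v, tab = tab, n = n)
}

## 1-based inclusive argmax query
.rmqQuery <- function(rmq, l, r) {
  if (l > r) return(NA_integer_)
  k <- .ilog2(r - l + 1L)
  a <- rmq$tab[[k + 1L]][l]
  b <- rmq$tab[[k + 1L]][r - 2L^k + 1L]
  if (rmq$v[b] > rmq$v[a]) b else a
}

## ---- block index ---------------------------------------------------------

#' Build a block index over an ms bitvector
#'
#' Divides the bitvector into blocks of \code{B} bits and extracts, per
#' block, the maximum decoded value at a one-bit, the one-count, and the
#' running prefix sum of decoded values, plus a range-maximum structure
#' over the block maxima.  Queries then touch only two boundary blocks and
#' the RMQ.
#'
#' @param bv an \code{\linkS4class{MSBitvector}}.
#' @param B block size in bits; a multiple of 8, at least 8 (default 1024).
#' @return a \code{\linkS4class{BlockIndex}}.
#' @export
buildBlockIndex <- function(bv, B = 1024L) {
  B <- as.integer(B)
  if (B < 8L || B %% 8L != 0L) stop("B must be a multiple of 8, >= 8")
  len <- length(bv@bits)
  nBlocks <- as.integer(max(1L, ceiling(len / B)))
  vals <- bv@onePos - 2L * (0:(bv@m - 1L))
  blk <- bv@onePos %/% B + 1L            # 1-based block of each one
  blockMax <- rep(NA_integer_, nBlocks)
  blockOnes <- integer(nBlocks)
  agg <- tapply(vals, blk, max)
  blockMax[as.integer(names(agg))] <- as.integer(agg)
  cnt <- tapply(vals, blk, length)
  blockOnes[as.integer(names(cnt))] <- as.integer(cnt)
  sums <- rep(0, nBlocks)
  sagg <- tapply(vals, blk, sum)
  sums[as.integer(names(sagg))] <- as.numeric(sagg)
  new("BlockIndex", B = B, nBlocks = nBlocks, blockMax = blockMax,
      blockOnes = blockOnes, blockPrefix = cumsum(sums),
      rmq = .rmqBuild(as.numeric(blockMax)))
}

## decoded values of ones with indices r (0-based)
.valsAt <- function(bv, r) bv@onePos[r + 1L] - 2L * as.integer(r)

## 0-based index of the last one-bit inside blocks 1..b (0 if none)
.onesUpTo <- function(bv, idx, b) findInterval(b * idx@B - 1L, bv@onePos)

.checkRange <- function(bv, i, j) {
  if (i < 0L || j >= bv@m || i > j) stop("range out of bounds")
}

#' Range-maximum query
#'
#' \code{max(MS[i..j])} over query positions (0-based, inclusive), using
#' the block decomposition: a linear scan of the two boundary blocks plus
#' one RMQ over the interior blocks.
#'
#' @param idx a \code{\linkS4class{BlockIndex}} built on \code{bv}.
#' @param bv the \code{\linkS4class{MSBitvector}}.
#' @param i,j 0-based query positions, \code{0 <= i <= j < m}.
#' @return the maximum decoded value in the range.
#' @export
rangeMax <- function(idx, bv, i, j) {
  i <- as.integer(i); j <- as.integer(j)
  .checkRange(bv, i, j)
  bi <- bv@onePos[i + 1L] %/% idx@B + 1L
  bj <- bv@onePos[j + 1L] %/% idx@B + 1L
  if (bj - bi <= 1L)
    return(max(.valsAt(bv, i:j)))
  endBi <- .onesUpTo(bv, idx, bi) - 1L   # last one (0-based) in block bi
  startBj <- .onesUpTo(bv, idx, bj - 1L) # first one (0-based) in block bj
  best <- max(.valsAt(bv, i:endBi), .valsAt(bv, startBj:j))
  mid <- .rmqQuery(idx@rmq, bi + 1L, bj - 1L)
  if (!is.na(mid) && is.finite(idx@rmq$v[mid]))
    best <- max(best, idx@blockMax[mid])
  best
}

#' Range-sum query
#'
#' \code{sum(MS[i..j])} via per-block prefix sums and scans of the two
#' boundary blocks; \code{rangeSum(idx, bv, i, j) / (j - i + 1)} is the
#' local average match length over the range.
#'
#' @inheritParams rangeMax
#' @return the sum of decoded values in the range.
#' @export
rangeSum <- function(idx, bv, i, j) {
  i <- as.integer(i); j <- as.integer(j)
  .checkRange(bv, i, j)
  bi <- bv@onePos[i + 1L] %/% idx@B + 1L
  bj <- bv@onePos[j + 1L] %/% idx@B + 1L
  if (bj - bi <= 1L)
    return(as.numeric(sum(.valsAt(bv, i:j))))
  endBi <- .onesUpTo(bv, idx, bi) - 1L
  startBj <- .onesUpTo(bv, idx, bj - 1L)
  sum(.valsAt(bv, i:endBi)) + sum(.valsAt(bv, startBj:j)) +
    (idx@blockPrefix[bj - 1L] - idx@blockPrefix[bi])
}

#' Report positions with value at least tau
#'
#' All positions k in \code{[i..j]} with \code{MS[k] >= tau}, ascending,
#' found by recursive descent on the RMQ over block maxima so that only
#' blocks containing qualifying values (plus the two boundary blocks) are
#' scanned.
#'
#' @inheritParams rangeMax
#' @param tau threshold.
#' @return 0-based positions (possibly empty).
#' @export
reportGE <- function(idx, bv, i, j, tau) {
  i <- as.integer(i); j <- as.integer(j)
  .checkRange(bv, i, j)
  bi <- bv@onePos[i + 1L] %/% idx@B + 1L
  bj <- bv@onePos[j + 1L] %/% idx@B + 1L
  scanOnes <- function(r0, r1) {
    r <- r0:r1
    r[.valsAt(bv, r) >= tau]
  }
  if (bj - bi <= 1L) return(scanOnes(i, j))
  endBi <- .onesUpTo(bv, idx, bi) - 1L
  startBj <- .onesUpTo(bv, idx, bj - 1L)
  out <- list(scanOnes(i, endBi))
  descend <- function(lo, hi) {
    if (lo > hi) return(NULL)
    q <- .rmqQuery(idx@rmq, lo, hi)
    if (is.na(q) || !is.finite(idx@rmq$v[q]) || idx@blockMax[q] < tau)
      return(NULL)
    first <- .onesUpTo(bv, idx, q - 1L)          # 0-based first one in block q
    last <- .onesUpTo(bv, idx, q) - 1L
    c(descend(lo, q - 1L), list(scanOnes(first, last)), descend(q + 1L, hi))
  }
  out <- c(out, descend(bi + 1L, bj - 1L), list(scanOnes(startBj, j)))
  sort(unlist(out))
}

#' Analytics primitives over a range
#'
#' \code{msHistogram}: exact counts of each decoded value in the range.
#' \code{longestCover}: the position k of a longest interval
#' \code{[k..k+MS[k]-1]} containing \code{[i..j]} (ties: smallest k; error
#' if no interval covers the range).  \code{maxWindows}: all start
#' positions of length-\code{k} windows inside \code{[i..j]} attaining the
#' maximum window sum.
#'
#' @param bv an \code{\linkS4class{MSBitvector}}.
#' @param i,j 0-based range over query positions.
#' @return \code{msHistogram}: named integer vector (value -> count).
#' @export
msHistogram <- function(bv, i, j) {
  .checkRange(bv, as.integer(i), as.integer(j))
  tab <- table(.valsAt(bv, i:j))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' @rdname msHistogram
#' @export
longestCover <- function(bv, i, j) {
  i <- as.integer(i); j <- as.integer(j)
  .checkRange(bv, i, j)
  ks <- 0:i
  vals <- .valsAt(bv, ks)
  ok <- ks + vals - 1L >= j
  if (!any(ok)) stop("no matching interval covers the range")
  cand <- ks[ok]
  cand[which.max(vals[ok])]              # which.max takes the smallest tie
}

#' @rdname msHistogram
#' @param k window length.
#' @export
maxWindows <- function(bv, i, j, k) {
  i <- as.integer(i); j <- as.integer(j); k <- as.integer(k)
  .checkRange(bv, i, j)
  if (k < 1L || k > j - i + 1L) stop("window length out of range")
  vals <- .valsAt(bv, i:j)
  cs <- cumsum(c(0, vals))
  sums <- cs[(k + 1L):length(cs)] - cs[seq_len(length(cs) - k)]
  i + which(sums == max(sums)) - 1L
}

## ---- scan backends -------------------------------------------------------

## positions of one-bits inside each byte value, least-significant first
.byteOnes <- local({
  tab <- lapply(0:255, function(b) which(bitwAnd(b, 2L^(0:7)) != 0L) - 1L)
  tab
})

#' Decode the value stream of an ms bitvector by chunked scanning
#'
#' Streams the decoded value of every one-bit, left to right, with one of
#' two backends: \code{word} packs the bits and looks every byte up in a
#' precomputed table of one-bit offsets; \code{run} consumes a run-length
#' container one run at a time (fastest on highly repetitive bitvectors).
#' Both backends return identical streams.
#'
#' @param bits integer 0/1 vector, or (for the run backend) a container
#'   from \code{\link{rleEncode}}.
#' @param backend \code{"word"} or \code{"run"}.
#' @return integer vector: decoded value at each one-bit in order.
#' @export
scanChunk <- function(bits, backend = c("word", "run")) {
  backend <- match.arg(backend)
  if (backend == "word") {
    bits <- as.integer(bits)
    pad <- (8L - length(bits) %% 8L) %% 8L
    bytes <- as.integer(packBits(as.logical(c(bits, rep(0L, pad))),
                                 type = "raw"))
    offs <- .byteOnes[bytes + 1L]
    counts <- lengths(offs)
    basePos <- rep(8L * (seq_along(bytes) - 1L), counts)
    pos <- unlist(offs, use.names = FALSE) + basePos
  } else {
    enc <- if (is.list(bits)) bits else rleEncode(bits)
    vals <- rep_len(c(enc$first, 1L - enc$first), length(enc$lengths))
    ends <- cumsum(enc$lengths)
    startsR <- ends - enc$lengths        # 0-based run starts
    oneRuns <- which(vals == 1L)
    pos <- unlist(lapply(oneRuns, function(r)
      startsR[r] + seq_len(enc$lengths[r]) - 1L), use.names = FALSE)
  }
  if (is.null(pos) || !length(pos)) return(integer(0))
  as.integer(pos) - 2L * (seq_along(pos) - 1L)
}
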