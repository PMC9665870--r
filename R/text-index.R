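## Suffix array over t (integer codes >= 1) + implicit sentinel 0, by
## prefix doubling: each round radix-sorts (via order) on the pair of ranks
## at distance k.  Returns 0-based suffix start positions, length n+1.
.suffixArray <- function(t) {
  tx <- c(as.integer(t), 0L)
  n <- length(tx)
  rk <- tx
  k <- 1L
  repeat {
    second <- c(rk[-seq_len(k)], rep(-1L, min(k, n)))
    o <- order(rk, second, method = "radix")
    r1 <- rk[o]; r2 <- second[o]
    newr <- cumsum(c(1L, as.integer(r1[-1L] != r1[-n] | r2[-1L] != r2[-n])))
    rk[o] <- newr
    if (newr[n] == n) return(o - 1L)
    k <- 2L * k
  }
}

## Kasai: PLCP (lcp of suffix i with its lexicographic predecessor, in text
## order) from the suffix array, O(n) amortized.
.kasaiPLCP <- function(tx, sa) {
  n <- length(tx)                      # tx includes sentinel
  rank <- integer(n); rank[sa + 1L] <- 0:(n - 1L)
  phi <- integer(n)                    # predecessor suffix of i, by text pos
  prev <- sa[-n]; cur <- sa[-1L]
  phi[cur + 1L] <- prev
  plcp <- integer(n)
  h <- 0L
  for (i in 0:(n - 1L)) {
    if (rank[i + 1L] > 0L) {
      j <- phi[i + 1L]
      while (i + h < n - 1L && j + h < n - 1L &&
             tx[i + h + 1L] == tx[j + h + 1L]) h <- h + 1L
      plcp[i + 1L] <- h
      if (h > 0L) h <- h - 1L
    } else {
      plcp[i + 1L] <- 0L
      h <- 0L
    }
  }
  plcp
}

## Previous/next strictly-smaller-value positions over the boundary-extended
## lcp array (stack based, O(n)).
.psvNsv <- function(lcpx) {
  n <- length(lcpx)
  psv <- integer(n); nsv <- integer(n)
  stack <- integer(n); top <- 0L
  for (i in seq_len(n)) {
    while (top > 0L && lcpx[stack[top]] >= lcpx[i]) top <- top - 1L
    psv[i] <- if (top > 0L) stack[top] - 1L else -1L   # 0-based, -1 = none
    top <- top + 1L; stack[top] <- i
  }
  top <- 0L
  for (i in rev(seq_len(n))) {
    while (top > 0L && lcpx[stack[top]] >= lcpx[i]) top <- top - 1L
    nsv[i] <- if (top > 0L) stack[top] - 1L else n     # 0-based, n = none
    top <- top + 1L; stack[top] <- i
  }
  list(psv = psv, nsv = nsv)
}

#' Build a BWT index over a text
#'
#' Indexes \code{text} plus an appended sentinel (smaller than every
#' symbol), producing the suffix array, the Burrows-Wheeler transform with
#' rank support, cumulative symbol counts, and the LCP array with
#' previous/next-smaller-value tables for constant-time parent intervals.
#'
#' @param text a \code{\linkS4class{Sequence}}, character string, or integer
#'   vector of symbols in \code{[1..sigma]}.
#' @return a \code{\linkS4class{TextIndex}}.
#' @examples
#' idx <- buildIndex("abab")
#' idx@sa    # 4 2 0 3 1
#' @export
buildIndex <- function(text) {
  s <- asSequence(text)
  t <- s@symbols
  n <- length(t)
  tx <- c(t, 0L)
  sa <- .suffixArray(t)
  ## bwt[r] = symbol preceding suffix sa[r]; sentinel (0) when sa[r] = 0
  bwt <- integer(n + 1L)
  nz <- sa > 0L
  bwt[nz] <- tx[sa[nz]]
  counts <- tabulate(tx + 1L, nbins = s@sigma + 1L)
  C <- c(0L, cumsum(counts))[seq_len(s@sigma + 1L)]
  occPos <- lapply(seq_len(s@sigma), function(a) which(bwt == a) - 1L)
  plcp <- .kasaiPLCP(tx, sa)
  lcpSA <- plcp[sa + 1L]               # lcp[r] for rows r = 0..n (row0 = 0)
  lcpx <- c(-1L, lcpSA[-1L], -1L)      # boundaries r = 0 and r = n+1
  pn <- .psvNsv(lcpx)
  new("TextIndex", text = t, n = n, sigma = s@sigma, alphabet = s@alphabet,
      sa = sa, bwt = bwt, cumCount = C, occPos = occPos, lcp = lcpx,
      plcp = plcp, psv = pn$psv, nsv = pn$nsv)
}

#' Lexicographic intervals
#'
#' A lexicographic interval is a closed, 0-based row range \code{[lo..hi]}
#' of the suffix array of text+sentinel; the empty interval has
#' \code{lo > hi}.
#'
#' @param idx a \code{\linkS4class{TextIndex}}.
#' @return \code{rootInterval}: the full interval \code{[0..n]};
#'   \code{emptyInterval}: the canonical empty interval.
#' @export
rootInterval <- function(idx) c(0L, idx@n)

#' @rdname rootInterval
#' @export
emptyInterval <- function() c(0L, -1L)

#' @rdname rootInterval
#' @param iv an interval.
#' @export
isEmptyInterval <- function(iv) iv[1L] > iv[2L]

#' @rdname rootInterval
#' @export
isRootInterval <- function(idx, iv) iv[1L] == 0L && iv[2L] == idx@n

#' @rdname rootInterval
#' @export
intervalWidth <- function(iv) max(0L, iv[2L] - iv[1L] + 1L)

## rank(bwt, a, i): occurrences of a in bwt[0..i], 0-based inclusive.
.bwtRank <- function(idx, a, i) {
  if (a > length(idx@occPos)) return(0L)
  findInterval(i, idx@occPos[[a]])
}

#' Backward step
#'
#' Maps the interval of a string W to the interval of aW:
#' \code{[C[a] + rank(bwt, a, lo-1) .. C[a] + rank(bwt, a, hi) - 1]};
#' empty when aW does not occur in the text.
#'
#' @param idx a \code{\linkS4class{TextIndex}}.
#' @param iv non-empty interval within \code{[0..n]}.
#' @param a symbol code (symbols absent from the text yield the empty
#'   interval).
#' @return the interval of aW (possibly empty).
#' @examples
#' idx <- buildIndex("abab")
#' backwardStep(idx, rootInterval(idx), 1L)  # interval of "a": [1..2]
#' @export
backwardStep <- function(idx, iv, a) {
  stopifnot(!isEmptyInterval(iv), iv[1L] >= 0L, iv[2L] <= idx@n)
  if (a < 1L || a > idx@sigma) return(emptyInterval())
  pos <- idx@occPos[[a]]
  lo <- idx@cumCount[a + 1L] + findInterval(iv[1L] - 1L, pos)
  hi <- idx@cumCount[a + 1L] + findInterval(iv[2L], pos) - 1L
  if (lo > hi) emptyInterval() else c(lo, hi)
}

#' Parent interval
#'
#' The smallest lcp-interval strictly containing \code{iv}: the interval of
#' the longest proper prefix of \code{iv}'s string that is a suffix-tree
#' node.  Replaces the balanced-parentheses suffix-tree topology at an
#' identical contract for the operations the two-phase algorithm uses.
#'
#' @param idx a \code{\linkS4class{TextIndex}}.
#' @param iv non-empty, non-root interval reached by backward search.
#' @return the parent interval, with attribute \code{"depth"} holding the
#'   string depth (label length) of the parent node.
#' @examples
#' idx <- buildIndex("abab")
#' aba <- backwardStep(idx, backwardStep(idx, backwardStep(idx,
#'   rootInterval(idx), 1L), 2L), 1L)   # built right to left: "aba"
#' parentInterval(idx, aba)             # interval of "ab": [1..2]
#' @export
parentInterval <- function(idx, iv) {
  if (isRootInterval(idx, iv))
    stop("parentInterval called on the root interval")
  lo <- iv[1L]; hi <- iv[2L]
  lcpx <- idx@lcp
  lLeft <- lcpx[lo + 1L]               # boundary below row lo
  lRight <- lcpx[hi + 2L]              # boundary above row hi
  l <- max(lLeft, lRight)
  newLo <- if (lLeft < l) lo else idx@psv[lo + 1L]
  newHi <- if (lRight < l) hi else idx@nsv[hi + 2L] - 1L
  out <- c(newLo, newHi)
  attr(out, "depth") <- l
  out
}

#' Interval of a pattern (by backward search from the root)
#'
#' Convenience wrapper used in examples and tests: runs backward steps over
#' the reversed pattern; the width of the result is the occurrence count of
#' the pattern in the text.
#'
#' @param idx a \code{\linkS4class{TextIndex}}.
#' @param pattern Sequence/character/integer pattern (codes must be on the
#'   text's alphabet).
#' @return the pattern's interval (possibly empty).
#' @export
patternInterval <- function(idx, pattern) {
  p <- if (is.character(pattern))
    asSequence(pattern, alphabet = idx@alphabet)@symbols
  else asSequence(pattern)@symbols
  iv <- rootInterval(idx)
  for (a in rev(p)) {
    iv <- backwardStep(idx, iv, a)
    if (isEmptyInterval(iv)) return(iv)
  }
  iv
}
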