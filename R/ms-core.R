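## Internal scans are written against hoisted index components (plain
## vectors/lists) so the per-position loops avoid repeated S4 slot access.

.idxEnv <- function(idx) {
  list(n = idx@n, sigma = idx@sigma, cumCount = idx@cumCount, occPos = idx@occPos,
       lcp = idx@lcp, psv = idx@psv, nsv = idx@nsv)
}

## backward step on hoisted components; returns c(lo, hi) (lo > hi = empty)
.bstep <- function(e, lo, hi, a) {
  if (a > e$sigma || a < 1L) return(c(0L, -1L))
  pos <- e$occPos[[a]]
  Ca <- e$cumCount[a + 1L]
  c(Ca + findInterval(lo - 1L, pos), Ca + findInterval(hi, pos) - 1L)
}

## parent interval on hoisted components; returns c(lo, hi, depth)
.parent <- function(e, lo, hi) {
  lLeft <- e$lcp[lo + 1L]
  lRight <- e$lcp[hi + 2L]
  if (lLeft >= lRight) {
    l <- lLeft
    newLo <- e$psv[lo + 1L]
    newHi <- if (lRight < l) hi else e$nsv[hi + 2L] - 1L
  } else {
    l <- lRight
    newLo <- lo
    newHi <- e$nsv[hi + 2L] - 1L
  }
  c(newLo, newHi, l)
}

## Phase-1 scan over 1-based query positions [pLo..pHi]: fresh start at the
## right end, writes runs bits r[pHi..max(pLo,2)] into `runs` (passed by
## value, returned).  Returns also the final state = the match interval for
## position pLo-1, and the rightmost zero written (NA if none).
## When `state` is supplied (correction tasks) the fresh start is skipped.
.phase1Scan <- function(s, e, runs, pLo, pHi, state = NULL) {
  root <- c(0L, e$n)
  if (is.null(state)) {
    iv <- root
    a <- s[pHi]
    iv2 <- .bstep(e, iv[1L], iv[2L], a)
    if (iv2[1L] <= iv2[2L]) iv <- iv2
    p0 <- pHi
  } else {
    iv <- state                         # the match interval for pHi itself
    p0 <- pHi
  }
  lastZero <- NA_integer_
  p <- p0
  while (p >= max(pLo, 2L)) {
    ## have match interval for position p; trial with s[p-1] decides r[p]
    a <- s[p - 1L]
    iv2 <- .bstep(e, iv[1L], iv[2L], a)
    if (iv2[1L] <= iv2[2L]) {
      runs[p] <- 1L
      iv <- iv2
    } else {
      runs[p] <- 0L
      if (is.na(lastZero) || p > lastZero) lastZero <- p
      repeat {
        if (iv[1L] == 0L && iv[2L] == e$n) break   # root: match for p-1 empty
        pv <- .parent(e, iv[1L], iv[2L])
        iv <- pv[1:2]
        iv2 <- .bstep(e, iv[1L], iv[2L], a)
        if (iv2[1L] <= iv2[2L]) { iv <- iv2; break }
      }
    }
    p <- p - 1L
  }
  list(runs = runs, state = iv, lastZero = lastZero)
}

#' Phase 1: compute the runs bitvector
#'
#' Scans the query right to left over the text's BWT index, maintaining the
#' interval of the current match and trying one backward step per position;
#' on failure it climbs parent intervals until the step succeeds or the
#' root is reached.  Bit i is 1 iff the first trial succeeded, i.e. iff
#' \code{MS[i] = MS[i-1] - 1}.
#'
#' @param S query (Sequence, character, or integer codes on the text's
#'   alphabet); symbols absent from the text are legal and match nothing.
#' @param idxT \code{\link{buildIndex}} of the text.
#' @return a \code{\linkS4class{RunsBitvector}} of length \code{|S|}.
#' @examples
#' idx <- buildIndex("abab")
#' computeRuns(asSequence("bba", alphabet = idx@alphabet), idx)@bits
#' @export
computeRuns <- function(S, idxT) {
  s <- .harmonizeQuery(S, idxT)
  m <- length(s)
  e <- .idxEnv(idxT)
  res <- .phase1Scan(s, e, integer(m), 1L, m)
  new("RunsBitvector", bits = res$runs)
}

## Phase-2 scan: emits the ms encoding for 1-based positions [kStart..kEnd]
## with a fresh start (MS[kStart-1] taken as 1).  Reads s and runs freely to
## the right.  Returns unpadded bits; optionally per-position frequencies.
.phase2Scan <- function(s, e, runsBits, kStart, kEnd, withFreq = FALSE) {
  m <- length(s)
  root <- c(0L, e$n)
  iv <- root
  k <- kStart; ext <- kStart; prev <- 1L
  chunks <- vector("list", 64L); nc <- 0L
  freq <- if (withFreq) integer(m) else NULL
  emitted <- 0L
  repeat {
    ## extend the current match s[k..ext-1] with further characters
    while (ext <= m) {
      iv2 <- .bstep(e, iv[1L], iv[2L], s[ext])
      if (iv2[1L] > iv2[2L]) break
      iv <- iv2
      ext <- ext + 1L
    }
    zeros <- (ext - k) - prev + 1L
    if (zeros < 0L) stop("inconsistent runs bitvector (negative zero-run)")
    nc <- nc + 1L
    if (nc > length(chunks)) chunks <- c(chunks, vector("list", length(chunks)))
    chunks[[nc]] <- c(rep(0L, zeros), 1L)
    ## next segment start: first zero in runs strictly right of k
    kp <- k + 1L
    while (kp <= m && runsBits[kp] == 1L) kp <- kp + 1L
    ones <- min(kp - 1L, kEnd) - k
    if (ones > 0L) {
      nc <- nc + 1L
      if (nc > length(chunks)) chunks <- c(chunks, vector("list", length(chunks)))
      chunks[[nc]] <- rep(1L, ones)
    }
    emitted <- emitted + 1L + max(0L, ones)
    if (emitted > kEnd - kStart + 1L)
      stop("inconsistent runs bitvector (too many one-bits)")
    done <- kp > kEnd
    if (done && !withFreq) break
    if (!done && ext > m)
      stop("inconsistent runs bitvector (scan ran past query end)")
    ## walk parent intervals until a backward step with s[ext] succeeds or
    ## the root is reached; for the frequency extension, record the depth
    ## bracket (lower, upper] and width of every chain interval visited
    synced <- FALSE
    uppers <- integer(0); lowers <- integer(0); widths <- integer(0)
    u <- ext - k; w <- iv[2L] - iv[1L] + 1L
    tryExtend <- !done && ext <= m
    repeat {
      if (iv[1L] == 0L && iv[2L] == e$n) break
      pv <- .parent(e, iv[1L], iv[2L])
      uppers <- c(uppers, u); lowers <- c(lowers, pv[3L]); widths <- c(widths, w)
      if (tryExtend) {
        iv2 <- .bstep(e, pv[1L], pv[2L], s[ext])
        if (iv2[1L] <= iv2[2L]) { iv <- iv2; synced <- TRUE; break }
      }
      iv <- pv[1:2]; u <- pv[3L]; w <- pv[2L] - pv[1L] + 1L
    }
    if (withFreq) {
      ## positions q in [k..kp-1] matched s[q..ext-1]; the occurrence count
      ## of a length-len match is the width of the chain interval whose
      ## depth bracket contains len (len = 0 keeps frequency 0)
      qs <- k:min(kp - 1L, kEnd)
      lens <- ext - qs
      keep <- lens >= 1L
      if (any(keep) && length(uppers)) {
        idxBr <- vapply(lens[keep], function(x)
          which(x <= uppers & x > lowers)[1L], integer(1))
        freq[qs[keep]] <- widths[idxBr]
      }
    }
    if (done) break
    prev <- ext - kp + 1L
    k <- kp
    ext <- ext + 1L
  }
  bits <- unlist(chunks[seq_len(nc)], use.names = FALSE)
  list(bits = if (is.null(bits)) integer(0) else bits, freq = freq)
}

#' Phase 2: build the ms bitvector
#'
#' Scans the query left to right over the index of the \emph{reversed}
#' text, extending the current match with backward steps until failure;
#' each failure finalizes one zero-run (its length given by the jump in MS)
#' and the runs bitvector supplies the length of the following one-run.
#'
#' @param S query, as in \code{\link{computeRuns}}.
#' @param idxTrev \code{\link{buildIndex}} of the reversed text.
#' @param runs the \code{\linkS4class{RunsBitvector}} from phase 1 for the
#'   same query/text pair.
#' @return an \code{\linkS4class{MSBitvector}} (exactly 2|S| bits).
#' @export
computeMS <- function(S, idxTrev, runs) {
  s <- .harmonizeQuery(S, idxTrev)
  m <- length(s)
  if (length(runs@bits) != m) stop("runs length does not match query")
  e <- .idxEnv(idxTrev)
  res <- .phase2Scan(s, e, runs@bits, 1L, m)
  bits <- res$bits
  if (length(bits) > 2L * m) stop("inconsistent runs bitvector (overflow)")
  bits <- c(bits, rep(0L, 2L * m - length(bits)))
  .newMSBitvector(bits, m)
}

#' Matching statistics between a query and a text
#'
#' End-to-end wrapper: builds the index of the text and of the reversed
#' text, runs the two scan phases, and returns the 2|S|-bit encoding.
#' \code{MS[i]} is the length of the longest prefix of \code{S[i..]} that
#' occurs anywhere in \code{T}.
#'
#' @param S query.
#' @param T text (Sequence, character, or integer codes).
#' @param idxT,idxTrev optional prebuilt indexes of \code{T} and reversed
#'   \code{T} (must share the text's alphabet).
#' @return an \code{\linkS4class{MSBitvector}}.
#' @examples
#' decodeMS(matchingStatistics("bba", "abab"))   # 1 2 1
#' @export
matchingStatistics <- function(S, T, idxT = NULL, idxTrev = NULL) {
  Tseq <- asSequence(T)
  if (is.null(idxT)) idxT <- buildIndex(Tseq)
  if (is.null(idxTrev)) idxTrev <- buildIndex(reverseSequence(Tseq))
  Sq <- if (is.character(S) && length(idxT@alphabet))
    asSequence(S, alphabet = idxT@alphabet) else asSequence(S)
  runs <- computeRuns(Sq, idxT)
  computeMS(Sq, idxTrev, runs)
}

#' Matching statistics with per-position match frequencies
#'
#' Extends phase 2 to also report, for every position i, the number of
#' occurrences in the text of the exact matched string
#' \code{S[i..i+MS[i]-1]} (the width of its interval at the moment MS[i] is
#' finalized).  Positions with \code{MS[i] = 0} report frequency 0 by
#' convention.
#'
#' @inheritParams matchingStatistics
#' @return list with elements \code{ms} (an
#'   \code{\linkS4class{MSBitvector}}) and \code{freq} (integer vector).
#' @export
msWithFrequencies <- function(S, T, idxT = NULL, idxTrev = NULL) {
  Tseq <- asSequence(T)
  if (is.null(idxT)) idxT <- buildIndex(Tseq)
  if (is.null(idxTrev)) idxTrev <- buildIndex(reverseSequence(Tseq))
  Sq <- if (is.character(S) && length(idxT@alphabet))
    asSequence(S, alphabet = idxT@alphabet) else asSequence(S)
  runs <- computeRuns(Sq, idxT)
  s <- .harmonizeQuery(Sq, idxTrev)
  m <- length(s)
  e <- .idxEnv(idxTrev)
  res <- .phase2Scan(s, e, runs@bits, 1L, m, withFreq = TRUE)
  bits <- c(res$bits, rep(0L, 2L * m - length(res$bits)))
  list(ms = .newMSBitvector(bits, m), freq = res$freq)
}

#' Naive matching statistics (reference implementation)
#'
#' Direct-search definition of MS: for each i, the longest prefix of
#' \code{S[i..]} found by substring search in \code{T} (binary search on
#' the length, which is valid because occurrence is prefix-closed).
#' Quadratic-ish and index-free; serves as the package's internal oracle.
#'
#' @inheritParams matchingStatistics
#' @return integer vector of MS values.
#' @export
naiveMS <- function(S, T) {
  Tseq <- asSequence(T)
  Sq <- if (is.character(S) && length(Tseq@alphabet))
    asSequence(S, alphabet = Tseq@alphabet) else asSequence(S)
  s <- Sq@symbols; t <- Tseq@symbols
  if (max(s, t) <= 255L) {
    sChr <- rawToChar(as.raw(s)); tChr <- rawToChar(as.raw(t))
    m <- length(s)
    vapply(seq_len(m), function(i) {
      lo <- 0L; hi <- min(m - i + 1L, length(t))
      while (lo < hi) {
        mid <- as.integer((lo + hi + 1L) %/% 2L)
        pat <- substr(sChr, i, i + mid - 1L)
        if (grepl(pat, tChr, fixed = TRUE, useBytes = TRUE)) lo <- mid
        else hi <- mid - 1L
      }
      lo
    }, integer(1))
  } else {
    m <- length(s); n <- length(t)
    vapply(seq_len(m), function(i) {
      best <- 0L
      for (j in seq_len(n)) {
        l <- 0L
        while (i + l <= m && j + l <= n && s[i + l] == t[j + l]) l <- l + 1L
        if (l > best) best <- l
      }
      best
    }, integer(1))
  }
}

#' PLCP bitvector of a text
#'
#' The permuted LCP array holds, for every text position i, the length of
#' the longest common prefix of suffix i with its lexicographic predecessor
#' suffix.  Consecutive values obey \code{PLCP[i+1] >= PLCP[i] - 1}, so the
#' array admits the same 2n-bit unary-difference encoding as matching
#' statistics, and all downstream compression and range-query machinery
#' applies unchanged.
#'
#' @param T text.
#' @return an \code{\linkS4class{MSBitvector}} of 2|T| bits encoding PLCP.
#' @export
computePLCPBitvector <- function(T) {
  idx <- buildIndex(asSequence(T))
  encodeMS(idx@plcp[seq_len(idx@n)])
}
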