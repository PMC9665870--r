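#' Partition a query into blocks
#'
#' Splits \code{[0..m-1]} into \code{t} contiguous blocks whose sizes
#' differ by at most one (the remainder is spread over the first blocks).
#'
#' @param m query length.
#' @param t block count, \code{1 <= t <= m}.
#' @return integer vector of 0-based first positions of each block.
#' @examples
#' planBlocks(10L, 3L)   # 0 4 7
#' @export
planBlocks <- function(m, t) {
  m <- as.integer(m); t <- as.integer(t)
  if (t < 1L || t > m) stop("block count must be in [1..m]")
  sizes <- rep(m %/% t, t) + c(rep(1L, m %% t), rep(0L, t - m %% t))
  cumsum(c(0L, sizes[-t]))
}

#' Block-parallel runs computation
#'
#' The practical parallel scheme: each block is scanned right to left from
#' a fresh (root) state, so bits to the right of the block's first-from-
#' right zero are provisional ones; blocks containing a zero, plus the last
#' block, are \emph{marked} and store their end-of-scan interval.  A
#' correction pass then re-runs the scan leftward from each marked block's
#' stored state, rewriting the provisional ones through intervening
#' unmarked blocks and the trailing-ones suffix of the previous marked
#' block.  The result is bit-identical to \code{\link{computeRuns}}.
#' Tasks run on a deterministic sequential scheduler; the contract is the
#' decomposition, not the parallel substrate.
#'
#' @inheritParams computeRuns
#' @param t number of blocks (threads).
#' @param verbose report marked-block and corrected-bit counts.
#' @return a \code{\linkS4class{RunsBitvector}}.
#' @export
computeRunsParallel <- function(S, idxT, t, verbose = FALSE) {
  s <- .harmonizeQuery(S, idxT)
  m <- length(s)
  e <- .idxEnv(idxT)
  starts <- planBlocks(m, t) + 1L              # 1-based block starts
  ends <- c(starts[-1L] - 1L, m)
  runs <- integer(m)
  marked <- logical(t); states <- vector("list", t); lastZero <- rep(NA_integer_, t)
  ## phase A: independent fresh scans, one per block
  for (i in seq_len(t)) {
    res <- .phase1Scan(s, e, runs, starts[i], ends[i])
    runs[starts[i]:ends[i]] <- res$runs[starts[i]:ends[i]]
    states[[i]] <- res$state
    lastZero[i] <- res$lastZero
    marked[i] <- i == t || !is.na(res$lastZero)
  }
  ## phase B: one correction task per marked block, rewriting leftward to
  ## the rightmost correct zero of the previous marked block
  corrected <- 0L
  for (i in which(marked)) {
    if (i == 1L) next
    prevMarked <- which(marked[seq_len(i - 1L)] & !is.na(lastZero[seq_len(i - 1L)]))
    stopBit <- if (length(prevMarked)) lastZero[max(prevMarked)] else 1L
    hi <- starts[i] - 1L                       # bit set from the stored state
    if (hi < stopBit + 1L) next
    res <- .phase1Scan(s, e, runs, stopBit + 1L, hi, state = states[[i]])
    runs[(stopBit + 1L):hi] <- res$runs[(stopBit + 1L):hi]
    corrected <- corrected + (hi - stopBit)
  }
  if (verbose)
    message(sprintf("runs correction: %d marked blocks, %d bits rewritten",
                    sum(marked), corrected))
  new("RunsBitvector", bits = runs)
}

#' Block-parallel ms construction
#'
#' Each block's partial bitvector is built independently by a fresh
#' left-to-right scan starting at the block's first position (threads may
#' read the query and runs arbitrarily far right); the fresh start encodes
#' the block's first value as \code{MS[p_i]} zeros and a one.  A final
#' concatenation pass rewrites each block's leading zero-run to
#' \code{MS[p_i] - MS[p_i-1] + 1} zeros, chaining
#' \code{MS[p_i - 1] = |ms_{i-1}| - 2*|S_{i-1}| + 1} across blocks.  The
#' result is bit-identical to \code{\link{computeMS}}.
#'
#' @inheritParams computeMS
#' @param t number of blocks (threads).
#' @return an \code{\linkS4class{MSBitvector}}.
#' @export
computeMSParallel <- function(S, idxTrev, runs, t) {
  s <- .harmonizeQuery(S, idxTrev)
  m <- length(s)
  if (length(runs@bits) != m) stop("runs length does not match query")
  e <- .idxEnv(idxTrev)
  starts <- planBlocks(m, t) + 1L
  ends <- c(starts[-1L] - 1L, m)
  parts <- vector("list", t)
  for (i in seq_len(t))
    parts[[i]] <- .phase2Scan(s, e, runs@bits, starts[i], ends[i])$bits
  ## concatenation correction
  out <- parts[[1L]]
  if (t > 1L) {
    prevEnd <- length(parts[[1L]]) - 2L * (ends[1L] - starts[1L] + 1L) + 1L
    for (i in 2:t) {
      p <- parts[[i]]
      lead <- which(p == 1L)[1L] - 1L          # = MS[p_i]
      newLead <- lead - prevEnd + 1L
      if (newLead < 0L) stop("negative corrected zero-run; invalid inputs")
      rest <- if (lead > 0L) p[-seq_len(lead)] else p
      out <- c(out, rep(0L, newLead), rest)
      prevEnd <- length(p) - 2L * (ends[i] - starts[i] + 1L) + 1L
    }
  }
  if (length(out) > 2L * m) stop("parallel ms exceeds 2m bits")
  out <- c(out, rep(0L, 2L * m - length(out)))
  .newMSBitvector(out, m)
}
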