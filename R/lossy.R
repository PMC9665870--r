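## ---- integer codes -------------------------------------------------------

.ilog2 <- function(n) as.integer(floor(log2(n) + 1e-12))

#' Elias-delta code length
#'
#' Length in bits of the Elias-delta code of a positive integer:
#' \code{floor(log2 n) + 2*floor(log2(floor(log2 n) + 1)) + 1}.  This is the
#' default run-length encoder cost used throughout the lossy compression
#' scheme; any length function on positive integers can be substituted.
#'
#' @param n vector of positive integers.
#' @return integer vector of code lengths.
#' @examples
#' eliasDeltaLength(c(1, 2, 5, 1024))
#' @export
eliasDeltaLength <- function(n) {
  if (any(n < 1)) stop("delta code defined for n >= 1")
  fl <- .ilog2(n)
  fl + 2L * .ilog2(fl + 1L) + 1L
}

#' Threshold specification for lossy compression
#'
#' @param tau positive integer threshold: values \code{>= tau} are
#'   preserved exactly, values below it may be rewritten.
#' @param allowNegative permit rewritten values below zero (enables the
#'   trivial ones-then-zeros window scheme for the ND variant).
#' @param minValue integer floor for rewritten values (default 0; must be
#'   \code{< tau}).  Ignored when \code{allowNegative}.
#' @return a list of class \code{"ThresholdSpec"}.
#' @export
thresholdSpec <- function(tau, allowNegative = FALSE, minValue = 0L) {
  tau <- as.integer(tau); minValue <- as.integer(minValue)
  if (tau < 1L) stop("tau must be >= 1")
  if (minValue >= tau) stop("minValue must be < tau")
  structure(list(tau = tau, allowNegative = allowNegative,
                 minValue = minValue), class = "ThresholdSpec")
}

#' Anchors of a thresholded bitvector
#'
#' Positions \code{x} with \code{MS[x] >= tau} and the corresponding
#' one-bit positions \code{y = selectOne(bv, x)}.  These one-bits are fixed
#' (in position and rank) by every thresholded permutation.
#'
#' @param bv an \code{\linkS4class{MSBitvector}}.
#' @param tau threshold.
#' @return list with 0-based \code{x} (query positions) and \code{y} (bit
#'   positions), both increasing.
#' @export
findAnchors <- function(bv, tau) {
  vals <- bv@onePos - 2L * (0:(bv@m - 1L))
  x <- which(vals >= tau) - 1L
  list(x = x, y = bv@onePos[x + 1L])
}

## ---- g(y|x) remapping ----------------------------------------------------

#' Pairing map for correlated run lengths
#'
#' Maps the length y of a one-run, conditioned on the length x of the
#' preceding zero-run, to a small integer exploiting that long zero-runs
#' tend to be followed by one-runs of similar length: \code{y = x} maps to
#' 1, \code{y = x - d} to the even integer \code{2d}, \code{y = x + d}
#' (\code{d <= x - 2}) to the odd integer \code{2d + 1}, and every
#' remaining y (\code{y >= 2x - 1}) to itself.  Bijective for every fixed
#' x; \code{gUnmap} inverts exactly.
#'
#' @param y one-run length (positive).
#' @param x preceding zero-run length (positive).
#' @return the code (positive integer).
#' @examples
#' gMap(5, 5); gMap(4, 5); gMap(6, 5); gMap(9, 5)
#' @export
gMap <- function(y, x) {
  stopifnot(all(x >= 1L), all(y >= 1L))
  d <- y - x
  out <- ifelse(d == 0L, 1L,
         ifelse(d < 0L, 2L * (-d),
         ifelse(d <= x - 2L, 2L * d + 1L, y)))
  as.integer(out)
}

#' @rdname gMap
#' @param code a value produced by \code{gMap}.
#' @export
gUnmap <- function(code, x) {
  stopifnot(all(x >= 1L), all(code >= 1L))
  out <- ifelse(code >= 2L * x - 1L, code,
         ifelse(code == 1L, x,
         ifelse(code %% 2L == 0L, x - code %/% 2L, x + (code - 1L) %/% 2L)))
  as.integer(out)
}

## per-pair cost of a (dz zeros, do ones) pair under a variant
.pairCost <- function(dz, do, delta, variant, tau) {
  switch(variant,
    nd = (if (dz > 0L) delta(dz) else 0L) + delta(do),
    d  = delta(dz) + delta(gMap(do, dz)),
    dl = delta(dz) + (if (dz >= tau) delta(gMap(do, dz)) else delta(do)))
}

## ---- window dynamic program (Lemma-3 style) ------------------------------

## Interior DP over cumulative pairs (Z, O): f(Z,O) = min cost of a valid
## run-pair sequence placing Z zeros and O ones, with the value at every
## one-bit (base + Z' - O') inside [minValue .. tau-1].  Arcs between pairs
## additionally require the value at the first one of the new run to stay
## below tau, which reduces to O_prev >= base + Z_new - tau.  Returns cost,
## pair-count and backpointer matrices over [0..zCap] x [1..oCap].
## Ties: least cost, then fewest pairs, then smallest (Zprev, Oprev).
.interiorDP <- function(zCap, oCap, tau, delta, minValue, base,
                        variant = "nd", startZero = FALSE) {
  Fm <- matrix(Inf, zCap + 1L, oCap)      # rows Z = 0..zCap, cols O = 1..oCap
  Gm <- matrix(NA_integer_, zCap + 1L, oCap)
  BZ <- matrix(NA_integer_, zCap + 1L, oCap)
  BO <- matrix(NA_integer_, zCap + 1L, oCap)
  dcache <- c(0, vapply(seq_len(max(zCap, oCap, 1L)), delta, numeric(1)))
  for (O in seq_len(oCap)) {
    Zlo <- max(0L, O + minValue - base)
    Zhi <- min(zCap, O + tau - 1L - base)
    if (Zlo > Zhi) next
    for (Z in Zlo:Zhi) {
      best <- Inf; bestG <- NA_integer_; bz <- NA_integer_; bo <- NA_integer_
      ## source: single first pair (Z zeros, O ones)
      okSrc <- (base + Z - 1L <= tau - 1L) && (!startZero || Z >= 1L)
      if (okSrc) {
        best <- .pairCost(Z, O, delta, variant, tau)
        bestG <- 1L; bz <- -1L; bo <- -1L
      }
      ## interior predecessors
      OpLo <- max(1L, base + Z - tau)
      OpHi <- O - 1L
      if (OpLo <= OpHi) {
        for (Op in OpLo:OpHi) {
          ZpLo <- max(0L, Op + minValue - base)
          ZpHi <- min(Z - 1L, Op + tau - 1L - base)
          if (ZpLo > ZpHi) next
          fr <- Fm[(ZpLo:ZpHi) + 1L, Op]
          fin <- which(is.finite(fr))
          if (!length(fin)) next
          Zp <- (ZpLo:ZpHi)[fin]
          dz <- Z - Zp; do <- O - Op
          cost <- fr[fin] + switch(variant,
            nd = dcache[dz + 1L] + dcache[do + 1L],
            d  = dcache[dz + 1L] + vapply(gMap(rep(do, length(dz)), dz),
                                          delta, numeric(1)),
            dl = dcache[dz + 1L] + ifelse(dz >= tau,
                   vapply(gMap(rep(do, length(dz)), dz), delta, numeric(1)),
                   dcache[do + 1L]))
          pcnt <- Gm[Zp + 1L, Op] + 1L
          j <- order(cost, pcnt, Zp)[1L]  # ties: fewest pairs, smallest Zp
          curG <- if (is.na(bestG)) .Machine$integer.max else bestG
          if (cost[j] < best - 1e-9 ||
              (abs(cost[j] - best) < 1e-9 && pcnt[j] < curG)) {
            best <- cost[j]; bestG <- pcnt[j]
            bz <- Zp[j]; bo <- Op
          }
        }
      }
      if (is.finite(best)) {
        Fm[Z + 1L, O] <- best; Gm[Z + 1L, O] <- bestG
        BZ[Z + 1L, O] <- bz; BO[Z + 1L, O] <- bo
      }
    }
  }
  list(F = Fm, G = Gm, BZ = BZ, BO = BO, zCap = zCap, oCap = oCap,
       tau = tau, minValue = minValue, base = base, variant = variant,
       startZero = startZero, delta = delta)
}

## Recover the pair sequence ending at node (Z, O) from backpointers.
.tracePairs <- function(dp, Z, O) {
  pairs <- matrix(0L, 0L, 2L)
  while (Z >= 0L) {
    pz <- dp$BZ[Z + 1L, O]; po <- dp$BO[Z + 1L, O]
    if (pz < 0L) { pairs <- rbind(c(Z, O), pairs); break }
    pairs <- rbind(c(Z - pz, O - po), pairs)
    Z <- pz; O <- po
  }
  pairs
}

#' Optimal window permutation (dynamic program)
#'
#' Computes a rearrangement of a window of z zeros and o ones that
#' minimizes the total run-length code cost while keeping every
#' intermediate value (the decoded MS value at each one-bit, starting from
#' \code{base}) inside \code{[minValue .. tau-1]}.  With
#' \code{type = "anchor"} the window is the span between two consecutive
#' anchors: \code{o} counts the terminal anchor one, whose position is
#' fixed, and the window must end with at least one zero before it.  With
#' \code{type = "free"} (prefix/suffix windows) all o ones are permutable
#' and the window may end with ones or zeros.
#'
#' @param z number of zeros in the window.
#' @param o number of ones in the window (including the terminal anchor
#'   one when \code{type = "anchor"}).
#' @param tau threshold.
#' @param delta code-length function (default \code{\link{eliasDeltaLength}}).
#' @param minValue floor for intermediate values.
#' @param base value at the virtual one-bit preceding the window
#'   (\code{tau} after an anchor; 1 for a prefix window).
#' @param type window termination, see above.
#' @return a permutation plan: list with \code{pairs} (two-column matrix of
#'   zero-run/one-run lengths; the first zero-run may be empty),
#'   \code{trailing} (length of the final zero-run), \code{cost} (total
#'   code bits) and \code{feasible}.
#' @examples
#' optimalWindowPermutation(4, 4, 2)
#' @export
optimalWindowPermutation <- function(z, o, tau, delta = eliasDeltaLength,
                                     minValue = 0L, base = tau,
                                     type = c("anchor", "free")) {
  type <- match.arg(type)
  z <- as.integer(z); o <- as.integer(o)
  stopifnot(z >= 0L, o >= if (type == "anchor") 1L else 0L, tau >= 1L)
  oF <- if (type == "anchor") o - 1L else o       # permutable ones
  infeasible <- list(pairs = matrix(0L, 0L, 2L), trailing = 0L,
                     cost = Inf, feasible = FALSE)
  if (oF == 0L)
    return(list(pairs = matrix(0L, 0L, 2L), trailing = z,
                cost = if (z > 0L) delta(z) else 0, feasible = TRUE))
  if (z == 0L) {
    ## a terminated window must end with a zero before its anchor
    if (type == "anchor") return(infeasible)
    ## single run of ones; values descend from base - 1, so check bounds
    if (base - oF < minValue || base - 1L > tau - 1L) return(infeasible)
    return(list(pairs = matrix(c(0L, oF), 1L, 2L), trailing = 0L,
                cost = delta(oF), feasible = TRUE))
  }
  zCap <- if (type == "anchor") z - 1L else z
  dp <- .interiorDP(zCap, oF, tau, delta, minValue, base)
  fr <- dp$F[, oF]                                 # nodes (Z, O = oF)
  cand <- which(is.finite(fr)) - 1L                # Z values
  if (!length(cand)) return(infeasible)
  tot <- fr[cand + 1L] +
    ifelse(z - cand > 0L, vapply(pmax(z - cand, 1L), delta, numeric(1)), 0)
  best <- min(tot)
  sel <- cand[which(abs(tot - best) < 1e-9)]
  sel <- sel[order(dp$G[sel + 1L, oF], -sel)][1L]  # fewest pairs, longest tail
  list(pairs = .tracePairs(dp, sel, oF), trailing = z - sel,
       cost = best, feasible = TRUE)
}

#' Trivial window permutation with negative values
#'
#' Rewrites a window as all its ones followed by all its zeros
#' (\code{1^p 0^q}); only legal when negative rewritten values are
#' acceptable.
#'
#' @param pOnes,qZeros run lengths.
#' @return integer 0/1 vector.
#' @export
trivialNegativePermutation <- function(pOnes, qZeros) {
  c(rep(1L, pOnes), rep(0L, qZeros))
}

#' Materialize the bits of a permutation plan
#'
#' @param plan a plan from \code{\link{optimalWindowPermutation}}.
#' @return integer 0/1 vector of the window content.
#' @export
planToBits <- function(plan) {
  if (!plan$feasible) stop("infeasible plan")
  bits <- integer(0)
  if (nrow(plan$pairs))
    bits <- unlist(lapply(seq_len(nrow(plan$pairs)), function(i)
      c(rep(0L, plan$pairs[i, 1L]), rep(1L, plan$pairs[i, 2L]))))
  c(bits, rep(0L, plan$trailing))
}

## ---- precomputed all-queries DAG ----------------------------------------

#' Precomputed window-permutation DAG
#'
#' Builds the interior dynamic program once for every cumulative pair up to
#' the caps, so that any between-anchors window with at most \code{zMax}
#' zeros and \code{oMax} ones can be answered by a terminal minimization
#' plus backtracking.  Queries beyond the caps fall back to a greedy walk
#' (largest progress \code{g = z - Z + o - O}, or largest
#' \code{g / cost} with \code{strategy = 2}) until a precomputed node is
#' reached.
#'
#' @param zMax,oMax caps on window zeros/ones.
#' @param tau threshold.
#' @param delta code-length function.
#' @param minValue floor for rewritten values.
#' @return an opaque list consumed by \code{\link{queryDAG}}.
#' @export
buildWindowDAG <- function(zMax, oMax, tau, delta = eliasDeltaLength,
                           minValue = 0L) {
  .interiorDP(as.integer(zMax), as.integer(oMax), as.integer(tau), delta,
              as.integer(minValue), base = as.integer(tau))
}

#' @rdname buildWindowDAG
#' @param dag a DAG from \code{buildWindowDAG}.
#' @param z,o window query (o includes the terminal anchor one).
#' @param strategy greedy fallback: 1 maximizes the progress of each step,
#'   2 the progress per code bit.
#' @return a permutation plan as in \code{\link{optimalWindowPermutation}}.
#' @export
queryDAG <- function(dag, z, o, strategy = 1L) {
  z <- as.integer(z); o <- as.integer(o)
  tau <- dag$tau; minValue <- dag$minValue; base <- dag$base
  delta <- dag$delta
  oF <- o - 1L
  if (oF == 0L)
    return(list(pairs = matrix(0L, 0L, 2L), trailing = z,
                cost = if (z > 0L) delta(z) else 0, feasible = TRUE))
  infeasible <- list(pairs = matrix(0L, 0L, 2L), trailing = 0L,
                     cost = Inf, feasible = FALSE)
  tailPairs <- matrix(0L, 0L, 2L)
  trailing <- NA_integer_
  ## terminal step: pick the pair ending at the last permutable one
  ZiLo <- max(0L, oF + minValue - base)
  ZiHi <- min(z - 1L, oF + tau - 1L - base)
  if (ZiLo > ZiHi) return(infeasible)
  inDag <- function(Z, O) Z <= dag$zCap && O >= 1L && O <= dag$oCap &&
    is.finite(dag$F[Z + 1L, O])
  if (oF <= dag$oCap) {
    cand <- (ZiLo:ZiHi)[(ZiLo:ZiHi) <= dag$zCap]
    cand <- cand[is.finite(dag$F[cand + 1L, oF])]
    if (length(cand)) {
      tot <- dag$F[cand + 1L, oF] +
        ifelse(z - cand > 0L, vapply(pmax(z - cand, 1L), delta, numeric(1)), 0)
      sel <- cand[which.min(tot)]
      return(list(pairs = .tracePairs(dag, sel, oF), trailing = z - sel,
                  cost = min(tot), feasible = TRUE))
    }
  }
  ## greedy walk from (z, oF) down to a precomputed node
  Zc <- ZiLo                                  # strategy 1 on the terminal arc
  trailing <- z - Zc
  Oc <- oF
  cost <- if (trailing > 0L) delta(trailing) else 0
  repeat {
    if (inDag(Zc, Oc)) {
      return(list(pairs = rbind(.tracePairs(dag, Zc, Oc), tailPairs),
                  trailing = trailing, cost = NA_real_, feasible = TRUE))
    }
    ## in-neighbors (Zp, Op): Op in [max(1, Zc + base - tau) .. Oc-1],
    ## Zp in the validity band, Zp < Zc
    OpLo <- max(1L, base + Zc - tau)
    OpHi <- Oc - 1L
    if (OpLo > OpHi) {
      ## maybe (Zc, Oc) is itself a valid first pair
      okSrc <- base + Zc - 1L <= tau - 1L &&
        base + Zc - Oc >= minValue && base + Zc - Oc <= tau - 1L
      if (okSrc)
        return(list(pairs = rbind(c(Zc, Oc), tailPairs), trailing = trailing,
                    cost = NA_real_, feasible = TRUE))
      return(infeasible)
    }
    cands <- do.call(rbind, lapply(OpLo:OpHi, function(Op) {
      ZpLo <- max(0L, Op + minValue - base)
      ZpHi <- min(Zc - 1L, Op + tau - 1L - base)
      if (ZpLo > ZpHi) return(NULL)
      cbind(ZpLo:ZpHi, Op)
    }))
    if (is.null(cands)) return(infeasible)
    g <- (Zc - cands[, 1L]) + (Oc - cands[, 2L])
    score <- if (strategy == 1L) g else
      g / (vapply(pmax(Zc - cands[, 1L], 1L), delta, numeric(1)) +
           vapply(Oc - cands[, 2L], delta, numeric(1)))
    j <- order(-score, cands[, 1L], cands[, 2L])[1L]
    tailPairs <- rbind(c(Zc - cands[j, 1L], Oc - cands[j, 2L]), tailPairs)
    Zc <- cands[j, 1L]; Oc <- cands[j, 2L]
  }
}

## ---- full-bitvector compression ------------------------------------------

## split window content into leading ones, inner (first zero .. last one),
## trailing zeros
.splitBoundary <- function(bits) {
  ones <- which(bits == 1L)
  if (!length(ones))
    return(list(lead = 0L, inner = integer(0), tail = length(bits)))
  zeros <- which(bits == 0L)
  if (!length(zeros))
    return(list(lead = length(bits), inner = integer(0), tail = 0L))
  p <- zeros[1L]; q <- ones[length(ones)]
  if (p > q)                             # e.g. all ones before all zeros
    return(list(lead = p - 1L, inner = integer(0), tail = length(bits) - q))
  list(lead = p - 1L, inner = bits[p:q], tail = length(bits) - q)
}

## permute one window's content (without any fixed anchor bit) and return
## the new content bits, or NULL if the window is kept as identity
.permuteWindow <- function(content, base, tau, delta, variant, spec,
                           terminated) {
  identity <- list(bits = NULL, infeasible = FALSE)
  z <- sum(content == 0L); oF <- sum(content == 1L)
  if (z == 0L || oF == 0L) return(identity)
  if (variant == "ND") {
    if (spec$allowNegative)
      return(list(bits = trivialNegativePermutation(oF, z),
                  infeasible = FALSE))
    plan <- optimalWindowPermutation(z, oF + if (terminated) 1L else 0L,
                                     tau, delta, spec$minValue, base,
                                     type = if (terminated) "anchor" else "free")
    if (!plan$feasible) return(list(bits = NULL, infeasible = TRUE))
    return(list(bits = planToBits(plan), infeasible = FALSE))
  }
  ## D / DL: fix the boundary one-run and trailing zero-run, permute the
  ## inner [p..q] span (starts with a zero, ends with a one)
  sp <- .splitBoundary(content)
  if (!length(sp$inner)) return(identity)
  zi <- sum(sp$inner == 0L); oi <- sum(sp$inner == 1L)
  if (zi == 0L || oi == 0L) return(identity)
  baseI <- base - sp$lead
  minV <- if (spec$allowNegative) baseI - oi - zi - 1L else spec$minValue
  dp <- .interiorDP(zi, oi, tau, delta, minV, baseI,
                    variant = tolower(variant), startZero = TRUE)
  if (!is.finite(dp$F[zi + 1L, oi]))
    return(list(bits = NULL, infeasible = TRUE))
  pairs <- .tracePairs(dp, zi, oi)
  inner <- planToBits(list(pairs = pairs, trailing = 0L, feasible = TRUE))
  list(bits = c(rep(1L, sp$lead), inner, rep(0L, sp$tail)),
       infeasible = FALSE)
}

#' Lossy thresholded compression of an ms bitvector
#'
#' Rewrites the bitvector so that every value \code{>= tau} (and its
#' one-bit position and rank) is preserved exactly, while values below the
#' threshold are replaced by other values below it, chosen so that the
#' run-length code of the result is as small as possible.  The output is a
#' permutation of the input.  Variants: \code{ND} permutes each
#' between-anchors window freely (ones-then-zeros when negative values are
#' allowed); \code{D} fixes the boundary one-runs and codes each zero-run
#' x with its following one-run y as \code{delta(x) + delta(g(y|x))};
#' \code{DL} applies the paired code only when \code{x >= tau}.
#'
#' Windows with no feasible rewriting (possible when \code{minValue > 0})
#' are kept as identity and reported via a message.
#'
#' @param bv an \code{\linkS4class{MSBitvector}}.
#' @param spec a \code{\link{thresholdSpec}}.
#' @param variant \code{"ND"}, \code{"D"} or \code{"DL"}.
#' @param delta code-length function.
#' @return the permuted \code{\linkS4class{MSBitvector}} (with the
#'   negative-values flag set according to \code{spec}).
#' @examples
#' bv <- encodeMS(c(1L, 5L, 4L, 3L, 2L, 1L, 0L, 1L))
#' compressMS(bv, thresholdSpec(3L))
#' @export
compressMS <- function(bv, spec, variant = c("ND", "D", "DL"),
                       delta = eliasDeltaLength) {
  variant <- match.arg(variant)
  stopifnot(inherits(spec, "ThresholdSpec"))
  tau <- spec$tau
  vals <- bv@onePos - 2L * (0:(bv@m - 1L))
  anc <- findAnchors(bv, tau)
  bits <- bv@bits
  len <- length(bits)
  fallbacks <- 0L
  ## window spans: (start, end) of permutable content, plus base value and
  ## whether the window is terminated by a fixed anchor one
  spans <- list()
  if (length(anc$y) == 0L) {
    spans[[1L]] <- list(from = 1L, to = len, base = 1L, term = FALSE)
  } else {
    y <- anc$y
    if (y[1L] > 0L)
      spans[[length(spans) + 1L]] <-
        list(from = 1L, to = y[1L] + 1L, base = 1L, term = TRUE)
    if (length(y) > 1L)
      for (i in seq_len(length(y) - 1L))
        if (y[i + 1L] > y[i] + 1L)
          spans[[length(spans) + 1L]] <-
            list(from = y[i] + 2L, to = y[i + 1L] + 1L,
                 base = vals[anc$x[i] + 1L], term = TRUE)
    if (y[length(y)] + 2L <= len)
      spans[[length(spans) + 1L]] <-
        list(from = y[length(y)] + 2L, to = len,
             base = vals[anc$x[length(anc$x)] + 1L], term = FALSE)
  }
  for (w in spans) {
    if ((w$term && w$from > w$to - 1L) || w$from > w$to) next
    content <- if (w$term) bits[w$from:(w$to - 1L)] else bits[w$from:w$to]
    res <- .permuteWindow(content, w$base, tau, delta, variant, spec, w$term)
    if (res$infeasible) fallbacks <- fallbacks + 1L
    if (is.null(res$bits)) next
    if (w$term) bits[w$from:(w$to - 1L)] <- res$bits
    else bits[w$from:w$to] <- res$bits
  }
  if (fallbacks > 0L)
    message(sprintf("compressMS: %d window(s) kept as identity (infeasible)",
                    fallbacks))
  .newMSBitvector(bits, bv@m, allowNegative = spec$allowNegative)
}

#' Verify a thresholded permutation
#'
#' Checks that \code{permuted} is a valid thresholded rewriting of
#' \code{original}: equal length and one-count, every anchor one-bit at its
#' original position and rank, values \code{>= tau} preserved exactly, and
#' every other value below \code{tau} (and \code{>= max(0, minValue)}
#' unless negatives are allowed).
#'
#' @param original,permuted \code{\linkS4class{MSBitvector}}s.
#' @param spec a \code{\link{thresholdSpec}}.
#' @return TRUE/FALSE.
#' @export
verifyThresholded <- function(original, permuted, spec) {
  if (length(original@bits) != length(permuted@bits)) return(FALSE)
  if (original@m != permuted@m) return(FALSE)
  v0 <- original@onePos - 2L * (0:(original@m - 1L))
  v1 <- permuted@onePos - 2L * (0:(permuted@m - 1L))
  big <- v0 >= spec$tau
  if (!all(v1[big] == v0[big])) return(FALSE)
  if (!all(permuted@onePos[big] == original@onePos[big])) return(FALSE)
  if (any(v1[!big] >= spec$tau)) return(FALSE)
  if (!spec$allowNegative && any(v1[!big] < max(0L, spec$minValue)))
    return(FALSE)
  TRUE
}

## ---- run-length coding and sparse baselines ------------------------------

#' Run-length encode a bit sequence
#'
#' @param bits integer 0/1 vector.
#' @return list with \code{first} (value of the first run) and
#'   \code{lengths} (maximal run lengths).
#' @export
rleEncode <- function(bits) {
  r <- rle(as.integer(bits))
  list(first = r$values[1L], lengths = r$lengths)
}

#' @rdname rleEncode
#' @param enc a list from \code{rleEncode}.
#' @export
rleDecode <- function(enc) {
  vals <- rep_len(c(enc$first, 1L - enc$first), length(enc$lengths))
  inverse.rle(structure(list(lengths = enc$lengths, values = vals),
                        class = "rle"))
}

#' @rdname rleEncode
#' @param delta code-length function.
#' @return \code{rleSize}: total bits of delta-coding every maximal run
#'   length, plus one bit for the leading bit value.
#' @export
rleSize <- function(bits, delta = eliasDeltaLength) {
  sum(delta(rle(as.integer(bits))$lengths)) + 1L
}

## minimal bits to write a positive integer v (ceil(log2 v); 0 for v = 1),
## matching the fixed-width convention of the B scheme
.bitsFor <- function(v) ifelse(v <= 1L, 0L, as.integer(ceiling(log2(v))))

#' Sparse above-threshold baselines
#'
#' Alternatives to compressing the bitvector when few values reach the
#' threshold.  Scheme A stores every value \code{>= tau} and its position
#' in the minimal number of bits for each number; scheme B stores each
#' value in \code{ceil(log2 M)} bits (M = maximum observed value) and each
#' position in \code{ceil(log2 L)} bits (L = query length).
#'
#' @param bv an \code{\linkS4class{MSBitvector}}.
#' @param tau threshold.
#' @return total size in bits.
#' @export
sparseSizeA <- function(bv, tau) {
  vals <- decodeMS(bv)
  keep <- vals >= tau
  if (!any(keep)) return(0L)
  pos <- which(keep) - 1L
  sum(.bitsFor(vals[keep])) + sum(.bitsFor(pos + 1L))
}

#' @rdname sparseSizeA
#' @export
sparseSizeB <- function(bv, tau) {
  vals <- decodeMS(bv)
  keep <- vals >= tau
  if (!any(keep)) return(0L)
  M <- max(vals)
  L <- bv@m
  sum(keep) * (.bitsFor(M) + .bitsFor(L))
}

#' Compression report across variants
#'
#' Measures, for each requested variant, the run-length-coded size of the
#' thresholded permutation against the plain 2m-bit encoding and the
#' sparse baselines.
#'
#' @param bv an \code{\linkS4class{MSBitvector}}.
#' @param spec a \code{\link{thresholdSpec}}.
#' @param variants character vector among ND, D, DL.
#' @param delta code-length function.
#' @return data.frame with columns variant, tau, plain_bits, rle_bits,
#'   ratio, bpc (bits per query character), A_bits, B_bits.
#' @export
compressionReport <- function(bv, spec, variants = c("ND", "D", "DL"),
                              delta = eliasDeltaLength) {
  plain <- length(bv@bits)
  a <- sparseSizeA(bv, spec$tau); b <- sparseSizeB(bv, spec$tau)
  rows <- lapply(variants, function(v) {
    cb <- compressMS(bv, spec, v, delta)
    rb <- rleSize(cb@bits, delta)
    data.frame(variant = v, tau = spec$tau, plain_bits = plain,
               rle_bits = rb, ratio = rb / plain, bpc = rb / bv@m,
               A_bits = a, B_bits = b)
  })
  do.call(rbind, rows)
}
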