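# Independent oracles and generators shared across the suite.  Everything
# here avoids the package's BWT/DP code paths: suffix arrays by full string
# sorting, matching statistics by direct window comparison, window
# permutations by exhaustive enumeration.

pick <- function(v) v[sample.int(length(v), 1L)]

randSeq <- function(n, sigma) {
  asSequence(sample.int(sigma, n, replace = TRUE), sigma = sigma)
}

# random valid MS-like array: drops by exactly one or jumps to any value
# >= current - 1 (the slope invariant), ending naturally
randMSArray <- function(m, hi = 12L) {
  v <- integer(m)
  cur <- pick(0:3)
  for (i in seq_len(m)) {
    cur <- if (stats::runif(1) < 0.25) pick(max(0L, cur - 1L):hi)
           else max(0L, cur - 1L)
    v[i] <- cur
  }
  as.integer(v)
}

# naive suffix array of text+sentinel by sorting explicit suffix strings;
# sentinel encoded as byte 1, symbols shifted by +1 (all < 128 in tests)
naiveSuffixArray <- function(t) {
  tx <- c(as.integer(t) + 1L, 1L)
  suff <- vapply(seq_along(tx), function(i)
    rawToChar(as.raw(tx[i:length(tx)])), "")
  order(suff, method = "radix") - 1L
}

# naive matching statistics by direct per-position window comparison
bruteMS <- function(S, T) {
  s <- seqSymbols(S); t <- seqSymbols(T)
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

# occurrence count of a plain integer pattern in a text
naiveCount <- function(pat, t) {
  L <- length(pat); n <- length(t)
  if (L == 0L || L > n) return(0L)
  cnt <- 0L
  for (j in seq_len(n - L + 1L))
    if (all(t[j:(j + L - 1L)] == pat)) cnt <- cnt + 1L
  cnt
}

# decoded values (at one-bits) of a window played from a base value
windowValues <- function(bits, base) {
  v <- base
  out <- integer(0)
  for (b in bits) {
    if (b == 1L) { v <- v - 1L; out <- c(out, v) } else v <- v + 1L
  }
  out
}

# exhaustive minimum run-length-coded cost over all valid arrangements of
# z zeros and oF permutable ones; "anchor" windows must end with a zero
.enumCache <- new.env(parent = emptyenv())
enumWindowBest <- function(z, oF, tau, minValue, base, type,
                           delta = eliasDeltaLength) {
  if (oF == 0L) return(if (z > 0L) delta(z) else 0)
  slots <- z + oF
  key <- paste(slots, oF)
  combos <- get0(key, .enumCache)
  if (is.null(combos)) {
    combos <- utils::combn(slots, oF)
    assign(key, combos, .enumCache)
  }
  best <- Inf
  for (c in seq_len(ncol(combos))) {
    bits <- integer(slots); bits[combos[, c]] <- 1L
    if (type == "anchor" && bits[slots] != 0L) next
    v <- windowValues(bits, base)
    if (any(v < minValue | v > tau - 1L)) next
    cost <- sum(delta(rle(bits)$lengths))
    if (cost < best) best <- cost
  }
  best
}

expect_bits_equal <- function(a, b) expect_identical(as.integer(a),
                                                     as.integer(b))
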