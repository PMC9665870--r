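test_that("worked example: S = bba against T = abab", {
  expect_identical(naiveMS("bba", "abab"), c(1L, 2L, 1L))
  idx <- buildIndex("abab")
  runs <- computeRuns(asSequence("bba", alphabet = idx@alphabet), idx)
  expect_identical(runs@bits, c(0L, 0L, 1L))
  bv <- matchingStatistics("bba", "abab")
  expect_identical(paste(bv@bits, collapse = ""), "010011")
})

test_that("self-comparison gives the maximal staircase", {
  s <- asSequence("abracadabra")
  m <- seqLength(s)
  bv <- matchingStatistics(s, s)
  expect_identical(decodeMS(bv), m:1)
  expect_identical(bv@bits, c(rep(0L, m), rep(1L, m)))
  runs <- computeRuns(s, buildIndex(s))
  expect_identical(runs@bits[-1L], rep(1L, m - 1L))
})

test_that("disjoint alphabets give all-zero matching statistics", {
  S <- asSequence(c(5L, 6L, 5L), sigma = 6L)
  T <- asSequence(c(1L, 2L, 1L, 2L), sigma = 2L)
  expect_identical(naiveMS(S, T), c(0L, 0L, 0L))
  expect_identical(decodeMS(matchingStatistics(S, T)), c(0L, 0L, 0L))
})

test_that("two-phase pipeline equals the direct-search oracle", {
  set.seed(301)
  for (r in 1:150) {
    sig <- pick(c(2, 4, 20))
    T <- randSeq(pick(1:200), sig)
    S <- if (r %% 17 == 0) T else randSeq(pick(1:200), sig)
    got <- decodeMS(matchingStatistics(S, T))
    expect_identical(got, bruteMS(S, T))
  }
})

test_that("runs bits recompute from the decoded values", {
  set.seed(302)
  for (r in 1:40) {
    sig <- pick(c(2, 4))
    T <- randSeq(pick(2:100), sig); S <- randSeq(pick(2:100), sig)
    idx <- buildIndex(T)
    runs <- computeRuns(S, idx)
    ms <- decodeMS(matchingStatistics(S, T, idxT = idx))
    m <- length(ms)
    expect_identical(runs@bits[-1L],
                     as.integer(ms[-1L] == ms[-m] - 1L))
    expect_identical(runs@bits[1L], 0L)
  }
})

test_that("queries with symbols absent from the text are handled", {
  T <- asSequence("abab")
  S <- asSequence("abcba", alphabet = T@alphabet)
  expect_identical(decodeMS(matchingStatistics(S, "abab")),
                   bruteMS(S, T))
})

test_that("match frequencies equal naive occurrence counts", {
  set.seed(303)
  for (r in 1:40) {
    sig <- pick(c(2, 4))
    T <- randSeq(pick(1:80), sig); S <- randSeq(pick(1:80), sig)
    res <- msWithFrequencies(S, T)
    vals <- decodeMS(res$ms)
    tv <- seqSymbols(T); sv <- seqSymbols(S)
    expf <- vapply(seq_along(sv), function(i)
      if (vals[i] == 0L) 0L else naiveCount(sv[i:(i + vals[i] - 1L)], tv),
      integer(1))
    expect_identical(res$freq, expf)
    expect_true(all(res$freq[vals >= 1L] >= 1L))
    expect_true(all(res$freq[vals == 0L] == 0L))
  }
  resST <- msWithFrequencies("abab", "abab")
  expect_true(all(resST$freq >= 1L))
})

test_that("an inconsistent runs bitvector is rejected rather than decoded", {
  T <- asSequence("abab")
  idxR <- buildIndex(reverseSequence(T))
  S <- asSequence("bba", alphabet = T@alphabet)
  badRuns <- new("RunsBitvector", bits = c(0L, 1L, 1L))
  ## surfaces either as an explicit scan error or as a violated decoding
  ## invariant, whichever the malformed input trips first
  expect_error(computeMS(S, idxR, badRuns),
               "inconsistent|negative decoded")
})

test_that("PLCP bitvector matches a naive sort-and-compare oracle", {
  ## distinct symbols: PLCP is all zeros
  expect_identical(decodeMS(computePLCPBitvector(asSequence(1:6, sigma = 6))),
                   rep(0L, 6L))
  set.seed(304)
  for (r in 1:20) {
    t <- seqSymbols(randSeq(pick(1:150), pick(c(2, 4))))
    tx <- c(t, 0L)
    sa <- naiveSuffixArray(t)
    lcpPair <- function(i, j) {
      l <- 0L
      while (i + l < length(tx) - 1L && j + l < length(tx) - 1L &&
             tx[i + l + 1L] == tx[j + l + 1L]) l <- l + 1L
      l
    }
    plcp <- integer(length(t))
    for (r2 in 2:length(sa)) {
      p <- sa[r2]
      if (p < length(t)) plcp[p + 1L] <- lcpPair(sa[r2 - 1L], p)
    }
    bv <- computePLCPBitvector(asSequence(t, sigma = max(t)))
    expect_identical(decodeMS(bv), plcp)
    expect_identical(length(bv@bits), 2L * length(t))
  }
})
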