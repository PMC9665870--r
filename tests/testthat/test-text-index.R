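test_that("index of a known text matches hand-derived structures", {
  idx <- buildIndex("abab")
  expect_identical(idx@sa, c(4L, 2L, 0L, 3L, 1L))
  expect_identical(idx@bwt, c(2L, 2L, 0L, 1L, 1L))   # "bb$aa"
  idx1 <- buildIndex("a")
  expect_identical(idx1@sa, c(1L, 0L))
  expect_identical(idx1@bwt, c(1L, 0L))              # "a$"
})

test_that("suffix array agrees with naive full-suffix sorting", {
  set.seed(101)
  for (r in 1:40) {
    n <- pick(1:200)
    t <- randSeq(n, pick(c(2, 4, 20)))
    expect_identical(buildIndex(t)@sa, naiveSuffixArray(seqSymbols(t)))
  }
})

test_that("LCP array matches pairwise comparison of sorted suffixes", {
  set.seed(102)
  for (r in 1:15) {
    t <- seqSymbols(randSeq(pick(2:80), pick(c(2, 4))))
    idx <- buildIndex(asSequence(t, sigma = max(t)))
    tx <- c(t, 0L)
    sa <- idx@sa
    lcpPair <- function(i, j) {
      a <- tx[(i + 1):length(tx)]; b <- tx[(j + 1):length(tx)]
      l <- 0L
      while (l < min(length(a), length(b)) && a[l + 1] == b[l + 1]) l <- l + 1L
      l
    }
    expLcp <- vapply(2:length(sa), function(r) lcpPair(sa[r - 1], sa[r]),
                     integer(1))
    expect_identical(idx@lcp[2:length(sa)], expLcp)
  }
})

test_that("backward step maps string intervals and rejects absent symbols", {
  idx <- buildIndex("abab")
  root <- rootInterval(idx)
  ivA <- backwardStep(idx, root, 1L)
  expect_identical(as.integer(ivA), c(1L, 2L))       # rows of "a…"
  ivBA <- backwardStep(idx, ivA, 2L)
  expect_identical(as.integer(ivBA), c(4L, 4L))      # "ba" occurs once
  expect_identical(as.integer(backwardStep(idx, rootInterval(idx), 2L)),
                   c(3L, 4L))                        # rows of "b…"
  expect_true(isEmptyInterval(backwardStep(idx, root, 3L)))  # 'c' absent
})

test_that("backward search counts occurrences of every substring", {
  set.seed(103)
  for (r in 1:10) {
    t <- seqSymbols(randSeq(pick(2:60), pick(c(2, 4))))
    idx <- buildIndex(asSequence(t, sigma = max(t)))
    for (i in seq_along(t)) for (j in i:min(i + 6, length(t))) {
      pat <- t[i:j]
      iv <- patternInterval(idx, asSequence(pat, sigma = idx@sigma))
      expect_identical(intervalWidth(iv), naiveCount(pat, t))
    }
  }
})

test_that("parent interval is the smallest strictly enclosing lcp-interval", {
  idx <- buildIndex("abab")
  aba <- patternInterval(idx, "aba")
  p <- parentInterval(idx, aba)
  expect_identical(as.integer(p), c(1L, 2L))         # interval of "ab"
  expect_identical(attr(p, "depth"), 2L)
  ab <- patternInterval(idx, "ab")
  expect_identical(as.integer(parentInterval(idx, ab)),
                   as.integer(rootInterval(idx)))
  expect_error(parentInterval(idx, rootInterval(idx)), "root")
})

test_that("repeated parents strictly grow and reach the root in <= n steps", {
  set.seed(104)
  for (r in 1:10) {
    t <- randSeq(pick(5:80), pick(c(2, 4)))
    idx <- buildIndex(t)
    i <- pick(seq_len(seqLength(t)))
    pat <- seqSymbols(t)[i:min(i + pick(1:6), seqLength(t))]
    iv <- patternInterval(idx, asSequence(pat, sigma = idx@sigma))
    steps <- 0L
    while (!isRootInterval(idx, iv)) {
      nxt <- parentInterval(idx, iv)
      expect_gt(intervalWidth(nxt), intervalWidth(iv))
      iv <- as.integer(nxt[1:2])
      steps <- steps + 1L
      expect_lte(steps, seqLength(t))
    }
  }
})

test_that("the sentinel never takes part in a match", {
  ## the sentinel occurs once at the end, so no pattern interval of width
  ## > 1 can involve it, and a full-text match has width exactly 1
  idx <- buildIndex("abab")
  full <- patternInterval(idx, "abab")
  expect_identical(intervalWidth(full), 1L)
  ## MS against a text whose last symbol is unique elsewhere cannot exceed n
  expect_identical(max(decodeMS(matchingStatistics("ababab", "abab"))), 4L)
})
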