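test_that("block index summarizes the worked example", {
  bv <- msbvFromText("010011")          # MS = 1 2 1
  idx <- buildBlockIndex(bv, 8L)
  expect_identical(idx@nBlocks, 1L)
  expect_identical(idx@blockMax, 2L)
  expect_identical(idx@blockOnes, 3L)
  expect_identical(idx@blockPrefix, 4)
  expect_identical(rangeMax(idx, bv, 0L, 2L), 2L)
  expect_identical(rangeSum(idx, bv, 0L, 2L), 4)
  expect_identical(reportGE(idx, bv, 0L, 2L, 2L), 1L)
  expect_error(buildBlockIndex(bv, 12L), "multiple of 8")
})

test_that("blocks without one-bits carry the empty sentinel", {
  bv <- encodeMS(c(30L, 29L, 28L))      # long leading zero run
  idx <- buildBlockIndex(bv, 8L)
  expect_true(any(is.na(idx@blockMax)))
  expect_identical(sum(idx@blockOnes), 3L)
  expect_identical(rangeMax(idx, bv, 0L, 2L), 30L)
})

test_that("range queries agree with naive scans across block sizes", {
  set.seed(601)
  for (r in 1:60) {
    m <- pick(3:200)
    ms <- randMSArray(m, hi = 20L)
    bv <- encodeMS(ms)
    idx <- buildBlockIndex(bv, pick(c(8L, 64L, 1024L)))
    for (q in 1:4) {
      i <- pick(0:(m - 1L)); j <- pick(i:(m - 1L))
      sl <- ms[(i + 1L):(j + 1L)]
      expect_identical(rangeMax(idx, bv, i, j), max(sl))
      expect_identical(rangeSum(idx, bv, i, j), as.numeric(sum(sl)))
      tau <- pick(1:10)
      expect_identical(reportGE(idx, bv, i, j, tau),
                       as.integer(which(sl >= tau) + i - 1L))
    }
  }
})

test_that("point queries reduce to access", {
  set.seed(602)
  ms <- randMSArray(50L)
  bv <- encodeMS(ms)
  idx <- buildBlockIndex(bv, 8L)
  for (i in c(0L, 7L, 49L)) {
    expect_identical(rangeMax(idx, bv, i, i), msAccess(bv, i))
    expect_identical(rangeSum(idx, bv, i, i), as.numeric(msAccess(bv, i)))
  }
  expect_error(rangeMax(idx, bv, -1L, 3L), "bounds")
  expect_error(rangeMax(idx, bv, 0L, 50L), "bounds")
})

test_that("histogram, cover and window analytics match naive computation", {
  bv <- msbvFromText("010011")
  h <- msHistogram(bv, 0L, 2L)
  expect_identical(h, c(`1` = 2L, `2` = 1L))
  ## self-comparison: position 0 covers everything
  s <- asSequence("banana")
  bvS <- matchingStatistics(s, s)
  expect_identical(longestCover(bvS, 2L, 4L), 0L)
  set.seed(603)
  for (r in 1:40) {
    m <- pick(3:120)
    ms <- randMSArray(m, hi = 15L)
    bv <- encodeMS(ms)
    i <- pick(0:(m - 1L)); j <- pick(i:(m - 1L))
    sl <- ms[(i + 1L):(j + 1L)]
    expect_identical(as.integer(msHistogram(bv, i, j)),
                     as.integer(table(sl)))
    k <- pick(1:(j - i + 1L))
    sums <- vapply(i:(j - k + 1L), function(s0)
      sum(ms[(s0 + 1L):(s0 + k)]), numeric(1))
    expect_identical(maxWindows(bv, i, j, k),
                     as.integer((i:(j - k + 1L))[sums == max(sums)]))
    cov <- (0:i) + ms[1:(i + 1L)] - 1L >= j
    if (any(cov)) {
      expect_identical(longestCover(bv, i, j),
                       (0:i)[cov][which.max(ms[1:(i + 1L)][cov])])
    } else {
      expect_error(longestCover(bv, i, j), "covers")
    }
  }
})

test_that("word-scan and run-scan backends yield identical value streams", {
  set.seed(604)
  for (r in 1:40) {
    bv <- encodeMS(randMSArray(pick(1:150)))
    w <- scanChunk(bv@bits, "word")
    expect_identical(w, scanChunk(bv@bits, "run"))
    expect_identical(w, decodeMS(bv))
    ## run backend accepts the RLE container directly
    expect_identical(scanChunk(rleEncode(bv@bits), "run"), w)
  }
  staircase <- c(rep(0L, 6L), rep(1L, 6L))
  expect_identical(length(rleEncode(staircase)$lengths), 2L)
  expect_identical(scanChunk(staircase, "run"), 6:1)
})

test_that("queries above the threshold survive lossy compression", {
  set.seed(605)
  for (r in 1:25) {
    m <- pick(10:120)
    bv <- encodeMS(randMSArray(m, hi = 14L))
    tau <- pick(2:4)
    cb <- suppressMessages(compressMS(bv, thresholdSpec(tau), "ND"))
    idx0 <- buildBlockIndex(bv, 64L)
    idx1 <- buildBlockIndex(cb, 64L)
    i <- pick(0:(m - 1L)); j <- pick(i:(m - 1L))
    trueMax <- rangeMax(idx0, bv, i, j)
    if (trueMax >= tau)
      expect_identical(rangeMax(idx1, cb, i, j), trueMax)
    for (tp in tau:(tau + 3L))
      expect_identical(reportGE(idx1, cb, i, j, tp),
                       reportGE(idx0, bv, i, j, tp))
  }
})
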