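test_that("anchors are all and only the positions at or above threshold", {
  bv <- encodeMS(c(1L, 2L, 1L))
  a2 <- findAnchors(bv, 2L)
  expect_identical(a2$x, 1L)
  expect_identical(a2$y, 4L)
  a1 <- findAnchors(bv, 1L)
  expect_identical(a1$x, 0:2)
  expect_identical(findAnchors(bv, 3L)$x, integer(0))
  ## increasing tau never increases the anchor count
  set.seed(501)
  for (r in 1:20) {
    bv <- encodeMS(randMSArray(pick(5:60)))
    k <- vapply(1:9, function(tt) length(findAnchors(bv, tt)$x), integer(1))
    expect_true(all(diff(k) <= 0L))
  }
})

test_that("g map is a bijection inverted exactly by gUnmap", {
  expect_identical(gMap(5L, 5L), 1L)
  expect_identical(gMap(4L, 5L), 2L)
  expect_identical(gMap(3L, 5L), 4L)
  expect_identical(gMap(6L, 5L), 3L)
  expect_identical(gMap(7L, 5L), 5L)
  expect_identical(gMap(9L, 5L), 9L)
  for (x in 1:64) {
    codes <- gMap(1:200, x)
    expect_identical(anyDuplicated(codes), 0L)
    expect_identical(gUnmap(codes, x), 1:200)
  }
})

test_that("window DP cost equals the exhaustive-enumeration minimum", {
  ## spot grid here; the full stated grid runs in the acceptance suite
  delta <- eliasDeltaLength
  for (tau in c(2L, 4L)) for (mv in 0:1) {
    if (mv >= tau) next
    for (z in c(0L, 2L, 4L, 6L)) for (o in c(1L, 3L, 5L)) {
      for (type in c("anchor", "free")) {
        oF <- if (type == "anchor") o - 1L else o
        expc <- enumWindowBest(z, oF, tau, mv, tau, type)
        plan <- optimalWindowPermutation(z, o, tau, delta, mv, type = type)
        got <- if (plan$feasible) plan$cost else Inf
        expect_equal(got, expc,
                     info = sprintf("z=%d o=%d tau=%d mv=%d %s",
                                    z, o, tau, mv, type))
        if (plan$feasible) {
          bits <- planToBits(plan)
          expect_identical(sum(bits == 0L), z)
          expect_identical(sum(bits == 1L), oF)
          v <- windowValues(bits, tau)
          expect_true(all(v >= mv & v <= tau - 1L))
        }
      }
    }
  }
})

test_that("trivial negative permutation is ones then zeros", {
  expect_identical(trivialNegativePermutation(3L, 2L),
                   c(1L, 1L, 1L, 0L, 0L))
  expect_identical(trivialNegativePermutation(0L, 4L), rep(0L, 4L))
})

test_that("compress preserves anchors and bounds for every variant", {
  set.seed(502)
  for (r in 1:30) {
    bv <- encodeMS(randMSArray(pick(5:60)))
    for (tau in c(2L, 4L)) for (neg in c(FALSE, TRUE))
      for (v in c("ND", "D", "DL")) {
        sp <- thresholdSpec(tau, allowNegative = neg)
        cb <- suppressMessages(compressMS(bv, sp, v))
        expect_true(verifyThresholded(bv, cb, sp))
        expect_identical(sort(cb@bits), sort(bv@bits))   # permutation
        expect_identical(cb@allowNegative, neg)
      }
  }
})

test_that("compress is the identity when no window is permutable", {
  bv <- encodeMS(c(9L, 8L, 7L, 6L, 5L))
  expect_identical(compressMS(bv, thresholdSpec(3L))@bits, bv@bits)
})

test_that("ND with negatives rewrites windows as ones-then-zeros", {
  bv <- encodeMS(c(1L, 5L, 4L, 3L, 2L, 1L, 0L, 1L))
  sp <- thresholdSpec(3L, allowNegative = TRUE)
  cb <- compressMS(bv, sp, "ND")
  expect_true(verifyThresholded(bv, cb, sp))
  y <- findAnchors(bv, 3L)$y
  suffix <- cb@bits[(y[length(y)] + 2L):length(cb@bits)]
  ones <- sum(suffix == 1L)
  expect_identical(suffix, c(rep(1L, ones), rep(0L, length(suffix) - ones)))
})

test_that("verifyThresholded rejects a moved anchor", {
  bv <- encodeMS(c(1L, 2L, 1L))
  sp <- thresholdSpec(2L)
  expect_true(verifyThresholded(bv, bv, sp))
  moved <- msbvFromText("010101")   # same counts, anchor displaced
  expect_false(verifyThresholded(bv, moved, sp))
})

test_that("the DP plan never costs more than any valid arrangement", {
  ## in particular never more than the identity arrangement of a window
  set.seed(503)
  delta <- eliasDeltaLength
  for (r in 1:25) {
    tau <- pick(2:4); z <- pick(1:6); oF <- pick(1:5)
    slots <- z + oF
    combos <- utils::combn(slots, oF)
    costs <- c()
    for (cc in seq_len(ncol(combos))) {
      bits <- integer(slots); bits[combos[, cc]] <- 1L
      if (bits[slots] != 0L) next
      v <- windowValues(bits, tau)
      if (any(v < 0L | v > tau - 1L)) next
      costs <- c(costs, sum(delta(rle(bits)$lengths)))
    }
    plan <- optimalWindowPermutation(z, oF + 1L, tau, delta, type = "anchor")
    if (length(costs)) {
      expect_true(plan$feasible)
      expect_true(all(plan$cost <= costs))
    } else {
      expect_false(plan$feasible)
    }
  }
})

test_that("precomputed DAG answers match the per-window DP in-cap", {
  delta <- eliasDeltaLength
  dag <- buildWindowDAG(15L, 15L, 3L, delta)
  for (z in c(1L, 3L, 8L, 12L)) for (o in c(2L, 5L, 9L)) {
    a <- optimalWindowPermutation(z, o, 3L, delta, type = "anchor")
    b <- queryDAG(dag, z, o)
    expect_identical(a$feasible, b$feasible)
    if (a$feasible) expect_equal(a$cost, b$cost)
  }
  ## out-of-cap greedy fallback still returns the right bit counts
  small <- buildWindowDAG(5L, 5L, 3L, delta)
  p <- queryDAG(small, 14L, 10L)
  expect_true(p$feasible)
  bits <- planToBits(p)
  expect_identical(sum(bits == 0L), 14L)
  expect_identical(sum(bits == 1L), 9L)
  p2 <- queryDAG(small, 14L, 10L, strategy = 2L)
  bits2 <- planToBits(p2)
  expect_identical(sum(bits2 == 0L), 14L)
  expect_identical(sum(bits2 == 1L), 9L)
  ## forced tiny query
  p3 <- queryDAG(dag, 1L, 1L)
  expect_true(p3$feasible)
  expect_identical(planToBits(p3), 0L)
})

test_that("run-length coding round-trips and sizes as stated", {
  set.seed(504)
  for (r in 1:40) {
    b <- sample(0:1, pick(1:300), replace = TRUE)
    expect_identical(rleDecode(rleEncode(b)), as.integer(b))
  }
  expect_identical(rleSize(c(rep(0L, 5L), rep(1L, 5L))),
                   2L * eliasDeltaLength(5L) + 1L)
  expect_identical(rleSize(rep(1L, 9L)), eliasDeltaLength(9L) + 1L)
})

test_that("sparse baselines follow their stated formulas", {
  bv <- encodeMS(c(1L, 2L, 1L))
  expect_identical(sparseSizeB(bv, 2L), 3L)   # 1 entry, ceil(lg 2)+ceil(lg 3)
  expect_identical(sparseSizeA(bv, 3L), 0L)
  expect_identical(sparseSizeB(bv, 3L), 0L)
  set.seed(505)
  for (r in 1:20) {
    bv <- encodeMS(randMSArray(pick(5:80)))
    for (tau in c(2L, 4L))
      expect_lte(sparseSizeA(bv, tau), sparseSizeB(bv, tau))
  }
})

test_that("compression report measures both directions of Figure-style ratios", {
  ## similar pair: strong shrinkage at a high threshold
  p <- synthPair(4000, 0.002, 4L, seed = 11L)
  bv <- matchingStatistics(p$S, p$T)
  rep1 <- compressionReport(bv, thresholdSpec(16L), "ND")
  expect_lt(rep1$ratio, 1)
  ## unrelated pair at tau = 1: run coding expands the bitvector
  set.seed(506)
  T2 <- randSeq(800, 4L); S2 <- randSeq(800, 4L)
  bv2 <- matchingStatistics(S2, T2)
  rep2 <- compressionReport(bv2, thresholdSpec(1L), "ND")
  expect_gt(rep2$ratio, 1)
  expect_identical(rep2$plain_bits, length(bv2@bits))
  ## deterministic given inputs
  rep3 <- compressionReport(bv2, thresholdSpec(1L), "ND")
  expect_identical(rep2, rep3)
})
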