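mkBoxes <- function(n, label = "t", scores = NULL, offset = 0) {
  data.frame(label = label,
             L = offset + (seq_len(n) - 1) * 20, T = 0,
             R = offset + (seq_len(n) - 1) * 20 + 10, B = 10,
             score = scores %||% rep(1, n), stringsAsFactors = FALSE)
}

test_that("perfect predictions match every truth box", {
  truth <- mkBoxes(5)[, 1:5]
  pred <- mkBoxes(5)
  m <- matchDetections(pred, truth)
  expect_equal(c(m$nTp, m$nFp, m$nFn), c(5L, 0L, 0L))
})

test_that("a wrong label is a false positive and leaves truths unmatched", {
  truth <- mkBoxes(3)[, 1:5]
  pred <- mkBoxes(1, label = "other")
  m <- matchDetections(pred, truth)
  expect_equal(c(m$nTp, m$nFp, m$nFn), c(0L, 1L, 3L))
})

test_that("greedy matching consumes each truth box at most once", {
  truth <- mkBoxes(1)[, 1:5]
  pred <- rbind(mkBoxes(1, scores = 0.9), mkBoxes(1, scores = 0.8))
  m <- matchDetections(pred, truth)
  expect_equal(c(m$nTp, m$nFp, m$nFn), c(1L, 1L, 0L))
  ## the higher-scoring prediction got the match
  expect_equal(m$matches$predRow, 1L)
})

test_that("sub-threshold scores are negatives and bad IoU thresholds error", {
  truth <- mkBoxes(2)[, 1:5]
  pred <- mkBoxes(2, scores = c(0.9, 0.2))
  m <- matchDetections(pred, truth, scoreThreshold = 0.5)
  expect_equal(c(m$nTp, m$nFp, m$nFn), c(1L, 0L, 1L))
  expect_error(matchDetections(pred, truth, iouThreshold = 0), "\\(0, 1\\]")
  expect_error(matchDetections(pred, truth, iouThreshold = 1.5), "\\(0, 1\\]")
})

test_that("precision/recall/F1 match the printed-table arithmetic", {
  ## the published P = 90.82%, R = 90.80% row rounds to F1 = 0.9
  expect_equal(round(f1Score(0.9082, 0.9080), 1), 0.9)
  expect_equal(f1Score(0.7, 0.7), 0.7)
  prf <- precisionRecallF1(list(nTp = 0L, nFp = 0L, nFn = 5L))
  expect_equal(unname(prf), c(0, 0, 0))
  prf2 <- precisionRecallF1(list(nTp = 8L, nFp = 2L, nFn = 2L))
  expect_equal(unname(prf2), c(0.8, 0.8, 0.8))
})

test_that("F1 obeys its harmonic-mean bounds on random counts", {
  set.seed(5)
  for (i in 1:200) {
    m <- list(nTp = sample(0:20, 1), nFp = sample(0:20, 1),
              nFn = sample(0:20, 1))
    prf <- precisionRecallF1(m)
    expect_true(all(prf >= 0 & prf <= 1))
    expect_lte(prf[["f1"]], (prf[["precision"]] + prf[["recall"]]) / 2 + 1e-12)
  }
})

test_that("AP is 1 for a perfect ranking and 0.5 for [wrong, right]", {
  truth <- mkBoxes(1)[, 1:5]
  expect_equal(averagePrecision(mkBoxes(1), truth, "t"), 1)
  pred <- rbind(mkBoxes(1, scores = 0.9, offset = 500),  # wrong box first
                mkBoxes(1, scores = 0.8))
  expect_equal(averagePrecision(pred, truth, "t"), 0.5)
  expect_error(averagePrecision(mkBoxes(1), truth, "nope"), "no ground-truth")
})

test_that("AP equals the brute-force PR-curve oracle on random instances", {
  set.seed(77)
  for (trial in 1:150) {
    nT <- sample(1:5, 1); nP <- sample(1:8, 1)
    truth <- data.frame(label = "t", L = runif(nT, 0, 80), T = runif(nT, 0, 80),
                        stringsAsFactors = FALSE)
    truth$R <- truth$L + runif(nT, 5, 30); truth$B <- truth$T + runif(nT, 5, 30)
    base <- truth[sample(nT, nP, replace = TRUE), , drop = FALSE]
    pred <- data.frame(label = "t",
                       L = base$L + runif(nP, -10, 10),
                       T = base$T + runif(nP, -10, 10),
                       stringsAsFactors = FALSE)
    pred$R <- pred$L + (base$R - base$L) * runif(nP, 0.7, 1.3)
    pred$B <- pred$T + (base$B - base$T) * runif(nP, 0.7, 1.3)
    pred$score <- runif(nP)
    expect_equal(averagePrecision(pred, truth, "t", iouThreshold = 0.5),
                 bruteForceAP(pred, truth, iouThreshold = 0.5),
                 tolerance = 1e-9)
  }
})

test_that("mAP averages labels with ground truth and errors without any", {
  truth <- rbind(mkBoxes(2, label = "a")[, 1:5],
                 mkBoxes(2, label = "b", offset = 200)[, 1:5])
  pred <- rbind(mkBoxes(2, label = "a"),
                mkBoxes(1, label = "b", offset = 900))  # b never matched
  expect_equal(meanAveragePrecision(pred, truth), 0.5)
  expect_error(meanAveragePrecision(pred, truth[0, ]), "mAP undefined")
})

test_that("OIR counts included mask pixels per the centre-in-box rule", {
  mask <- matrix(TRUE, 10, 10)
  expect_equal(oir(mask, Box(0, 0, 10, 10)), 1)
  expect_equal(oir(mask, Box(-5, -5, 50, 50)), 1)   # box superset of mask
  expect_equal(oir(mask, Box(40, 40, 50, 50)), 0)   # disjoint
  expect_equal(oir(mask, Box(0, 0, 5, 10)), 0.5)    # exact left half
  expect_error(oir(matrix(FALSE, 4, 4), Box(0, 0, 4, 4)), "missing")
})

test_that("OIR never decreases as the box grows", {
  set.seed(13)
  for (trial in 1:30) {
    mask <- matrix(runif(400) < 0.3, 20, 20)
    if (!any(mask)) next
    b <- Box(runif(1, 0, 10), runif(1, 0, 10),
             runif(1, 10, 20), runif(1, 10, 20))
    vals <- vapply(seq(0, 1, by = 0.2), function(g)
      oir(mask, enlargeBox(b, g)), 0)
    expect_true(all(diff(vals) >= -1e-12))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("per-image OIR skips teeth flagged missing", {
  mask <- matrix(TRUE, 4, 4)
  items <- list(list(mask = mask, box = Box(0, 0, 4, 4)),
                list(mask = mask, box = Box(0, 0, 2, 4)),
                list(mask = matrix(FALSE, 4, 4), box = Box(0, 0, 4, 4),
                     missing = TRUE))
  expect_equal(perImageOir(items), 0.75)
  expect_true(is.na(perImageOir(list(list(mask = mask, box = Box(0, 0, 4, 4),
                                          missing = TRUE)))))
})

test_that("the evaluation report pools per-image matches", {
  truth <- rbind(cbind(mkBoxes(2, label = "a")[, 1:5], image = 1L),
                 cbind(mkBoxes(2, label = "a")[, 1:5], image = 2L))
  pred <- rbind(cbind(mkBoxes(2, label = "a"), image = 1L),
                cbind(mkBoxes(1, label = "a"), image = 2L))
  rep <- evaluateDetections(pred, truth)
  expect_equal(rep$counts$nTp, 3L)
  expect_equal(rep$recall, 0.75)
  expect_equal(rep$precision, 1)
  expect_equal(rep$mAP, averagePrecision(pred, truth, "a"))
})
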