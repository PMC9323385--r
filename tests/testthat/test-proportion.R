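test_that("proportional point evaluates the position-ratio formula", {
  u <- Box(0, 0, 1, 1)
  expect_equal(unname(proportionalPoint(u, 1, 1)), c(0.5, 0.5))
  expect_equal(unname(proportionalPoint(u, 1 / 6, 2 / 9)),
               c(1 / 7, 2 / 11))
  expect_equal(unname(proportionalPoint(u, 0, 0)), c(0, 0))
  expect_equal(unname(proportionalPoint(u, Inf, Inf)), c(1, 1))
})

test_that("proportional point agrees with a bisection solve of the ratio", {
  ## independent oracle: solve lambda = (x - x1)/(x2 - x) for x by bisection
  solveRatio <- function(x1, x2, lambda) {
    lo <- x1; hi <- x2
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if ((mid - x1) - lambda * (x2 - mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  set.seed(8)
  grid <- c(0.01, 0.05, 0.2, 0.5, 1, 2, 5, 10)
  for (lx in grid) for (ly in grid) {
    b <- Box(runif(1, 0, 50), runif(1, 0, 50),
             runif(1, 60, 100), runif(1, 60, 100))
    p <- proportionalPoint(b, lx, ly)
    expect_equal(p[["x"]], solveRatio(b[["L"]], b[["R"]], lx),
                 tolerance = 1e-9)
    expect_equal(p[["y"]], solveRatio(b[["T"]], b[["B"]], ly),
                 tolerance = 1e-9)
  }
})

test_that("the shipped tooth-45 mapping reproduces its affine form", {
  e45 <- tooth45Proportion()
  expect_equal(unname(toothBoxFromBlock(Box(0, 0, 1, 1), e45)),
               c(0.17, 0.28, 0.83, 0.72))
  expect_equal(unname(toothBoxFromBlock(Box(100, 200, 200, 300), e45)),
               c(117, 228, 183, 272))
  ## the raw lambda evaluation is a related but distinct box
  raw <- toothProportion(e45$lt, e45$rb, enlarge = 0)
  rawBox <- toothBoxFromBlock(Box(0, 0, 1, 1), raw)
  expect_equal(rawBox[["L"]], 1 / 7)
  expect_false(isTRUE(all.equal(rawBox[["L"]], 0.17)))
})

test_that("degenerate block boxes degrade gracefully", {
  e <- toothProportion(c(0.2, 0.2), c(2, 2), enlarge = 0)
  expect_warning(b <- toothBoxFromBlock(Box(5, 0, 5, 10), e), "degenerate")
  expect_equal(b[["L"]], b[["R"]])
})

test_that("block division labels exactly the block's teeth", {
  tab <- defaultLambdaTable()
  out <- divideBlock(Box(0, 0, 100, 40), "upper", "incisors", tab)
  expect_equal(out$tooth, c(12L, 11L, 21L, 22L))
  out2 <- divideBlock(Box(0, 0, 60, 40), "lower", "right_canine_premolar",
                      tab)
  expect_setequal(out2$tooth, c(43L, 44L, 45L))
})

test_that("a missing tooth never shifts its neighbours", {
  tab <- defaultLambdaTable()
  full <- divideBlock(Box(10, 20, 110, 60), "upper", "incisors", tab)
  part <- divideBlock(Box(10, 20, 110, 60), "upper", "incisors", tab,
                      missing = 12L)
  expect_equal(nrow(part), 3L)
  expect_false(12L %in% part$tooth)
  expect_equal(part, full[full$tooth != 12L, ], ignore_attr = TRUE)
  ## property: each tooth's box is independent of any other tooth's absence
  set.seed(21)
  for (trial in 1:20) {
    b <- Box(runif(1, 0, 50), runif(1, 0, 50), runif(1, 60, 200),
             runif(1, 60, 120))
    jaw <- sample(c("upper", "lower"), 1)
    block <- sample(blockNames(), 1)
    teeth <- blockTeeth(jaw, block)
    drop <- sample(teeth, 1)
    full <- divideBlock(b, jaw, block, tab)
    part <- divideBlock(b, jaw, block, tab, missing = drop)
    expect_equal(part, full[full$tooth != drop, ], ignore_attr = TRUE)
  }
})

test_that("a table gap errors naming the tooth", {
  tab <- defaultLambdaTable()
  tab@entries[["44"]] <- NULL
  expect_error(divideBlock(Box(0, 0, 10, 10), "lower",
                           "right_canine_premolar", tab), "44")
})

test_that("pre-enlargement tooth boxes are contained in their block", {
  tab <- defaultLambdaTable(enlarge = 0)
  set.seed(31)
  for (trial in 1:25) {
    b <- Box(runif(1, 0, 100), runif(1, 0, 100),
             runif(1, 110, 300), runif(1, 110, 300))
    for (jaw in c("upper", "lower")) for (block in blockNames()) {
      out <- divideBlock(b, jaw, block, tab)
      expect_true(all(out$L >= b[["L"]] - 1e-9 & out$R <= b[["R"]] + 1e-9 &
                      out$T >= b[["T"]] - 1e-9 & out$B <= b[["B"]] + 1e-9))
    }
  }
})

test_that("lambda tables round trip through YAML", {
  tab <- defaultLambdaTable()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLambdaTable(tab, path)
  back <- readLambdaTable(path)
  expect_setequal(coveredTeeth(back), coveredTeeth(tab))
  for (code in coveredTeeth(tab)) {
    a <- lambdaEntry(tab, code); b <- lambdaEntry(back, code)
    expect_equal(b$lt, a$lt)
    expect_equal(b$rb, a$rb)
    expect_equal(b$enlarge, a$enlarge)
    expect_equal(b$affine, a$affine)
  }
})

test_that("calibration is a no-op at an optimal initialization", {
  ## truth generated from the init table itself
  tab <- defaultLambdaTable(enlarge = 0)
  set.seed(17)
  samples <- lapply(1:4, function(i) {
    b <- Box(runif(1, 0, 40), runif(1, 0, 40), runif(1, 120, 250),
             runif(1, 90, 160))
    out <- divideBlock(b, "lower", "right_canine_premolar", tab)
    tr <- lapply(seq_len(nrow(out)), function(r)
      Box(out$L[r], out$T[r], out$R[r], out$B[r]))
    names(tr) <- out$tooth
    list(jaw = "lower", block = "right_canine_premolar", blockBox = b,
         truth = tr)
  })
  cal <- calibrateLambdas(samples, tab, targetMeanIou = 0.85)
  expect_gte(cal$meanIou, 0.999)
  for (code in c(43L, 44L)) {
    expect_equal(lambdaEntry(cal$table, code)$lt,
                 lambdaEntry(tab, code)$lt)
    expect_equal(lambdaEntry(cal$table, code)$rb,
                 lambdaEntry(tab, code)$rb)
  }
})

test_that("calibration reaches the published criterion on phantom slices", {
  ## mirrors the one-slice-per-patient calibration protocol (14 samples)
  ph <- phantomFixture()
  slices <- round(seq(10, 16, length.out = 7))
  samples <- calibrationSamples(ph$truth, c(slices, slices + 16))
  cal <- calibrateLambdas(samples, defaultLambdaTable(enlarge = 0),
                          targetMeanIou = 0.85)
  expect_gte(cal$meanIou, 0.85)
})

test_that("box propagation follows the nearest same-jaw key slice", {
  ## 10 slices: lower no-tooth 1-2, lower crown 3-6, overlap 7,
  ## upper crown 8-9, upper no-tooth 10
  classes <- c("no_tooth", "crown", "overlap", "crown", "no_tooth")
  ll <- rep(layerLabelNames(), c(2, 4, 1, 2, 1))
  labeling <- antiNoiseSwitch(classes[match(ll, layerLabelNames())],
                              confirmRun = 1L)
  boxA <- data.frame(tooth = 41L, L = 0, T = 0, R = 1, B = 1)
  boxB <- data.frame(tooth = c(41L, 42L), L = c(5, 6), T = c(5, 6),
                     R = c(7, 8), B = c(7, 8))
  boxU <- data.frame(tooth = c(11L, 12L, 13L), L = 1:3, T = 1:3,
                     R = 4:6, B = 4:6)
  keyBoxes <- list(`3` = boxA, `6` = boxB, `8` = boxU)
  out <- propagateBoxes(keyBoxes, labeling)
  expect_equal(out[[3]], boxA)            # a key slice keeps its own boxes
  expect_equal(out[[4]], boxA)            # distance 1 vs 2
  expect_equal(out[[5]], boxB)            # distance 2 vs 1
  expect_equal(out[[1]], boxA)            # lower no-tooth -> nearest lower
  expect_equal(out[[10]], boxU)           # upper no-tooth -> nearest upper
  ## overlap slice receives the union of both jaws' nearest sets
  expect_equal(nrow(out[[7]]), nrow(boxB) + nrow(boxU))
  expect_setequal(out[[7]]$tooth, c(41L, 42L, 11L, 12L, 13L))
})

test_that("propagation ties break toward the smaller slice index", {
  classes <- c("no_tooth", "crown", "overlap", "crown", "no_tooth")
  ll <- rep(layerLabelNames(), c(0, 5, 1, 2, 1))
  labeling <- antiNoiseSwitch(classes[match(ll, layerLabelNames())],
                              confirmRun = 1L)
  boxA <- data.frame(tooth = 41L, L = 0, T = 0, R = 1, B = 1)
  boxB <- data.frame(tooth = 42L, L = 1, T = 1, R = 2, B = 2)
  boxU <- data.frame(tooth = 11L, L = 2, T = 2, R = 3, B = 3)
  out <- propagateBoxes(list(`2` = boxA, `4` = boxB, `7` = boxU), labeling)
  expect_equal(out[[3]], boxA)   # equidistant from keys 2 and 4
  expect_error(propagateBoxes(list(), labeling), "empty")
})
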