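test_that("the phantom is a pure function of its configuration", {
  cfg <- phantomConfig(regionLengths = c(3L, 4L, 3L, 4L, 3L), seed = 7L)
  a <- generatePhantom(cfg)
  b <- generatePhantom(cfg)
  expect_identical(a$stack@slices, b$stack@slices)
  expect_identical(a$truth@teeth, b$truth@teeth)
  expect_identical(a$truth@blocks, b$truth@blocks)
})

test_that("region lengths drive the class-label sequence", {
  ph <- generatePhantom(phantomConfig(regionLengths = rep(5L, 5)))
  expect_equal(ph$truth@classLabels,
               rep(c("no_tooth", "crown", "overlap", "crown", "no_tooth"),
                   each = 5))
  expect_equal(ph$truth@layerLabels, rep(layerLabelNames(), each = 5))
  expect_equal(nSlices(ph$stack), 25L)
})

test_that("missing teeth are absent from truth but blocks stay complete", {
  ph <- generatePhantom(phantomConfig(missing = 45L))
  s <- 12L   # lower crown
  tb <- toothBoxes(ph$truth, s)
  expect_equal(nrow(tb), 15L)
  expect_false(45L %in% tb$tooth)
  expect_equal(nrow(blockBoxes(ph$truth, s)), 5L)
  ## overlap slices carry both jaws: 15 + 16 teeth
  ov <- toothBoxes(ph$truth, 20L)
  expect_equal(nrow(ov), 31L)
})

test_that("the containment chain holds on every slice with teeth", {
  ph <- phantomFixture()
  truth <- ph$truth
  for (s in sort(unique(truth@teeth$slice))) {
    tb <- toothBoxes(truth, s)
    bb <- blockBoxes(truth, s)
    main <- mainAreaBox(truth, s)
    for (r in seq_len(nrow(tb))) {
      blk <- bb[bb$jaw == tb$jaw[r] & bb$block == tb$block[r], , drop = FALSE]
      expect_true(tb$L[r] >= blk$L && tb$R[r] <= blk$R &&
                  tb$T[r] >= blk$T && tb$B[r] <= blk$B)
    }
    expect_true(all(bb$L >= main[["L"]] & bb$R <= main[["R"]] &
                    bb$T >= main[["T"]] & bb$B <= main[["B"]]))
  }
  ## mask pixels lie inside the tooth box (spot-check one slice per jaw)
  for (s in c(12L, 28L)) {
    tb <- toothBoxes(truth, s)
    for (r in seq_len(nrow(tb))) {
      mask <- toothMask(truth, s, tb$tooth[r])
      px <- which(mask, arr.ind = TRUE)
      xs <- px[, 2] - 0.5; ys <- px[, 1] - 0.5
      expect_true(all(xs >= tb$L[r] & xs < tb$R[r] &
                      ys >= tb$T[r] & ys < tb$B[r]))
    }
  }
})

test_that("slices render teeth only in their active regions", {
  ph <- phantomFixture()
  ## a no-tooth slice has no very bright pixels, a crown slice has many
  expect_equal(sum(getSlice(ph$stack, 2) > 200), 0)
  expect_gt(sum(getSlice(ph$stack, 12) > 200), 1000)
})

test_that("metal artefacts brighten rays without touching the truth", {
  cfg <- phantomConfig(regionLengths = c(2L, 3L, 2L, 3L, 2L), seed = 4L)
  ph <- generatePhantom(cfg)
  noisy <- addMetalArtefacts(ph$stack, ph$truth, tooth = 41L, nStreaks = 8L,
                             seed = 4L)
  ang <- attr(noisy, "streakAngles")
  expect_length(ang$bright, 8L)
  s <- 4L   # lower crown slice contains tooth 41
  row <- ph$truth@teeth[ph$truth@teeth$slice == s &
                        ph$truth@teeth$tooth == 41L, ]
  pre <- getSlice(ph$stack, s); post <- getSlice(noisy, s)
  brightened <- 0L
  for (a in ang$bright) {
    steps <- seq(20, 100, by = 1)
    xs <- floor(row$cx + cos(a) * steps) + 1L
    ys <- floor(row$cy + sin(a) * steps) + 1L
    keep <- xs >= 1 & xs <= 256 & ys >= 1 & ys <= 256
    idx <- cbind(ys[keep], xs[keep])
    if (max(post[idx]) > max(pre[idx])) brightened <- brightened + 1L
  }
  expect_gte(brightened, 8L)
  ## zero streaks and bands is a no-op; fixed seeds reproduce exactly
  same <- addMetalArtefacts(ph$stack, ph$truth, tooth = 41L, nStreaks = 0L,
                            darkBands = 0L)
  expect_identical(same@slices, ph$stack@slices)
  again <- addMetalArtefacts(ph$stack, ph$truth, tooth = 41L, nStreaks = 8L,
                             seed = 4L)
  expect_identical(noisy@slices, again@slices)
  expect_error(addMetalArtefacts(ph$stack, ph$truth, tooth = 99L), "invalid|missing")
})

test_that("oracle classifier flips at the configured rate", {
  labels <- rep("crown", 1e4)
  cls <- oracleClassifier(labels, errorRate = 0.05, seed = 21L)
  got <- vapply(seq_along(labels), function(i) cls(NULL, i), "")
  frac <- mean(got != "crown")
  sigma <- sqrt(0.05 * 0.95 / 1e4)
  expect_lt(abs(frac - 0.05), 3 * sigma)
  ## zero error rate reproduces the truth exactly
  cls0 <- oracleClassifier(labels[1:50], errorRate = 0)
  expect_equal(vapply(1:50, function(i) cls0(NULL, i), ""), labels[1:50])
})

test_that("oracle detector without jitter returns truth boxes verbatim", {
  ph <- phantomFixture()
  det <- oracleDetector(ph$truth, jitterPx = 0)
  s <- 12L
  main <- det(NULL, "main_area", index = s)
  expect_equal(unname(c(main$L, main$T, main$R, main$B)),
               unname(mainAreaBox(ph$truth, s)))
  blocks <- det(NULL, "blocks", index = s)
  tb <- blockBoxes(ph$truth, s)
  expect_equal(blocks$L[match(tb$block, blocks$label)], tb$L)
  expect_equal(blocks$score, rep(1, nrow(blocks)))
})

test_that("artefact-configured phantoms build in one call", {
  cfg <- phantomConfig(regionLengths = c(2L, 3L, 2L, 3L, 2L),
                       artefact = list(tooth = 41L, nStreaks = 6L))
  ph <- generatePhantom(cfg)
  expect_length(attr(ph$stack, "streakAngles")$bright, 6L)
})
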