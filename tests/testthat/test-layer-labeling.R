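test_that("consecutive-error probability follows the independent model", {
  expect_equal(consecutiveErrorProbability(0.05, 2), 0.0025)
  expect_equal(consecutiveErrorProbability(0.05, 3), 0.000125)
  expect_equal(consecutiveErrorProbability(0, 5), 0)
  ## monotone decreasing in the run length for error < 1
  for (p in c(0.01, 0.2, 0.7)) {
    vals <- vapply(1:6, function(k) consecutiveErrorProbability(p, k), 0)
    expect_true(all(diff(vals) < 0))
  }
})

test_that("anti-noise switch traces a clean 5-region sequence", {
  lab <- rep(c("no_tooth", "crown", "overlap", "crown", "no_tooth"), each = 3)
  out <- antiNoiseSwitch(lab, confirmRun = 3L)
  expect_equal(layerLabels(out), rep(layerLabelNames(), each = 3))
  expect_equal(boundaries(out), c(4L, 7L, 10L, 13L))
  expect_equal(classLabels(out), lab)
})

test_that("anti-noise switch ignores bursts shorter than the confirm run", {
  lab <- c("no_tooth", "no_tooth", "crown", "no_tooth", "no_tooth",
           "no_tooth", "crown", "crown", "crown")
  out <- antiNoiseSwitch(lab, confirmRun = 3L)
  expect_equal(layerLabels(out),
               c(rep("lower_no_tooth", 6), rep("lower_crown", 3)))
  expect_equal(boundaries(out), c(7L, NA, NA, NA))
})

test_that("constant input never switches", {
  out <- antiNoiseSwitch(rep("no_tooth", 12), confirmRun = 3L)
  expect_equal(unique(layerLabels(out)), "lower_no_tooth")
  expect_true(all(is.na(boundaries(out))))
  expect_error(antiNoiseSwitch(character(0)), "empty")
})

test_that("labels not matching the next expected class never switch", {
  ## a long overlap run cannot be entered from lower_no_tooth
  lab <- c(rep("no_tooth", 3), rep("overlap", 5), rep("no_tooth", 2))
  out <- antiNoiseSwitch(lab, confirmRun = 3L)
  expect_equal(unique(layerLabels(out)), "lower_no_tooth")
})

test_that("a top-to-bottom stack labels consistently after flipping", {
  lab <- rep(c("no_tooth", "crown", "overlap", "crown", "no_tooth"), each = 4)
  up <- antiNoiseSwitch(lab, confirmRun = 3L)
  down <- antiNoiseSwitch(rev(lab), confirmRun = 3L,
                          scanDirection = "top_to_bottom")
  expect_equal(layerLabels(down), rev(layerLabels(up)))
})

test_that("layer state is monotone along the scan direction", {
  set.seed(99)
  for (rep in 1:50) {
    lab <- sample(classLabelNames(), 60, replace = TRUE)
    out <- antiNoiseSwitch(lab, confirmRun = 2L)
    st <- match(layerLabels(out), layerLabelNames())
    expect_true(all(diff(st) >= 0))
  }
})

test_that("noise bursts shorter than the confirm run never change labels", {
  set.seed(123)
  clean <- cleanRegionSequence()
  ref <- antiNoiseSwitch(clean$classLabels, confirmRun = 3L)
  expect_equal(layerLabels(ref), clean$layerLabels)
  for (trial in 1:100) {
    noisy <- corruptSequence(clean, confirmRun = 3L, nBursts = 3L)
    out <- antiNoiseSwitch(noisy, confirmRun = 3L)
    expect_equal(layerLabels(out), clean$layerLabels)
  }
})

test_that("key slices are the 10th and 10th-from-last of each crown region", {
  ll <- c(rep("lower_no_tooth", 19), rep("lower_crown", 40),
          rep("overlap", 10), rep("upper_crown", 20),
          rep("upper_no_tooth", 11))
  labeling <- antiNoiseSwitch(
    c("no_tooth", "crown", "overlap", "crown",
      "no_tooth")[match(ll, layerLabelNames())], confirmRun = 1L)
  expect_equal(layerLabels(labeling), ll)
  keys <- selectKeySlices(labeling)
  expect_equal(keys$slice[keys$jaw == "lower"], c(29L, 50L))
  ## upper crown is 70..89 (length 20): offsets 9 and 10 from each end
  expect_equal(keys$slice[keys$jaw == "upper"], c(79L, 80L))
})

test_that("short crown regions clamp and deduplicate key slices", {
  mk <- function(lens) {
    ll <- rep(layerLabelNames(), lens)
    antiNoiseSwitch(c("no_tooth", "crown", "overlap", "crown",
                      "no_tooth")[match(ll, layerLabelNames())],
                    confirmRun = 1L)
  }
  expect_warning(keys <- selectKeySlices(mk(c(2L, 5L, 2L, 25L, 2L))),
                 "clamped")
  low <- keys$slice[keys$jaw == "lower"]
  expect_equal(low, c(3L, 7L))       # offsets 0 and 4 into slices 3..7
  ## a 19-slice region collapses to a single key slice
  expect_warning(keys2 <- selectKeySlices(mk(c(1L, 19L, 1L, 25L, 2L))))
  expect_equal(sum(keys2$jaw == "lower"), 1L)
  expect_equal(keys2$slice[keys2$jaw == "lower"], 11L)  # offset 9 into 2..20
})

test_that("an empty crown region is a hard error", {
  ll <- antiNoiseSwitch(rep("no_tooth", 10), confirmRun = 3L)
  expect_error(selectKeySlices(ll), "empty")
})

test_that("layer labeling serializes to JSON and back", {
  lab <- rep(c("no_tooth", "crown", "overlap", "crown", "no_tooth"), each = 5)
  out <- antiNoiseSwitch(lab, confirmRun = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  writeLayerLabeling(out, path)
  back <- readLayerLabeling(path)
  expect_equal(layerLabels(back), layerLabels(out))
  expect_equal(boundaries(back), boundaries(out))
})

test_that("classifier preprocessing normalizes and resizes", {
  img <- matrix(runif(32 * 48, 10, 200), 32, 48)
  out <- prepClassifierInput(img, size = 128L)
  expect_equal(dim(out), c(128L, 128L))
  expect_true(min(out) >= 0 && max(out) <= 1 + 1e-9)
})
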