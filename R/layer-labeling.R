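## Layer labeling: from per-slice 3-class labels to the monotone 5-state
## layer labels via the anti-noise switch, plus key-slice selection.
##
## The five z-regions, ordered along the scan direction (bottom to top), are
## lower_no_tooth, lower_crown, overlap, upper_crown, upper_no_tooth. A
## state advances only when the *next* state's expected class label is held
## for a confirmed run of consecutive slices, which suppresses isolated
## classifier errors: with per-slice error p, a spurious switch needs k
## consecutive errors, probability p^k.

## class label expected to *enter* each state (state 1 is the start state)
.enterClass <- c(NA, "crown", "overlap", "crown", "no_tooth")

#' Probability of k consecutive classification errors
#'
#' Under an independent-error model with per-slice error probability `p`,
#' the probability that `k` consecutive slices are all misclassified is
#' `p^k`. This is the quantity that bounds the rate of spurious layer
#' switches when the anti-noise switch requires a confirmed run of length
#' `k`: at 95% per-slice accuracy, two consecutive errors occur with
#' probability 0.25% and three with 0.0125%.
#'
#' @param perSliceError per-slice error probability in `[0, 1]`.
#' @param k run length, integer `>= 1`.
#' @return `perSliceError ^ k`.
#' @examples
#' consecutiveErrorProbability(0.05, 2) # 0.0025
#' @export
consecutiveErrorProbability <- function(perSliceError, k) {
  stopifnot(is.numeric(perSliceError), perSliceError >= 0, perSliceError <= 1,
            k >= 1, k == as.integer(k))
  perSliceError^k
}

#' Anti-noise switch: 3-class slice labels to 5-state layer labels
#'
#' Starts in `lower_no_tooth` and advances to the next of the five layer
#' states only at the first slice of a run of at least `confirmRun`
#' consecutive identical class labels equal to the next state's expected
#' class (`crown`, `overlap`, `crown`, `no_tooth` in order). Labels that do
#' not match the next expected class never trigger a switch and are treated
#' as noise; all slices between switches carry the current layer label.
#'
#' @param classLabels character vector of per-slice class labels
#'   (`"no_tooth"`, `"crown"`, `"overlap"`), ordered along `scanDirection`.
#' @param confirmRun total consecutive identical new-class labels required to
#'   confirm a switch, including the first changed slice (default 3: the
#'   changed slice plus two or more following slices).
#' @param scanDirection direction in which the input stack is ordered; a
#'   `"top_to_bottom"` stack is flipped internally before labeling and the
#'   outputs are mapped back to input order.
#' @return A [LayerLabeling-class].
#' @export
antiNoiseSwitch <- function(classLabels, confirmRun = 3L,
                            scanDirection = c("bottom_to_top",
                                              "top_to_bottom")) {
  scanDirection <- match.arg(scanDirection)
  if (length(classLabels) == 0L) stopfmt("empty class label sequence")
  if (!all(classLabels %in% classLabelNames()))
    stopfmt("invalid class labels: %s",
            paste(setdiff(classLabels, classLabelNames()), collapse = ", "))
  stopifnot(confirmRun >= 1L)
  flipped <- scanDirection == "top_to_bottom"
  lab <- if (flipped) rev(classLabels) else classLabels
  n <- length(lab)
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  state <- 1L
  states <- integer(n)
  bounds <- rep(NA_integer_, 4L)
  for (r in seq_along(runs$lengths)) {
    if (state < 5L && runs$values[r] == .enterClass[state + 1L] &&
        runs$lengths[r] >= confirmRun) {
      state <- state + 1L
      bounds[state - 1L] <- starts[r]
    }
    states[starts[r]:ends[r]] <- state
  }
  ## states within a run never change; fill forward between switches
  states <- cummax(states)
  if (flipped) {
    states <- rev(states)
    ## after reversal a region's first slice is its former last; recompute
    bounds <- vapply(2:5, function(s) {
      i <- which(states == s); if (length(i)) min(i) else NA_integer_
    }, 1L)
  }
  new("LayerLabeling", classLabels = classLabels,
      layerLabels = layerLabelNames()[states], boundaries = bounds)
}

#' Select the key slices of both crown regions
#'
#' From each crown region the 10th and the 10th-from-last slice are
#' selected; detection runs only on these key slices and their boxes are
#' shared with neighbouring slices. Regions shorter than 20 slices clamp
#' the offsets into the region (with a warning) and duplicates collapse.
#'
#' @param labeling a [LayerLabeling-class] with nonempty crown regions.
#' @return A data.frame with columns `slice` (sorted unique indices) and
#'   `jaw`.
#' @export
selectKeySlices <- function(labeling) {
  ll <- layerLabels(labeling)
  picks <- lapply(c(lower = "lower_crown", upper = "upper_crown"),
                  function(region) {
    idx <- which(ll == region)
    if (!length(idx))
      stopfmt(paste0("crown region '%s' is empty; supply a manual region ",
                     "override or relabel the stack"), region)
    n <- length(idx)
    if (n < 20L)
      warnfmt("crown region '%s' has only %d slices; key-slice offsets clamped",
              region, n)
    unique(idx[c(min(10L, n), max(n - 9L, 1L))])
  })
  out <- data.frame(
    slice = c(picks$lower, picks$upper),
    jaw = rep(c("lower", "upper"), c(length(picks$lower),
                                     length(picks$upper))),
    stringsAsFactors = FALSE)
  out[order(out$slice), , drop = FALSE]
}

#' Apply a slice classifier to every slice of a stack
#'
#' A slice classifier is a function `function(image, index)` returning one
#' of the three class labels. Unless `prep = FALSE`, each slice is first
#' normalized to `[0, 1]` by the stack-wide min-max range and resized to
#' `size x size` with bilinear interpolation, the preprocessing contract the
#' classifier input expects.
#'
#' @param stack a [SliceStack-class].
#' @param classifier a classifier function (see e.g. [oracleClassifier()]).
#' @param prep logical; apply preprocessing before the call.
#' @param size classifier input side length in pixels.
#' @return Character vector of class labels, one per slice.
#' @export
classifyStack <- function(stack, classifier, prep = TRUE, size = 128L) {
  rng <- range(vapply(stack@slices, range, double(2)))
  vapply(seq_len(nSlices(stack)), function(i) {
    img <- getSlice(stack, i)
    if (prep) img <- prepClassifierInput(img, size = size, range = rng)
    lbl <- classifier(img, i)
    if (!lbl %in% classLabelNames())
      stopfmt("classifier returned invalid label '%s' for slice %d", lbl, i)
    lbl
  }, character(1))
}

#' Classifier input preprocessing
#'
#' Min-max normalizes intensities to `[0, 1]` (by the supplied range, or the
#' image's own range) and resizes to `size x size` with bilinear
#' interpolation.
#'
#' @param image numeric matrix.
#' @param size output side length.
#' @param range optional `c(min, max)` used for normalization (e.g. the
#'   whole stack's range).
#' @return A `size x size` numeric matrix in `[0, 1]`.
#' @export
prepClassifierInput <- function(image, size = 128L, range = NULL) {
  rng <- range %||% base::range(image)
  den <- rng[2] - rng[1]
  m <- if (den > 0) (image - rng[1]) / den else image * 0
  out <- EBImage::resize(EBImage::Image(m), w = size, h = size,
                         filter = "bilinear")
  EBImage::imageData(out)
}

#' Serialize / read a LayerLabeling as JSON
#' @param labeling a [LayerLabeling-class].
#' @param path output (input) file path.
#' @return `writeLayerLabeling`: the path, invisibly; `readLayerLabeling`:
#'   a [LayerLabeling-class].
#' @export
writeLayerLabeling <- function(labeling, path) {
  jsonlite::write_json(
    list(class_labels = classLabels(labeling),
         layer_labels = layerLabels(labeling),
         boundaries = boundaries(labeling)),
    path, auto_unbox = FALSE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname writeLayerLabeling
#' @export
readLayerLabeling <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- as.integer(obj$boundaries)
  length(b) <- 4L
  new("LayerLabeling", classLabels = as.character(obj$class_labels),
      layerLabels = as.character(obj$layer_labels), boundaries = b)
}
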