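## Hierarchical detection on key slices: first the main dental area (the
## tight box around all teeth), then the five anatomical block boxes inside
## it. Detectors are pluggable: a detector is a function
##
##   function(image, target, index = NULL, roi = NULL)
##
## with target one of "main_area"/"blocks", returning a data.frame with
## columns label, L, T, R, B, score (full-image coordinates, scores in
## [0, 1]). `index` is the slice index (used by truth-backed oracle
## detectors), `roi` an optional box restricting the search.

#' Grid cells per side of a single-stage detector
#'
#' Single-stage detectors divide their square input into a regular grid of
#' stride-sized cells (e.g. a 416-px input at 32-px stride gives 13 x 13
#' cells).
#'
#' @param inputSize input side length in pixels.
#' @param stride cell side length in pixels; must divide `inputSize`.
#' @return Integer number of cells per side.
#' @examples
#' gridCells(416, 32) # 13
#' @export
gridCells <- function(inputSize, stride) {
  stopifnot(inputSize >= 1, stride >= 1)
  if (inputSize %% stride != 0)
    stopfmt("input size %d is not divisible by stride %d", inputSize, stride)
  as.integer(inputSize %/% stride)
}

#' Detect the main dental area on a slice
#'
#' Runs the detector with target `"main_area"` and returns the
#' highest-scoring detection at or above the score threshold, clamped to the
#' image bounds.
#'
#' @param image numeric matrix (one slice).
#' @param detector a detector function (see e.g. [oracleDetector()],
#'   [heuristicDetector()]).
#' @param scoreThreshold minimum score for a positive detection.
#' @param index slice index passed through to the detector.
#' @return A box (see [Box()]).
#' @export
detectMainArea <- function(image, detector, scoreThreshold = 0.5,
                           index = NULL) {
  det <- detector(image, "main_area", index = index)
  det <- det[det$label == "main_area", , drop = FALSE]
  if (!nrow(det))
    stopfmt("no main-area detection on slice %s", index %||% "?")
  best <- which.max(det$score)
  if (det$score[best] < scoreThreshold)
    stopfmt("no main-area detection above threshold %.2f (best score %.3f)",
            scoreThreshold, det$score[best])
  clampBox(Box(det$L[best], det$T[best], det$R[best], det$B[best]),
           ncol(image), nrow(image))
}

#' Detect the five block boxes inside the main area
#'
#' Runs the detector with target `"blocks"` restricted to the main-area
#' crop. For each block label the highest-scoring candidate wins; blocks
#' with no candidate above threshold are reported as missing rather than
#' extrapolated.
#'
#' @inheritParams detectMainArea
#' @param mainArea the main-area box from [detectMainArea()].
#' @param jaw jaw of the slice (`"lower"`/`"upper"`), attached to the result.
#' @return A list with `boxes` (data.frame jaw, block, L, T, R, B, score)
#'   and `missing` (character vector of undetected block names).
#' @export
detectBlocks <- function(image, mainArea, detector, jaw,
                         scoreThreshold = 0.5, index = NULL) {
  jaw <- match.arg(jaw, c("lower", "upper"))
  det <- detector(image, "blocks", index = index, roi = asBox(mainArea))
  det <- det[det$label %in% blockNames() & det$score >= scoreThreshold, ,
             drop = FALSE]
  if (!nrow(det))
    stopfmt("no block detections on slice %s", index %||% "?")
  rows <- lapply(blockNames(), function(bn) {
    cand <- det[det$label == bn, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    best <- cand[which.max(cand$score), , drop = FALSE]
    b <- clampBox(Box(best$L, best$T, best$R, best$B),
                  ncol(image), nrow(image))
    data.frame(jaw = jaw, block = bn, L = b[["L"]], T = b[["T"]],
               R = b[["R"]], B = b[["B"]], score = best$score,
               stringsAsFactors = FALSE)
  })
  boxes <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  list(boxes = boxes, missing = setdiff(blockNames(), boxes$block))
}

## ---------------------------------------------------------------------------
## Heuristic reference backend: lets the whole pipeline run on phantom-like
## images (bright teeth on a dark background) without any trained model.

## Otsu threshold of a value vector (256-bin between-class variance
## maximizer). EBImage::otsu only accepts whole images, so the second-stage
## threshold on the foreground subset is computed here.
otsuValue <- function(v, levels = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(
    floor((v - rng[1]) / diff(rng) * levels) + 1L, 1L), levels), levels)
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(levels))
  muT <- mu[levels]
  between <- (muT * w - mu * w[levels])^2 / (w * (w[levels] - w))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  rng[1] + k / levels * diff(rng)
}

## Connected bright components of a normalized [0,1] image. Two-level
## thresholding: a first Otsu cut separates tissue from background, a second
## one within the foreground isolates the teeth from the (dimmer) jaw bone.
brightComponents <- function(norm, minArea = 10L) {
  t1 <- EBImage::otsu(EBImage::Image(norm))
  fg <- norm[norm > t1]
  if (!length(fg)) return(NULL)
  ## apply the second cut only when the foreground is genuinely bimodal
  ## (bone band + teeth); if the first cut already isolated the teeth, a
  ## second Otsu would just split their noise
  t2 <- otsuValue(fg)
  lo <- mean(fg[fg <= t2]); hi <- mean(fg[fg > t2])
  thr <- if (is.finite(lo) && is.finite(hi) && hi - lo > 0.2) t2 else t1
  mask <- norm > thr
  if (!any(mask)) return(NULL)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  comps <- lapply(seq_len(max(lab)), function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) < minArea) return(NULL)
    ## pixel (row i, col j) spans [j-1, j] x [i-1, i] in continuous coords
    data.frame(cx = mean(px[, 2]) - 0.5, cy = mean(px[, 1]) - 0.5,
               L = min(px[, 2]) - 1, T = min(px[, 1]) - 1,
               R = max(px[, 2]), B = max(px[, 1]), area = nrow(px))
  })
  comps <- comps[!vapply(comps, is.null, TRUE)]
  if (!length(comps)) return(NULL)
  do.call(rbind, comps)
}

## Arc-length position of component centres along a parabola fitted to them,
## normalized to [0, 1] from image-left to image-right.
archPositions <- function(comp) {
  fit <- stats::lm(cy ~ cx + I(cx^2), data = comp)
  xr <- range(comp$cx)
  xs <- seq(xr[1], xr[2], length.out = 512L)
  ys <- stats::predict(fit, data.frame(cx = xs))
  s <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  pos <- stats::approx(xs, s, xout = comp$cx, rule = 2)$y
  (pos - min(pos)) / max(max(pos) - min(pos), .Machine$double.eps)
}

#' Heuristic threshold-based block detector
#'
#' A reference detector backend that needs no training: teeth are segmented
#' by two-level Otsu thresholding and connected-component labeling, the
#' dental arch is fitted with a parabola, and components are grouped into
#' the five blocks by their arc-length position along the fitted arch
#' (3 + 3 + 4 + 3 + 3 teeth from image-left to image-right for a full
#' dentition). Intended for phantom-like images with bright teeth on a dark
#' background.
#'
#' @param chirality block naming convention, see [blockTeeth()].
#' @param minArea minimum component area in pixels.
#' @return A detector function usable with [detectMainArea()] and
#'   [detectBlocks()].
#' @export
heuristicDetector <- function(chirality = c("radiological", "anatomical"),
                              minArea = 10L) {
  chirality <- match.arg(chirality)
  ## block order from image-left to image-right and their tooth-slot cuts
  ordBlocks <- c("right_molar", "right_canine_premolar", "incisors",
                 "left_canine_premolar", "left_molar")
  if (chirality == "anatomical") ordBlocks <- rev(ordBlocks)
  cuts <- c(2.5, 5.5, 9.5, 12.5) / 15
  function(image, target = c("main_area", "blocks"), index = NULL,
           roi = NULL) {
    target <- match.arg(target)
    rng <- range(image)
    norm <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
    offs <- c(0, 0)
    if (!is.null(roi) && target == "blocks") {
      roi <- clampBox(roi, ncol(image), nrow(image))
      rsel <- max(floor(roi[["T"]]), 0) + 1; rsel2 <- ceiling(roi[["B"]])
      csel <- max(floor(roi[["L"]]), 0) + 1; csel2 <- ceiling(roi[["R"]])
      norm <- norm[rsel:rsel2, csel:csel2, drop = FALSE]
      offs <- c(csel - 1, rsel - 1)   # (x, y) offset back to full image
    }
    comp <- brightComponents(norm, minArea = minArea)
    if (is.null(comp) || nrow(comp) < 3L)
      stopfmt("heuristic detector found %d component(s); need at least 3",
              if (is.null(comp)) 0L else nrow(comp))
    comp$cx <- comp$cx + offs[1]; comp$L <- comp$L + offs[1]
    comp$R <- comp$R + offs[1]
    comp$cy <- comp$cy + offs[2]; comp$T <- comp$T + offs[2]
    comp$B <- comp$B + offs[2]
    if (target == "main_area") {
      hull <- boxHull(dfBoxes(comp))
      return(data.frame(label = "main_area", L = hull[["L"]],
                        T = hull[["T"]], R = hull[["R"]], B = hull[["B"]],
                        score = 1, stringsAsFactors = FALSE))
    }
    pos <- archPositions(comp)
    grp <- ordBlocks[findInterval(pos, cuts) + 1L]
    rows <- lapply(unique(grp), function(g) {
      hull <- boxHull(dfBoxes(comp[grp == g, , drop = FALSE]))
      data.frame(label = g, L = hull[["L"]], T = hull[["T"]],
                 R = hull[["R"]], B = hull[["B"]], score = 1,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
}
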