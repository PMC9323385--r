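## Detection evaluation: greedy matching, precision/recall/F1, average
## precision and mAP, and the object inclusion ratio (OIR).

#' Match predictions against ground truth
#'
#' Predictions scoring below `scoreThreshold` are negatives. Positive
#' predictions are visited in descending score order; a prediction is a
#' true positive if some not-yet-matched ground-truth box with the same
#' label has IoU at least `iouThreshold` with it (the best such box is
#' consumed), otherwise a false positive. Ground-truth boxes left unmatched
#' are false negatives.
#'
#' @param pred data.frame of predictions: `label`, `L`, `T`, `R`, `B`,
#'   `score`.
#' @param truth data.frame of ground truth: `label`, `L`, `T`, `R`, `B`.
#' @param iouThreshold IoU threshold in `(0, 1]`.
#' @param scoreThreshold score threshold for a positive prediction.
#' @return A list with counts `nTp`, `nFp`, `nFn` and a `matches`
#'   data.frame (`predRow`, `truthRow`, `iou`).
#' @export
matchDetections <- function(pred, truth, iouThreshold = 0.5,
                            scoreThreshold = 0.5) {
  if (!is.numeric(iouThreshold) || iouThreshold <= 0 || iouThreshold > 1)
    stopfmt("iouThreshold must lie in (0, 1]")
  pos <- which(pred$score >= scoreThreshold)
  pos <- pos[order(-pred$score[pos])]
  matched <- rep(FALSE, nrow(truth))
  nTp <- 0L; nFp <- 0L
  matches <- list()
  for (i in pos) {
    cand <- which(!matched & truth$label == pred$label[i])
    if (length(cand)) {
      ious <- vapply(cand, function(j)
        boxIoU(Box(pred$L[i], pred$T[i], pred$R[i], pred$B[i]),
               Box(truth$L[j], truth$T[j], truth$R[j], truth$B[j])), 0)
      best <- which.max(ious)
      if (ious[best] >= iouThreshold) {
        matched[cand[best]] <- TRUE
        nTp <- nTp + 1L
        matches[[length(matches) + 1L]] <-
          data.frame(predRow = i, truthRow = cand[best], iou = ious[best])
        next
      }
    }
    nFp <- nFp + 1L
  }
  list(nTp = nTp, nFp = nFp, nFn = sum(!matched),
       matches = if (length(matches)) do.call(rbind, matches)
                 else data.frame(predRow = integer(), truthRow = integer(),
                                 iou = double()))
}

#' Precision, recall and F1 from match counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`; any 0/0 case returns 0.
#'
#' @param m a match result from [matchDetections()], or a list with `nTp`,
#'   `nFp`, `nFn`.
#' @return Named numeric `c(precision, recall, f1)`.
#' @export
precisionRecallF1 <- function(m) {
  safe <- function(num, den) if (den > 0) num / den else 0
  p <- safe(m$nTp, m$nTp + m$nFp)
  r <- safe(m$nTp, m$nTp + m$nFn)
  c(precision = p, recall = r, f1 = f1Score(p, r))
}

#' F1 score from precision and recall
#' @param precision,recall values in `[0, 1]`.
#' @return The harmonic mean `2 P R / (P + R)`, 0 when `P + R = 0`.
#' @export
f1Score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

## rank predictions of one label across images and flag TP/FP by per-image
## greedy matching in global rank order
.rankedFlags <- function(pred, truth, iouThreshold) {
  ord <- order(-pred$score)
  matched <- rep(FALSE, nrow(truth))
  tp <- logical(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    cand <- which(!matched & truth$image == pred$image[i])
    if (length(cand)) {
      ious <- vapply(cand, function(j)
        boxIoU(Box(pred$L[i], pred$T[i], pred$R[i], pred$B[i]),
               Box(truth$L[j], truth$T[j], truth$R[j], truth$B[j])), 0)
      best <- which.max(ious)
      if (ious[best] >= iouThreshold) {
        matched[cand[best]] <- TRUE
        tp[k] <- TRUE
      }
    }
  }
  tp
}

#' Average precision of one label; mean average precision over labels
#'
#' Predictions of the label are ranked by score across all images; the
#' precision-recall curve is swept over the ranks (greedy per-image
#' matching) and integrated. `interp = "all"` uses all-point interpolation
#' (the area under the precision envelope); `"11point"` averages the
#' envelope at recalls 0, 0.1, ..., 1. `meanAveragePrecision` averages AP
#' over all labels with at least one ground-truth box.
#'
#' @param pred data.frame: `image`, `label`, `L`, `T`, `R`, `B`, `score`
#'   (an `image` column of 1s is assumed when absent).
#' @param truth data.frame: `image`, `label`, `L`, `T`, `R`, `B`.
#' @param label the label to evaluate.
#' @param iouThreshold IoU threshold for a correct detection.
#' @param interp interpolation variant.
#' @return A number in `[0, 1]`.
#' @export
averagePrecision <- function(pred, truth, label, iouThreshold = 0.5,
                             interp = c("all", "11point")) {
  interp <- match.arg(interp)
  if (is.null(pred$image)) pred$image <- 1L
  if (is.null(truth$image)) truth$image <- 1L
  truth <- truth[truth$label == label, , drop = FALSE]
  if (!nrow(truth)) stopfmt("no ground-truth boxes for label '%s'", label)
  pred <- pred[pred$label == label, , drop = FALSE]
  if (!nrow(pred)) return(0)
  tp <- .rankedFlags(pred, truth, iouThreshold)
  ctp <- cumsum(tp)
  rec <- ctp / nrow(truth)
  prec <- ctp / seq_along(tp)
  if (interp == "11point") {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      sel <- rec >= r - 1e-12
      if (any(sel)) max(prec[sel]) else 0
    }, 0))
  } else {
    mrec <- c(0, rec, 1)
    mpre <- c(0, prec, 0)
    mpre <- rev(cummax(rev(mpre)))   # precision envelope
    idx <- which(diff(mrec) > 0)
    sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L])
  }
}

#' @rdname averagePrecision
#' @export
meanAveragePrecision <- function(pred, truth, iouThreshold = 0.5,
                                 interp = c("all", "11point")) {
  interp <- match.arg(interp)
  labels <- unique(truth$label)
  if (!length(labels)) stopfmt("no ground-truth boxes; mAP undefined")
  mean(vapply(labels, function(l)
    averagePrecision(pred, truth, l, iouThreshold, interp), 0))
}

#' Object inclusion ratio
#'
#' Fraction of an object's true pixel area covered by its detected box:
#' `OIR = |A ∩ D| / |A|` where `A` is the object's binary mask and `D` the
#' rasterized detected box. A pixel at row `i`, column `j` (1-based) lies
#' inside the box iff its centre does: `L <= j - 0.5 < R` and
#' `T <= i - 0.5 < B`, consistent with the half-open box area convention.
#'
#' @param mask binary (logical or 0/1) matrix; must contain at least one
#'   true pixel.
#' @param box the detected box for the object.
#' @return A number in `[0, 1]`.
#' @export
oir <- function(mask, box) {
  box <- asBox(box)
  nm <- sum(mask != 0)
  if (nm == 0)
    stopfmt("empty object mask (flag the tooth as missing to skip it)")
  rows <- which(box[["T"]] <= seq_len(nrow(mask)) - 0.5 &
                seq_len(nrow(mask)) - 0.5 < box[["B"]])
  cols <- which(box[["L"]] <= seq_len(ncol(mask)) - 0.5 &
                seq_len(ncol(mask)) - 0.5 < box[["R"]])
  if (!length(rows) || !length(cols)) return(0)
  sum(mask[rows, cols, drop = FALSE] != 0) / nm
}

#' Mean OIR of one image
#'
#' Averages [oir()] over the teeth of one image; teeth flagged missing are
#' skipped.
#'
#' @param items list of per-tooth lists with fields `mask`, `box` and
#'   optional `missing` (logical).
#' @return Mean OIR over the non-missing teeth (`NA` if all are missing).
#' @export
perImageOir <- function(items) {
  vals <- vapply(items, function(it) {
    if (isTRUE(it$missing)) return(NA_real_)
    oir(it$mask, it$box)
  }, 0)
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Full evaluation report for labeled detections
#'
#' Convenience wrapper combining [matchDetections()],
#' [precisionRecallF1()] and [meanAveragePrecision()] over annotation
#' data.frames (the `slice` column, when present, is the image id).
#'
#' @inheritParams matchDetections
#' @param apInterp AP interpolation variant, see [averagePrecision()].
#' @return A list: `precision`, `recall`, `f1`, `mAP`, `counts`, `perLabel`.
#' @export
evaluateDetections <- function(pred, truth, iouThreshold = 0.5,
                               scoreThreshold = 0.5,
                               apInterp = c("all", "11point")) {
  apInterp <- match.arg(apInterp)
  pred$image <- pred$image %||% pred$slice %||% 1L
  truth$image <- truth$image %||% truth$slice %||% 1L
  ## match within each image, then pool the counts
  imgs <- unique(c(pred$image, truth$image))
  m <- list(nTp = 0L, nFp = 0L, nFn = 0L)
  for (im in imgs) {
    mi <- matchDetections(pred[pred$image == im, , drop = FALSE],
                          truth[truth$image == im, , drop = FALSE],
                          iouThreshold, scoreThreshold)
    m$nTp <- m$nTp + mi$nTp; m$nFp <- m$nFp + mi$nFp; m$nFn <- m$nFn + mi$nFn
  }
  prf <- precisionRecallF1(m)
  labels <- sort(unique(truth$label))
  perLabel <- data.frame(
    label = labels,
    ap = vapply(labels, function(l)
      averagePrecision(pred, truth, l, iouThreshold, apInterp), 0),
    nTruth = vapply(labels, function(l) sum(truth$label == l), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(precision = unname(prf["precision"]), recall = unname(prf["recall"]),
       f1 = unname(prf["f1"]), mAP = mean(perLabel$ap),
       counts = m[c("nTp", "nFp", "nFn")], perLabel = perLabel)
}
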