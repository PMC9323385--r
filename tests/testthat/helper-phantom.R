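## Shared fixtures: a cached default phantom and calibration-sample
## builders, all generated in code.

phantomFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generatePhantom(phantomConfig())
    cache
  }
})

## Calibration samples (block box + per-tooth truth boxes) from phantom
## ground truth on the given slices.
calibrationSamples <- function(truth, slices) {
  truthCalibrationSamples(truth, slices)
}

## A clean 5-region class-label sequence and its expected layer labels.
cleanRegionSequence <- function(lengths = c(10L, 10L, 10L, 10L, 10L)) {
  classes <- c("no_tooth", "crown", "overlap", "crown", "no_tooth")
  list(classLabels = rep(classes, lengths),
       layerLabels = rep(layerLabelNames(), lengths),
       lengths = lengths)
}

## Corrupt a clean sequence with noise bursts of length < confirmRun, at
## least confirmRun slices away from every region boundary and from each
## other, with arbitrary replacement labels.
corruptSequence <- function(clean, confirmRun = 3L, nBursts = 2L) {
  lab <- clean$classLabels
  bounds <- cumsum(clean$lengths)
  forbidden <- unique(unlist(lapply(c(0L, bounds), function(b)
    (b - confirmRun + 1L):(b + confirmRun))))
  allowed <- setdiff(seq_along(lab), forbidden)
  placed <- integer()
  for (k in seq_len(nBursts)) {
    len <- sample.int(confirmRun - 1L, 1L)
    ok <- allowed[vapply(allowed, function(p) {
      span <- p:(p + len - 1L)
      all(span %in% allowed) &&
        (!length(placed) || min(abs(outer(span, placed, "-"))) > confirmRun)
    }, TRUE)]
    if (!length(ok)) next
    p <- sample(ok, 1L)
    span <- p:(p + len - 1L)
    lab[span] <- sample(classLabelNames(), len, replace = TRUE)
    placed <- c(placed, span)
  }
  lab
}

## Independent all-point AP oracle: re-derives the PR curve by rematching
## every rank prefix from scratch and integrating over a recall grid.
bruteForceAP <- function(pred, truth, iouThreshold = 0.5) {
  ord <- order(-pred$score)
  nT <- nrow(truth)
  prec <- double(length(ord)); rec <- double(length(ord))
  for (k in seq_along(ord)) {
    sub <- pred[ord[seq_len(k)], , drop = FALSE]
    matched <- rep(FALSE, nT)
    tp <- 0L
    for (i in seq_len(nrow(sub))) {
      cand <- which(!matched)
      if (!length(cand)) next
      ious <- vapply(cand, function(j)
        boxIoU(Box(sub$L[i], sub$T[i], sub$R[i], sub$B[i]),
               Box(truth$L[j], truth$T[j], truth$R[j], truth$B[j])), 0)
      if (max(ious) >= iouThreshold) {
        matched[cand[which.max(ious)]] <- TRUE
        tp <- tp + 1L
      }
    }
    prec[k] <- tp / k
    rec[k] <- tp / nT
  }
  mean(vapply(seq_len(nT) / nT, function(r) {
    sel <- rec >= r - 1e-12
    if (any(sel)) max(prec[sel]) else 0
  }, 0))
}
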