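## Proportion-based division of block boxes into per-tooth boxes.
##
## A point inside a box is addressed by its position ratio
## lambda = (x - x1) / (x2 - x), i.e. x = (x1 + lambda * x2) / (1 + lambda).
## Each tooth carries a lambda pair for its box's left-top corner and one
## for its right-bottom corner, relative to the block's detected box. The
## lambda domain is the closed interval [0, Inf]: lambda = 0 places the
## point at x1, lambda = Inf at x2 (both are well-defined limits of the
## formula and are needed for teeth at the edges of their block).

#' Proportionally located point inside a box
#'
#' Evaluates `x = (x1 + lambda_x * x2) / (1 + lambda_x)` with `x1 = L`,
#' `x2 = R` (and analogously for y with `T`, `B`), where `lambda` is the
#' position ratio `(x - x1) / (x2 - x)`.
#'
#' @param box a box from [Box()].
#' @param lx,ly lambda position ratios in `[0, Inf]`.
#' @return Named numeric `c(x, y)`.
#' @examples
#' proportionalPoint(Box(0, 0, 1, 1), 1, 1)        # midpoint
#' proportionalPoint(Box(0, 0, 1, 1), 1/6, 2/9)    # (1/7, 2/11)
#' @export
proportionalPoint <- function(box, lx, ly) {
  box <- asBox(box)
  stopifnot(lx >= 0, ly >= 0)
  x <- if (is.infinite(lx)) box[["R"]]
       else (box[["L"]] + lx * box[["R"]]) / (1 + lx)
  y <- if (is.infinite(ly)) box[["B"]]
       else (box[["T"]] + ly * box[["B"]]) / (1 + ly)
  c(x = x, y = y)
}

#' Build a proportion entry
#' @param lt,rb lambda pairs `c(lx, ly)` for the left-top and right-bottom
#'   corners.
#' @param enlarge fractional per-side enlargement applied after the
#'   proportional corners.
#' @param affine optional 4x2 matrix of exact affine coefficients
#'   (rows L, T, R, B; row L applies to `(L0, R0)`, row T to `(T0, B0)`,
#'   etc.). When present it overrides the lambda path and no enlargement is
#'   applied (published coefficient sets fold the enlargement in).
#' @return A proportion entry list.
#' @export
toothProportion <- function(lt, rb, enlarge = 0.05, affine = NULL) {
  stopifnot(length(lt) == 2L, length(rb) == 2L, all(lt >= 0), all(rb >= 0),
            enlarge >= 0)
  if (!is.null(affine)) {
    affine <- matrix(as.numeric(affine), 4L, 2L)
  }
  list(lt = as.numeric(lt), rb = as.numeric(rb),
       enlarge = as.numeric(enlarge), affine = affine)
}

#' The published tooth-45 proportion entry
#'
#' The block-to-tooth mapping for the lower-right second premolar (FDI 45)
#' in exact affine form: `L = 0.83 L0 + 0.17 R0`, `T = 0.72 T0 + 0.28 B0`,
#' `R = 0.17 L0 + 0.83 R0`, `B = 0.28 T0 + 0.72 B0` on the block box
#' `(L0, T0, R0, B0)`. The lambda fields carry the corresponding raw
#' position ratios (1/6, 2/9) and (5/6, 4/9); the affine coefficients
#' differ slightly from their raw evaluation because the published set
#' folds in a small enlargement, so the affine form takes precedence.
#'
#' @return A proportion entry (see [toothProportion()]).
#' @export
tooth45Proportion <- function() {
  toothProportion(lt = c(1 / 6, 2 / 9), rb = c(5 / 6, 4 / 9), enlarge = 0,
                  affine = rbind(c(0.83, 0.17),   # L on (L0, R0)
                                 c(0.72, 0.28),   # T on (T0, B0)
                                 c(0.17, 0.83),   # R on (L0, R0)
                                 c(0.28, 0.72)))  # B on (T0, B0)
}

#' Tooth box from a block box
#'
#' Applies a proportion entry to a detected block box: the tooth box corners
#' come from [proportionalPoint()] on the `lt` and `rb` lambda pairs,
#' followed by symmetric enlargement by the entry's `enlarge` fraction of
#' the width/height per side, clamped to the image when bounds are given.
#' Entries with an `affine` matrix evaluate it exactly instead.
#'
#' @param blockBox the block's detected box.
#' @param prop a proportion entry (see [toothProportion()]).
#' @param imageSize optional `c(width, height)` to clamp against.
#' @return A box (see [Box()]).
#' @examples
#' toothBoxFromBlock(Box(0, 0, 1, 1), tooth45Proportion())
#' @export
toothBoxFromBlock <- function(blockBox, prop, imageSize = NULL) {
  blockBox <- asBox(blockBox)
  if (boxArea(blockBox) == 0)
    warnfmt("degenerate (zero-area) block box; returning a degenerate tooth box")
  if (!is.null(prop$affine)) {
    A <- prop$affine
    b <- Box(A[1, 1] * blockBox[["L"]] + A[1, 2] * blockBox[["R"]],
             A[2, 1] * blockBox[["T"]] + A[2, 2] * blockBox[["B"]],
             A[3, 1] * blockBox[["L"]] + A[3, 2] * blockBox[["R"]],
             A[4, 1] * blockBox[["T"]] + A[4, 2] * blockBox[["B"]])
  } else {
    lt <- proportionalPoint(blockBox, prop$lt[1], prop$lt[2])
    rb <- proportionalPoint(blockBox, prop$rb[1], prop$rb[2])
    b <- enlargeBox(Box(lt[["x"]], lt[["y"]], rb[["x"]], rb[["y"]]),
                    prop$enlarge)
  }
  if (!is.null(imageSize)) b <- clampBox(b, imageSize[1], imageSize[2])
  b
}

#' Divide a block box into per-tooth boxes
#'
#' Generates one FDI-labeled box per non-missing tooth of the block. Each
#' tooth's box depends only on the block box and its own table entry, so
#' skipping a missing tooth never shifts its neighbours.
#'
#' @param blockBox the block's detected box.
#' @param jaw,block block identity, see [blockTeeth()].
#' @param table a [LambdaTable-class] covering the block's teeth.
#' @param missing integer vector of absent FDI codes to skip.
#' @param chirality see [blockTeeth()].
#' @param imageSize optional clamp bounds `c(width, height)`.
#' @param enlarge optional override of every entry's enlargement fraction.
#' @return A data.frame with columns `tooth`, `L`, `T`, `R`, `B`.
#' @export
divideBlock <- function(blockBox, jaw, block, table, missing = integer(),
                        chirality = c("radiological", "anatomical"),
                        imageSize = NULL, enlarge = NULL) {
  chirality <- match.arg(chirality)
  teeth <- blockTeeth(jaw, block, chirality)
  teeth <- setdiff(teeth, as.integer(missing))
  rows <- lapply(teeth, function(code) {
    prop <- lambdaEntry(table, code)
    if (!is.null(enlarge) && is.null(prop$affine)) prop$enlarge <- enlarge
    b <- toothBoxFromBlock(blockBox, prop, imageSize = imageSize)
    data.frame(tooth = code, L = b[["L"]], T = b[["T"]], R = b[["R"]],
               B = b[["B"]], stringsAsFactors = FALSE)
  })
  if (!length(rows)) return(emptyToothBoxes())
  do.call(rbind, rows)
}

## lambda value for the point at fraction f of the interval: f = l/(1+l)
.fracToLambda <- function(f) ifelse(f >= 1, Inf, f / (1 - f))

#' Default (pre-calibration) lambda table
#'
#' Covers all 32 teeth: within each block the teeth divide the block
#' uniformly along its left-right extent (the k-th of n teeth spans width
#' fractions `[(k-1)/n, k/n]` in image order), and vertically they span the
#' lambda range (2/9, 4/9) of the published tooth-45 example, mirrored for
#' the upper jaw. The published tooth-45 affine entry overrides its slot.
#' This table is an initialization; [calibrateLambdas()] refines it against
#' ground truth.
#'
#' @param enlarge per-side enlargement fraction stored on every entry.
#' @param chirality see [blockTeeth()].
#' @return A [LambdaTable-class].
#' @export
defaultLambdaTable <- function(enlarge = 0.05,
                               chirality = c("radiological", "anatomical")) {
  chirality <- match.arg(chirality)
  entries <- list()
  for (jaw in c("upper", "lower")) {
    ## vertical lambda range from the tooth-45 example, mirrored per jaw
    yl <- if (jaw == "lower") c(2 / 9, 4 / 9)
          else 1 / rev(c(2 / 9, 4 / 9))   # mirrored fractions: f' = 1 - f
    for (block in blockNames()) {
      teeth <- blockTeeth(jaw, block, chirality)
      n <- length(teeth)
      for (k in seq_len(n)) {
        entries[[as.character(teeth[k])]] <- toothProportion(
          lt = c(.fracToLambda((k - 1) / n), yl[1]),
          rb = c(.fracToLambda(k / n), yl[2]),
          enlarge = enlarge)
      }
    }
  }
  e45 <- tooth45Proportion()
  e45$enlarge <- enlarge
  entries[["45"]] <- e45
  new("LambdaTable", entries = entries)
}

#' Write / read a LambdaTable as YAML
#'
#' One YAML document keyed by FDI code with fields
#' `{lt: [lx, ly], rb: [lx, ly], enlarge: f}` and an optional
#' `affine: [[aL,bL],[aT,bT],[aR,bR],[aB,bB]]` for exact coefficient sets.
#'
#' @param table a [LambdaTable-class].
#' @param path file path.
#' @return `writeLambdaTable`: the path, invisibly; `readLambdaTable`: a
#'   [LambdaTable-class].
#' @export
writeLambdaTable <- function(table, path) {
  out <- lapply(table@entries, function(e) {
    r <- list(lt = e$lt, rb = e$rb, enlarge = e$enlarge)
    if (!is.null(e$affine))
      r$affine <- lapply(seq_len(4L), function(i) as.numeric(e$affine[i, ]))
    r
  })
  writeLines(yaml::as.yaml(out, precision = 15L), path)
  invisible(path)
}

#' @rdname writeLambdaTable
#' @export
readLambdaTable <- function(path) {
  raw <- yaml::read_yaml(path)
  entries <- lapply(raw, function(e) {
    toothProportion(lt = as.numeric(unlist(e$lt)),
                    rb = as.numeric(unlist(e$rb)),
                    enlarge = as.numeric(e$enlarge),
                    affine = if (!is.null(e$affine))
                      do.call(rbind, lapply(e$affine, as.numeric)))
  })
  new("LambdaTable", entries = entries)
}

#' Calibrate lambda values against ground-truth tooth boxes
#'
#' Per-tooth derivative-free local search: coordinate descent with a
#' shrinking step on the four lambda values of each entry, maximizing the
#' mean IoU between generated and ground-truth tooth boxes over the
#' calibration samples. Stops once the mean IoU over all covered teeth
#' reaches `targetMeanIou` (the published calibration criterion is 0.85) or
#' the step falls below `minStep`. Entries reached by calibration lose any
#' affine override (the lambdas now carry the geometry). If the target
#' cannot be reached the best table found is returned with a warning.
#'
#' @param samples list of calibration samples; each sample is a list with
#'   `jaw`, `block`, `blockBox` (a [Box()]) and `truth` (named list mapping
#'   FDI code to the ground-truth tooth box).
#' @param init initial [LambdaTable-class].
#' @param targetMeanIou stopping target for the mean IoU (default 0.85).
#' @param minStep step-size convergence tolerance.
#' @return A list with `table` (the calibrated [LambdaTable-class]) and
#'   `meanIou` (achieved mean IoU over all calibrated teeth).
#' @export
calibrateLambdas <- function(samples, init, targetMeanIou = 0.85,
                             minStep = 1e-4) {
  ## collect per-tooth calibration pairs
  pairs <- list()
  for (s in samples) {
    for (code in names(s$truth)) {
      pairs[[code]] <- c(pairs[[code]],
                         list(list(blockBox = asBox(s$blockBox),
                                   truthBox = asBox(s$truth[[code]]))))
    }
  }
  codes <- names(pairs)
  bad <- codes[!codes %in% as.character(coveredTeeth(init))]
  if (length(bad))
    stopfmt("lambda table has no entry for tooth %s", bad[1])
  table <- init
  ## objective: mean IoU, plus mean corner distance as a tie-breaker that
  ## guides the search toward contact while the IoU is still zero
  toothScore <- function(entry, ps) {
    ious <- double(length(ps)); dists <- double(length(ps))
    for (k in seq_along(ps)) {
      gen <- tryCatch(toothBoxFromBlock(ps[[k]]$blockBox, entry),
                      error = function(e) NULL)
      if (is.null(gen)) {   # inverted corners: worst possible candidate
        ious[k] <- 0; dists[k] <- Inf
      } else {
        ious[k] <- boxIoU(gen, ps[[k]]$truthBox)
        dists[k] <- sum(abs(gen - ps[[k]]$truthBox))
      }
    }
    c(iou = mean(ious), dist = mean(dists))
  }
  betterThan <- function(a, b) {
    if (a[["iou"]] > b[["iou"]] + 1e-12) return(TRUE)
    a[["iou"]] >= b[["iou"]] - 1e-12 && a[["dist"]] < b[["dist"]] - 1e-9
  }
  meanOver <- function(tab) {
    mean(vapply(codes, function(code)
      toothScore(lambdaEntry(tab, code), pairs[[code]])[["iou"]], 0))
  }
  for (code in codes) {
    entry <- lambdaEntry(table, code)
    entry$affine <- NULL   # calibration re-expresses the geometry in lambdas
    p <- c(entry$lt, entry$rb)
    p[!is.finite(p)] <- 1e4   # pull edge lambdas into the finite domain
    best <- toothScore(toothProportion(p[1:2], p[3:4], entry$enlarge),
                       pairs[[code]])
    delta <- 0.5
    while (delta >= minStep) {
      improved <- FALSE
      for (i in seq_len(4L)) {
        for (sgn in c(1, -1)) {
          cand <- p
          cand[i] <- max(p[i] + sgn * delta * max(p[i], 1), 0)
          val <- toothScore(toothProportion(cand[1:2], cand[3:4],
                                            entry$enlarge), pairs[[code]])
          if (betterThan(val, best)) {
            p <- cand; best <- val; improved <- TRUE
          }
        }
      }
      if (!improved) delta <- delta / 2
    }
    lambdaEntry(table, code) <- toothProportion(p[1:2], p[3:4], entry$enlarge)
    if (meanOver(table) >= targetMeanIou) break
  }
  achieved <- meanOver(table)
  if (achieved < targetMeanIou)
    warnfmt("lambda calibration reached mean IoU %.3f < target %.3f",
            achieved, targetMeanIou)
  list(table = table, meanIou = achieved)
}

#' Propagate key-slice tooth boxes to every slice
#'
#' Each slice receives the tooth-box set of the nearest key slice of its own
#' jaw (lower key slices serve the lower no-tooth and lower crown regions,
#' upper key slices the upper ones); slices in the overlap region receive
#' the union of the nearest lower-jaw and nearest upper-jaw sets. Distance
#' ties break toward the smaller slice index.
#'
#' @param keyBoxes named list mapping key slice index (as character) to a
#'   tooth-box data.frame (`tooth`, `L`, `T`, `R`, `B`).
#' @param labeling the stack's [LayerLabeling-class]; key slices must lie in
#'   its crown regions.
#' @return A list of tooth-box data.frames, one per slice.
#' @export
propagateBoxes <- function(keyBoxes, labeling) {
  if (!length(keyBoxes)) stopfmt("empty key-slice box set")
  keys <- as.integer(names(keyBoxes))
  ll <- layerLabels(labeling)
  keyJaw <- ll[keys]
  if (!all(keyJaw %in% c("lower_crown", "upper_crown")))
    stopfmt("key slices must lie in crown regions")
  lowKeys <- keys[keyJaw == "lower_crown"]
  upKeys <- keys[keyJaw == "upper_crown"]
  nearest <- function(s, ks) ks[order(abs(ks - s), ks)][1]
  lapply(seq_along(ll), function(s) {
    lab <- ll[s]
    if (lab == "overlap") {
      if (!length(lowKeys) || !length(upKeys))
        stopfmt("overlap region needs key slices of both jaws")
      rbind(keyBoxes[[as.character(nearest(s, lowKeys))]],
            keyBoxes[[as.character(nearest(s, upKeys))]])
    } else if (startsWith(lab, "lower")) {
      if (!length(lowKeys)) stopfmt("no lower-jaw key slices")
      keyBoxes[[as.character(nearest(s, lowKeys))]]
    } else {
      if (!length(upKeys)) stopfmt("no upper-jaw key slices")
      keyBoxes[[as.character(nearest(s, upKeys))]]
    }
  })
}
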