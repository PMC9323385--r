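## Synthetic dental phantom: deterministic slice stacks with full ground
## truth, so every pipeline stage is testable without clinical data.
##
## Geometry: each jaw's dental arch is a parabola in the axial plane; the 16
## teeth of a jaw sit at equal arc-length positions along it and are drawn
## as bright axis-aligned ellipses over a dimmer bone band on a dark
## background. Along z the stack has the five-region structure
## lower no-tooth / lower crown / overlap / upper crown / upper no-tooth;
## the overlap region draws both jaws.

#' Phantom configuration
#'
#' @param imageSize side length of the square slices in pixels.
#' @param regionLengths integer vector of 5 z-extents (lower no-tooth,
#'   lower crown, overlap, upper crown, upper no-tooth); their sum is the
#'   number of slices. The default 40-slice stack gives each crown region
#'   12 slices — crowns span the thickest z-range in practice, and the
#'   10th/10th-from-last key-slice rule presumes crown regions of at least
#'   ten slices.
#' @param missing FDI codes of absent teeth (a minor-defect dentition has at
#'   most a couple).
#' @param noiseSigma standard deviation of the additive Gaussian intensity
#'   noise, on the normalized \[0, 1\] scale.
#' @param artefact optional metal-artefact settings: a list with `tooth`
#'   (FDI code of the restored tooth), `nStreaks`, and `darkBands`.
#' @param seed RNG seed; the generated stack and truth are a pure function
#'   of the configuration.
#' @param arch,toothRadii optional overrides of the arch parabolas (list per
#'   jaw with `apexY`, `halfWidth`, `depth`, all in pixels) and of the
#'   per-position ellipse radii (list mapping position 1-8 to `c(rx, ry)`).
#' @return A configuration list for [generatePhantom()].
#' @export
phantomConfig <- function(imageSize = 256L,
                          regionLengths = c(4L, 12L, 8L, 12L, 4L),
                          missing = integer(), noiseSigma = 0.01,
                          artefact = NULL, seed = 1L, arch = NULL,
                          toothRadii = NULL) {
  stopifnot(length(regionLengths) == 5L, all(regionLengths >= 0L),
            sum(regionLengths) >= 1L, imageSize >= 64L)
  if (length(missing) && !all(isFdiCode(missing)))
    stopfmt("invalid FDI codes in missing set")
  s <- imageSize / 256
  arch <- arch %||% list(
    lower = list(apexY = 0.26 * imageSize, halfWidth = 0.34 * imageSize,
                 depth = 0.42 * imageSize),
    upper = list(apexY = 0.22 * imageSize, halfWidth = 0.37 * imageSize,
                 depth = 0.45 * imageSize))
  toothRadii <- toothRadii %||% lapply(list(
    `1` = c(6, 5), `2` = c(6, 5), `3` = c(6, 6), `4` = c(7, 6),
    `5` = c(7, 6), `6` = c(8, 7), `7` = c(8, 7), `8` = c(8, 7)),
    function(r) r * s)
  list(imageSize = as.integer(imageSize),
       regionLengths = as.integer(regionLengths),
       missing = as.integer(missing), noiseSigma = noiseSigma,
       artefact = artefact, seed = as.integer(seed), arch = arch,
       toothRadii = toothRadii)
}

## FDI codes of a jaw from image-left to image-right (radiological display)
.jawCodesImageOrder <- function(jaw) {
  if (jaw == "upper") c(18:11, 21:28) else c(48:41, 31:38)
}

## tooth centres at equal arc-length positions along the jaw's parabola
.archTeeth <- function(cfg, jaw) {
  a <- cfg$arch[[jaw]]
  W <- cfg$imageSize
  cx0 <- W / 2
  curv <- a$depth / a$halfWidth^2
  xs <- seq(cx0 - a$halfWidth, cx0 + a$halfWidth, length.out = 2001L)
  ys <- a$apexY + curv * (xs - cx0)^2
  s <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  codes <- .jawCodesImageOrder(jaw)
  targets <- (seq_along(codes) - 0.5) / length(codes) * max(s)
  cx <- stats::approx(s, xs, xout = targets)$y
  cy <- a$apexY + curv * (cx - cx0)^2
  pos <- fdiPosition(codes)
  rx <- vapply(pos, function(p) cfg$toothRadii[[as.character(p)]][1], 0)
  ry <- vapply(pos, function(p) cfg$toothRadii[[as.character(p)]][2], 0)
  df <- data.frame(tooth = codes, jaw = jaw,
                   block = vapply(codes, function(c)
                     blockOfTooth(c)$block, ""),
                   cx = cx, cy = cy, rx = rx, ry = ry,
                   stringsAsFactors = FALSE)
  df$L <- df$cx - df$rx; df$T <- df$cy - df$ry
  df$R <- df$cx + df$rx; df$B <- df$cy + df$ry
  df[!df$tooth %in% cfg$missing, , drop = FALSE]
}

## base image (no noise) for a set of active jaws
.baseImage <- function(cfg, jaws, teethByJaw) {
  W <- cfg$imageSize
  img <- matrix(0.1, W, W)
  xg <- matrix(rep(seq_len(W) - 0.5, each = W), W)   # x of pixel centres
  yg <- matrix(rep(seq_len(W) - 0.5, times = W), W)  # y of pixel centres
  for (jaw in jaws) {
    a <- cfg$arch[[jaw]]
    cx0 <- W / 2
    curv <- a$depth / a$halfWidth^2
    inX <- abs(xg - cx0) <= a$halfWidth + 6
    bone <- inX & abs(yg - (a$apexY + curv * (xg - cx0)^2)) <= 0.055 * W
    img[bone] <- 0.4
  }
  for (jaw in jaws) {
    tt <- teethByJaw[[jaw]]
    for (i in seq_len(nrow(tt))) {
      ell <- ((xg - tt$cx[i]) / tt$rx[i])^2 + ((yg - tt$cy[i]) / tt$ry[i])^2 <= 1
      img[ell] <- 0.9
    }
  }
  img
}

.regionJaws <- list(lower_no_tooth = character(),
                    lower_crown = "lower",
                    overlap = c("lower", "upper"),
                    upper_crown = "upper",
                    upper_no_tooth = character())
.regionClass <- c(lower_no_tooth = "no_tooth", lower_crown = "crown",
                  overlap = "overlap", upper_crown = "crown",
                  upper_no_tooth = "no_tooth")

#' Generate a synthetic phantom stack with ground truth
#'
#' Produces a deterministic [SliceStack-class] (8-bit intensity scale 0-255:
#' background 0.1, bone band 0.4, teeth 0.9 of the dynamic range, plus
#' Gaussian noise) and the matching [PhantomTruth-class]: per-slice class
#' and layer labels, per-tooth ellipse masks and boxes, per-jaw block boxes
#' (the hull of the member teeth) and the main-area box (the hull of all
#' teeth on the slice). When `cfg$artefact` is set, metal-artefact streaks
#' are added via [addMetalArtefacts()].
#'
#' @param cfg a configuration from [phantomConfig()].
#' @return A list with elements `stack` and `truth`.
#' @export
generatePhantom <- function(cfg = phantomConfig()) {
  W <- cfg$imageSize
  n <- sum(cfg$regionLengths)
  regions <- rep(layerLabelNames(), cfg$regionLengths)
  teethByJaw <- list(lower = .archTeeth(cfg, "lower"),
                     upper = .archTeeth(cfg, "upper"))
  bases <- lapply(layerLabelNames(), function(r)
    .baseImage(cfg, .regionJaws[[r]], teethByJaw))
  names(bases) <- layerLabelNames()
  slices <- withSeed(cfg$seed, lapply(seq_len(n), function(i) {
    v <- bases[[regions[i]]] +
      matrix(stats::rnorm(W * W, 0, cfg$noiseSigma), W, W)
    matrix(as.numeric(clampNum(round(v * 255), 0, 255)), W, W)
  }))
  teethRows <- list(); blockRows <- list(); mainRows <- list()
  for (i in seq_len(n)) {
    jaws <- .regionJaws[[regions[i]]]
    if (!length(jaws)) next
    tt <- do.call(rbind, teethByJaw[jaws])
    tt <- cbind(slice = i, tt)
    teethRows[[length(teethRows) + 1L]] <- tt
    for (jaw in jaws) {
      tj <- teethByJaw[[jaw]]
      for (bn in unique(tj$block)) {
        hull <- boxHull(dfBoxes(tj[tj$block == bn, , drop = FALSE]))
        blockRows[[length(blockRows) + 1L]] <- data.frame(
          slice = i, jaw = jaw, block = bn, L = hull[["L"]], T = hull[["T"]],
          R = hull[["R"]], B = hull[["B"]], stringsAsFactors = FALSE)
      }
    }
    hull <- boxHull(dfBoxes(tt))
    mainRows[[length(mainRows) + 1L]] <- data.frame(
      slice = i, L = hull[["L"]], T = hull[["T"]], R = hull[["R"]],
      B = hull[["B"]])
  }
  emptyTeeth <- data.frame(slice = integer(), tooth = integer(),
                           jaw = character(), block = character(),
                           cx = double(), cy = double(), rx = double(),
                           ry = double(), L = double(), T = double(),
                           R = double(), B = double())
  truth <- new("PhantomTruth",
    classLabels = unname(.regionClass[regions]),
    layerLabels = regions,
    teeth = if (length(teethRows)) do.call(rbind, teethRows) else emptyTeeth,
    blocks = if (length(blockRows)) do.call(rbind, blockRows)
             else data.frame(slice = integer(), jaw = character(),
                             block = character(), L = double(), T = double(),
                             R = double(), B = double()),
    mainArea = if (length(mainRows)) do.call(rbind, mainRows)
               else data.frame(slice = integer(), L = double(), T = double(),
                               R = double(), B = double()),
    imageSize = W, missing = cfg$missing)
  stack <- SliceStack(slices, pixelSpacing = 0.3, sliceThickness = 0.3,
                      zDirection = "bottom_to_top")
  if (!is.null(cfg$artefact))
    stack <- addMetalArtefacts(stack, truth,
                               tooth = cfg$artefact$tooth,
                               nStreaks = cfg$artefact$nStreaks %||% 8L,
                               darkBands = cfg$artefact$darkBands %||% 2L,
                               seed = cfg$seed)
  list(stack = stack, truth = truth)
}

#' Rasterize a tooth's ground-truth mask
#' @param truth a [PhantomTruth-class].
#' @param slice slice index.
#' @param tooth FDI code present on that slice.
#' @return Logical matrix (the tooth's elliptical pixel mask).
#' @export
toothMask <- function(truth, slice, tooth) {
  tt <- truth@teeth
  row <- tt[tt$slice == slice & tt$tooth == tooth, , drop = FALSE]
  if (!nrow(row))
    stopfmt("tooth %d is not present on slice %d", tooth, slice)
  W <- truth@imageSize
  xg <- matrix(rep(seq_len(W) - 0.5, each = W), W)
  yg <- matrix(rep(seq_len(W) - 0.5, times = W), W)
  ((xg - row$cx) / row$rx)^2 + ((yg - row$cy) / row$ry)^2 <= 1
}

#' Ground-truth boxes of a slice
#' @param truth a [PhantomTruth-class].
#' @param slice slice index.
#' @return `toothBoxes`: data.frame `tooth`, `jaw`, `block`, `L`, `T`, `R`,
#'   `B`; `blockBoxes`: the per-jaw block boxes; `mainAreaBox`: the
#'   main-area [Box()] (error if the slice has no teeth).
#' @export
toothBoxes <- function(truth, slice) {
  tt <- truth@teeth
  tt[tt$slice == slice, c("tooth", "jaw", "block", "L", "T", "R", "B"),
     drop = FALSE]
}

#' @rdname toothBoxes
#' @export
blockBoxes <- function(truth, slice) {
  bb <- truth@blocks
  bb[bb$slice == slice, , drop = FALSE]
}

#' @rdname toothBoxes
#' @export
mainAreaBox <- function(truth, slice) {
  ma <- truth@mainArea
  row <- ma[ma$slice == slice, , drop = FALSE]
  if (!nrow(row)) stopfmt("slice %d has no teeth (no main area)", slice)
  Box(row$L, row$T, row$R, row$B)
}

#' Calibration samples from phantom ground truth
#'
#' Assembles, for each block on each requested slice, the ground-truth
#' block box and the named ground-truth tooth boxes — the sample format
#' consumed by [calibrateLambdas()].
#'
#' @param truth a [PhantomTruth-class].
#' @param slices slice indices (must carry teeth).
#' @return A list of calibration samples.
#' @export
truthCalibrationSamples <- function(truth, slices) {
  out <- list()
  for (s in slices) {
    bb <- blockBoxes(truth, s)
    tb <- toothBoxes(truth, s)
    if (!nrow(bb)) stopfmt("slice %d carries no teeth", s)
    for (r in seq_len(nrow(bb))) {
      tt <- tb[tb$jaw == bb$jaw[r] & tb$block == bb$block[r], , drop = FALSE]
      tr <- lapply(seq_len(nrow(tt)), function(i)
        Box(tt$L[i], tt$T[i], tt$R[i], tt$B[i]))
      names(tr) <- tt$tooth
      out[[length(out) + 1L]] <- list(
        jaw = bb$jaw[r], block = bb$block[r],
        blockBox = Box(bb$L[r], bb$T[r], bb$R[r], bb$B[r]), truth = tr)
    }
  }
  out
}

#' Add metal-artefact streaks to a stack
#'
#' Emulates the streak pattern of a metallic restoration: bright rays
#' radiating from the named tooth's centre out to the image border, plus a
#' few dark bands, clipped to the intensity range. The ground truth is not
#' modified. Streak angles are drawn once from the seeded RNG and reused on
#' every affected slice; they are attached to the result as the
#' `"streakAngles"` attribute.
#'
#' @param stack a [SliceStack-class].
#' @param truth the stack's [PhantomTruth-class].
#' @param tooth FDI code of the restored tooth (must be present).
#' @param nStreaks number of bright streaks.
#' @param darkBands number of additional dark bands.
#' @param seed RNG seed for the streak angles.
#' @return The modified [SliceStack-class].
#' @export
addMetalArtefacts <- function(stack, truth, tooth = 11L, nStreaks = 8L,
                              darkBands = 2L, seed = 1L) {
  tt <- truth@teeth[truth@teeth$tooth == tooth, , drop = FALSE]
  if (!nrow(tt))
    stopfmt("artefact tooth %d is missing from the phantom", tooth)
  if (nStreaks == 0L && darkBands == 0L) return(stack)
  angles <- withSeed(seed, stats::runif(nStreaks + darkBands, 0, 2 * pi))
  bright <- utils::head(angles, nStreaks)
  dark <- utils::tail(angles, darkBands)
  W <- ncol(getSlice(stack, 1)); H <- nrow(getSlice(stack, 1))
  slices <- stack@slices
  for (s in unique(tt$slice)) {
    row <- tt[tt$slice == s, , drop = FALSE][1, ]
    img <- slices[[s]]
    paint <- function(theta, value) {
      tmax <- sqrt(W^2 + H^2)
      steps <- seq(0, tmax, by = 0.5)
      xs <- row$cx + cos(theta) * steps
      ys <- row$cy + sin(theta) * steps
      keep <- xs >= 0 & xs < W & ys >= 0 & ys < H
      ij <- cbind(floor(ys[keep]) + 1L, floor(xs[keep]) + 1L)
      img[unique(ij)] <<- value
      img
    }
    for (a in bright) img <- paint(a, 255)
    for (a in dark) img <- paint(a, 13)   # ~0.05 of the dynamic range
    slices[[s]] <- img
  }
  out <- SliceStack(slices, pixelSpacing = pixelSpacing(stack),
                    sliceThickness = sliceThickness(stack),
                    zDirection = zDirection(stack))
  attr(out, "streakAngles") <- list(bright = bright, dark = dark,
                                    tooth = tooth)
  out
}

#' Truth-backed oracle classifier
#'
#' Returns a slice classifier that emits the true class label of each slice,
#' optionally flipping labels at a configured error rate (to one of the two
#' other classes, uniformly) with a seeded RNG — the controlled way to
#' exercise the anti-noise switch.
#'
#' @param classLabels character vector of true class labels per slice (e.g.
#'   `truth@classLabels` of a [PhantomTruth-class]).
#' @param errorRate per-slice flip probability.
#' @param seed RNG seed; flips are drawn once at construction, so the
#'   classifier is deterministic.
#' @return A classifier `function(image, index)`.
#' @export
oracleClassifier <- function(classLabels, errorRate = 0, seed = 1L) {
  if (is(classLabels, "PhantomTruth")) classLabels <- classLabels@classLabels
  stopifnot(all(classLabels %in% classLabelNames()),
            errorRate >= 0, errorRate <= 1)
  labels <- withSeed(seed, {
    flip <- stats::runif(length(classLabels)) < errorRate
    out <- classLabels
    for (i in which(flip))
      out[i] <- sample(setdiff(classLabelNames(), classLabels[i]), 1L)
    out
  })
  function(image = NULL, index) labels[[index]]
}

#' Truth-backed oracle detector
#'
#' Returns a detector that emits the ground-truth main-area and block boxes
#' of the requested slice with uniform coordinate jitter of at most
#' `jitterPx` pixels and unit scores; block labels in `drop` are
#' suppressed. Jitter is drawn once at construction (seeded), so repeated
#' calls are identical.
#'
#' @param truth a [PhantomTruth-class].
#' @param jitterPx maximum absolute jitter per box coordinate, pixels.
#' @param drop character vector of labels to suppress (block names or
#'   `"main_area"`).
#' @param seed RNG seed.
#' @return A detector `function(image, target, index, roi)`.
#' @export
oracleDetector <- function(truth, jitterPx = 0, drop = character(),
                           seed = 1L) {
  main <- truth@mainArea
  blocks <- truth@blocks
  jit <- function(df) {
    if (!nrow(df)) return(df)
    j <- matrix(stats::runif(4L * nrow(df), -jitterPx, jitterPx), ncol = 4L)
    df$L <- df$L + j[, 1]; df$T <- df$T + j[, 2]
    df$R <- df$R + j[, 3]; df$B <- df$B + j[, 4]
    ## keep boxes valid under adversarial jitter of tiny boxes
    swp <- df$L > df$R; tmp <- df$L[swp]; df$L[swp] <- df$R[swp]; df$R[swp] <- tmp
    swp <- df$T > df$B; tmp <- df$T[swp]; df$T[swp] <- df$B[swp]; df$B[swp] <- tmp
    df
  }
  withSeed(seed, {
    main <- jit(main)
    blocks <- jit(blocks)
  })
  function(image = NULL, target = c("main_area", "blocks"), index = NULL,
           roi = NULL) {
    target <- match.arg(target)
    if (target == "main_area") {
      if ("main_area" %in% drop) return(emptyDetections())
      row <- main[main$slice == index, , drop = FALSE]
      if (!nrow(row)) return(emptyDetections())
      data.frame(label = "main_area", L = row$L, T = row$T, R = row$R,
                 B = row$B, score = 1, stringsAsFactors = FALSE)
    } else {
      rows <- blocks[blocks$slice == index & !(blocks$block %in% drop), ,
                     drop = FALSE]
      if (!nrow(rows)) return(emptyDetections())
      data.frame(label = rows$block, L = rows$L, T = rows$T, R = rows$R,
                 B = rows$B, score = 1, stringsAsFactors = FALSE)
    }
  }
}
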