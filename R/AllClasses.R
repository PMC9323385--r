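#' @import methods
NULL

#' SliceStack: a z-ordered stack of grayscale axial slices
#'
#' Container for the input volume: a list of equally sized 2-D numeric
#' matrices (one per axial slice, intensities on any monotone scale, e.g.
#' uint8 0-255 or uint16), plus the in-plane pixel spacing, slice thickness
#' and scan direction along z.
#'
#' @slot slices list of numeric matrices, all of the same dimension.
#' @slot pixelSpacing in-plane pixel spacing in millimetres (> 0).
#' @slot sliceThickness slice thickness in millimetres (> 0).
#' @slot zDirection `"bottom_to_top"` (the usual CBCT convention) or
#'   `"top_to_bottom"`.
#' @export
setClass("SliceStack",
  representation(slices = "list", pixelSpacing = "numeric",
                 sliceThickness = "numeric", zDirection = "character"))

setValidity("SliceStack", function(object) {
  msg <- character()
  if (length(object@slices) < 1L) msg <- c(msg, "need at least one slice")
  if (!all(vapply(object@slices, is.matrix, TRUE)))
    msg <- c(msg, "slices must be matrices")
  dims <- vapply(object@slices, dim, integer(2))
  if (length(object@slices) && any(dims != dims[, 1]))
    msg <- c(msg, "all slices must have the same shape")
  if (length(object@pixelSpacing) != 1L || !is.finite(object@pixelSpacing) ||
      object@pixelSpacing <= 0)
    msg <- c(msg, "pixelSpacing must be a single positive number")
  if (length(object@sliceThickness) != 1L ||
      !is.finite(object@sliceThickness) || object@sliceThickness <= 0)
    msg <- c(msg, "sliceThickness must be a single positive number")
  if (!object@zDirection %in% c("bottom_to_top", "top_to_bottom"))
    msg <- c(msg, "zDirection must be 'bottom_to_top' or 'top_to_bottom'")
  if (length(msg)) msg else TRUE
})

#' Construct a SliceStack
#' @param slices list of numeric matrices (z-ordered axial slices).
#' @param pixelSpacing in-plane spacing in mm.
#' @param sliceThickness slice thickness in mm.
#' @param zDirection scan direction along z.
#' @return A [SliceStack-class] object.
#' @export
SliceStack <- function(slices, pixelSpacing = 0.3, sliceThickness = 0.3,
                       zDirection = c("bottom_to_top", "top_to_bottom")) {
  new("SliceStack", slices = slices, pixelSpacing = pixelSpacing,
      sliceThickness = sliceThickness, zDirection = match.arg(zDirection))
}

#' LayerLabeling: per-slice class and layer labels
#'
#' Output of the anti-noise switch: the raw 3-class labels per slice
#' (`no_tooth`, `crown`, `overlap`), the derived 5-state layer labels
#' (`lower_no_tooth` ... `upper_no_tooth`, monotone along the scan
#' direction), and the indices of the four state switches (the first slice of
#' each new region; `NA` where a region was never entered).
#'
#' @slot classLabels character vector of 3-class labels per slice.
#' @slot layerLabels character vector of 5-state layer labels per slice.
#' @slot boundaries integer vector of length 4 (switch indices, `NA` allowed).
#' @export
setClass("LayerLabeling",
  representation(classLabels = "character", layerLabels = "character",
                 boundaries = "integer"))

setValidity("LayerLabeling", function(object) {
  msg <- character()
  if (length(object@classLabels) != length(object@layerLabels))
    msg <- c(msg, "classLabels and layerLabels must have equal length")
  if (!all(object@classLabels %in% classLabelNames()))
    msg <- c(msg, "invalid class labels")
  if (!all(object@layerLabels %in% layerLabelNames()))
    msg <- c(msg, "invalid layer labels")
  st <- match(object@layerLabels, layerLabelNames())
  ## monotone along the scan direction (either storage order is accepted)
  if (length(st) > 1L && any(diff(st) < 0) && any(diff(st) > 0))
    msg <- c(msg, "layer labels must be monotone in the 5-state order")
  if (length(object@boundaries) != 4L)
    msg <- c(msg, "boundaries must have length 4")
  b <- object@boundaries[!is.na(object@boundaries)]
  if (length(b) && (any(b < 1L) || any(b > length(object@layerLabels))))
    msg <- c(msg, "boundaries out of range")
  ## boundaries must point at the first stored slice of each region
  firsts <- vapply(2:5, function(s) {
    i <- which(st == s)
    if (length(i)) min(i) else NA_integer_
  }, 1L)
  if (!identical(firsts, object@boundaries))
    msg <- c(msg, "boundaries inconsistent with layerLabels")
  if (length(msg)) msg else TRUE
})

#' LambdaTable: per-tooth proportion coefficients
#'
#' Maps each FDI tooth to the proportion entry that places its bounding box
#' inside its block's detected box. An entry holds the left-top and
#' right-bottom lambda pairs (position ratios `lambda = (x - x1)/(x2 - x)`,
#' domain `[0, Inf]`), a fractional per-side enlargement, and optionally an
#' exact affine coefficient matrix that overrides the lambda path (used for
#' published coefficient sets where the enlargement is already folded in).
#'
#' @slot entries named list keyed by FDI code; each element is a list with
#'   fields `lt` (numeric 2), `rb` (numeric 2), `enlarge` (numeric 1) and
#'   `affine` (4x2 numeric matrix or `NULL`).
#' @export
setClass("LambdaTable", representation(entries = "list"))

setValidity("LambdaTable", function(object) {
  msg <- character()
  codes <- suppressWarnings(as.integer(names(object@entries)))
  if (anyNA(codes) || !all(isFdiCode(codes)))
    msg <- c(msg, "entry names must be valid FDI codes")
  for (e in object@entries) {
    if (!all(c("lt", "rb", "enlarge") %in% names(e))) {
      msg <- c(msg, "entries need fields lt, rb, enlarge"); break
    }
    if (length(e$lt) != 2L || length(e$rb) != 2L ||
        any(e$lt < 0) || any(e$rb < 0) || anyNA(e$lt) || anyNA(e$rb)) {
      msg <- c(msg, "lambda pairs must be non-negative numeric pairs"); break
    }
    if (e$enlarge < 0) { msg <- c(msg, "enlarge must be >= 0"); break }
    if (!is.null(e$affine) &&
        (!is.matrix(e$affine) || !all(dim(e$affine) == c(4L, 2L)))) {
      msg <- c(msg, "affine must be a 4x2 matrix or NULL"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: full ground truth of a synthetic phantom stack
#'
#' Per-slice class and layer labels, per-tooth ellipse parameters (from which
#' binary masks are rasterized on demand) and bounding boxes, per-jaw block
#' boxes, and the main-area box, for every slice of a generated phantom.
#'
#' @slot classLabels,layerLabels character vectors, one entry per slice.
#' @slot teeth data.frame: slice, tooth (FDI), jaw, block, cx, cy, rx, ry,
#'   L, T, R, B.
#' @slot blocks data.frame: slice, jaw, block, L, T, R, B.
#' @slot mainArea data.frame: slice, L, T, R, B.
#' @slot imageSize integer, side length of the square slices.
#' @slot missing integer vector of absent FDI codes.
#' @export
setClass("PhantomTruth",
  representation(classLabels = "character", layerLabels = "character",
                 teeth = "data.frame", blocks = "data.frame",
                 mainArea = "data.frame", imageSize = "integer",
                 missing = "integer"))

setValidity("PhantomTruth", function(object) {
  msg <- character()
  if (length(object@classLabels) != length(object@layerLabels))
    msg <- c(msg, "label vectors must have equal length")
  need <- c("slice", "tooth", "jaw", "block", "cx", "cy", "rx", "ry",
            "L", "T", "R", "B")
  if (!all(need %in% names(object@teeth)))
    msg <- c(msg, "teeth data.frame missing columns")
  if (nrow(object@teeth) && !all(isFdiCode(object@teeth$tooth)))
    msg <- c(msg, "invalid FDI codes in teeth table")
  if (length(object@imageSize) != 1L || object@imageSize < 1L)
    msg <- c(msg, "imageSize must be a positive integer")
  if (length(msg)) msg else TRUE
})
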