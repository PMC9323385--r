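## Axis-aligned bounding boxes.
##
## Boxes are length-4 numeric vectors (L, T, R, B) in continuous pixel
## coordinates: origin at the image's top-left corner, x rightward, y
## downward, half-open on the real line so that area = (R - L) * (B - T).
## This matches Pascal VOC box arithmetic and keeps subdivision exact.

#' Construct an axis-aligned box
#'
#' Boxes carry continuous pixel coordinates `(L, T, R, B)` with the origin at
#' the top-left corner of the image, x increasing rightward and y downward.
#' The box is half-open, so its area is `(R - L) * (B - T)`.
#'
#' @param L,T,R,B left, top, right, bottom coordinates (pixels). Must be
#'   finite with `L <= R` and `T <= B`.
#' @return A named numeric vector of length 4.
#' @examples
#' Box(0, 0, 2, 2)
#' @export
Box <- function(L, T, R, B) {
  b <- c(L = as.numeric(L), T = as.numeric(T),
         R = as.numeric(R), B = as.numeric(B))
  if (anyNA(b) || any(!is.finite(b)))
    stopfmt("Box coordinates must be finite, got (%s)",
            paste(signif(b, 6), collapse = ", "))
  if (b[["L"]] > b[["R"]] || b[["T"]] > b[["B"]])
    stopfmt("invalid Box: need L <= R and T <= B, got (%s)",
            paste(signif(b, 6), collapse = ", "))
  b
}

asBox <- function(b) {
  if (is.null(names(b))) names(b) <- c("L", "T", "R", "B")
  Box(b[["L"]], b[["T"]], b[["R"]], b[["B"]])
}

#' Box area
#' @param b a box from [Box()].
#' @return Numeric area in squared pixels.
#' @export
boxArea <- function(b) {
  b <- asBox(b)
  (b[["R"]] - b[["L"]]) * (b[["B"]] - b[["T"]])
}

#' Intersection-over-union of two boxes
#'
#' Area of the intersection divided by the area of the union. Returns 0 for
#' disjoint boxes and, by convention, 0 when both boxes have zero area.
#'
#' @param a,b boxes from [Box()].
#' @return A number in `[0, 1]`.
#' @examples
#' boxIoU(Box(0, 0, 2, 2), Box(1, 1, 3, 3)) # 1/7
#' @export
boxIoU <- function(a, b) {
  a <- asBox(a); b <- asBox(b)
  iw <- min(a[["R"]], b[["R"]]) - max(a[["L"]], b[["L"]])
  ih <- min(a[["B"]], b[["B"]]) - max(a[["T"]], b[["T"]])
  inter <- max(iw, 0) * max(ih, 0)
  uni <- boxArea(a) + boxArea(b) - inter
  if (uni <= 0) return(0)
  inter / uni
}

#' Bounding hull of two or more boxes
#' @param ... boxes, or a single list of boxes.
#' @return The smallest box containing all inputs.
#' @export
boxHull <- function(...) {
  bs <- list(...)
  if (length(bs) == 1L && is.list(bs[[1]])) bs <- bs[[1]]
  bs <- lapply(bs, asBox)
  Box(min(vapply(bs, `[[`, 0, "L")), min(vapply(bs, `[[`, 0, "T")),
      max(vapply(bs, `[[`, 0, "R")), max(vapply(bs, `[[`, 0, "B")))
}

#' Clamp a box to image bounds
#' @param b a box.
#' @param width,height image dimensions in pixels.
#' @return The clamped box.
#' @export
clampBox <- function(b, width, height) {
  b <- asBox(b)
  Box(clampNum(b[["L"]], 0, width),  clampNum(b[["T"]], 0, height),
      clampNum(b[["R"]], 0, width),  clampNum(b[["B"]], 0, height))
}

#' Symmetrically enlarge a box
#'
#' Grows the box by `frac` of its width on each of the left/right sides and
#' `frac` of its height on each of the top/bottom sides.
#'
#' @param b a box.
#' @param frac fractional margin per side, `>= 0`.
#' @return The enlarged box.
#' @export
enlargeBox <- function(b, frac) {
  b <- asBox(b)
  stopifnot(is.numeric(frac), frac >= 0)
  w <- b[["R"]] - b[["L"]]; h <- b[["B"]] - b[["T"]]
  Box(b[["L"]] - frac * w, b[["T"]] - frac * h,
      b[["R"]] + frac * w, b[["B"]] + frac * h)
}

## Row-wise boxes in a data frame -> list of Box
dfBoxes <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    Box(df$L[i], df$T[i], df$R[i], df$B[i]))
}
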