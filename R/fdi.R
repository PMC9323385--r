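## FDI two-digit tooth numbering and the five-block anatomy of the dental
## arch. Quadrants: 1 = upper right, 2 = upper left, 3 = lower left,
## 4 = lower right (patient's right/left). Positions 1..8 run from the
## central incisor to the third molar.

.blockNames <- c("incisors", "right_canine_premolar", "left_canine_premolar",
                 "right_molar", "left_molar")
.jawNames <- c("upper", "lower")
.classLabels <- c("no_tooth", "crown", "overlap")
.layerLabels <- c("lower_no_tooth", "lower_crown", "overlap",
                  "upper_crown", "upper_no_tooth")

## Positions belonging to each block (same on both sides of the jaw).
.blockPositions <- list(
  incisors = 1:2,
  canine_premolar = 3:5,
  molar = 6:8
)

#' All valid FDI tooth codes
#' @return Integer vector of the 32 permanent-dentition codes
#'   (11-18, 21-28, 31-38, 41-48).
#' @export
allFdiCodes <- function() as.integer(outer(1:8, c(10L, 20L, 30L, 40L), `+`))

#' Validate FDI codes
#' @param code integer vector.
#' @return Logical vector, `TRUE` where `code` is a valid FDI code.
#' @export
isFdiCode <- function(code) {
  q <- code %/% 10L; p <- code %% 10L
  !is.na(code) & q %in% 1:4 & p %in% 1:8
}

#' @rdname isFdiCode
#' @export
fdiQuadrant <- function(code) {
  stopifnot(all(isFdiCode(code)))
  code %/% 10L
}

#' @rdname isFdiCode
#' @export
fdiPosition <- function(code) {
  stopifnot(all(isFdiCode(code)))
  code %% 10L
}

#' Jaw of an FDI tooth
#' @param code valid FDI code(s).
#' @return `"upper"` or `"lower"` per code.
#' @export
fdiJaw <- function(code) {
  ifelse(fdiQuadrant(code) %in% 1:2, "upper", "lower")
}

#' The five detection blocks
#' @return Character vector of the five block names.
#' @export
blockNames <- function() .blockNames

#' Layer and class label vocabularies
#' @return `classLabelNames()`: the 3 per-slice classes; `layerLabelNames()`:
#'   the 5 z-region labels ordered bottom to top.
#' @export
classLabelNames <- function() .classLabels

#' @rdname classLabelNames
#' @export
layerLabelNames <- function() .layerLabels

checkJawBlock <- function(jaw, block) {
  jaw <- match.arg(jaw, .jawNames)
  block <- match.arg(block, .blockNames)
  list(jaw = jaw, block = block)
}

#' Teeth of a block, ordered left to right in image coordinates
#'
#' The dental arch is split into five blocks per jaw: the four incisors, the
#' right and left canine + premolar triplets, and the right and left molar
#' triplets. Under the default radiological display convention the patient's
#' right side appears on the image's left, so e.g. the upper incisors read
#' 12, 11, 21, 22 from image-left to image-right.
#'
#' @param jaw `"upper"` or `"lower"`.
#' @param block one of [blockNames()].
#' @param chirality `"radiological"` (patient right on image left, default)
#'   or `"anatomical"` (mirrored).
#' @return Integer vector of FDI codes in image left-to-right order.
#' @examples
#' blockTeeth("upper", "incisors")                  # 12 11 21 22
#' blockTeeth("lower", "right_canine_premolar")     # 45 44 43
#' @export
blockTeeth <- function(jaw, block,
                       chirality = c("radiological", "anatomical")) {
  jb <- checkJawBlock(jaw, block)
  chirality <- match.arg(chirality)
  qRight <- if (jb$jaw == "upper") 1L else 4L
  qLeft <- if (jb$jaw == "upper") 2L else 3L
  ## image left -> right under the radiological convention:
  ## patient-right teeth distal-to-mesial, then patient-left mesial-to-distal
  teeth <- switch(jb$block,
    incisors = c(qRight * 10L + 2:1, qLeft * 10L + 1:2),
    right_canine_premolar = qRight * 10L + 5:3,
    left_canine_premolar = qLeft * 10L + 3:5,
    right_molar = qRight * 10L + 8:6,
    left_molar = qLeft * 10L + 6:8)
  if (chirality == "anatomical") teeth <- rev(teeth)
  teeth
}

#' Block membership of a tooth
#' @param code a valid FDI code.
#' @return List with elements `jaw` and `block`.
#' @export
blockOfTooth <- function(code) {
  stopifnot(length(code) == 1L, isFdiCode(code))
  q <- fdiQuadrant(code); p <- fdiPosition(code)
  jaw <- if (q %in% 1:2) "upper" else "lower"
  side <- if (q %in% c(1L, 4L)) "right" else "left"
  block <- if (p %in% .blockPositions$incisors) "incisors"
  else if (p %in% .blockPositions$canine_premolar)
    paste0(side, "_canine_premolar")
  else paste0(side, "_molar")
  list(jaw = jaw, block = block)
}
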