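## Minimal reader for single-frame uncompressed grayscale DICOM series.
##
## Scope is deliberately narrow: one file per axial slice, little-endian
## explicit or implicit VR transfer syntax, MONOCHROME pixel data with 8 or
## 16 bits allocated. Everything else (sequences of undefined length,
## compressed transfer syntaxes, multi-frame objects, colour) is rejected
## with an informative error rather than guessed at.

.u16 <- function(raw, off) {
  as.integer(raw[off]) + 256L * as.integer(raw[off + 1L])
}
.u32 <- function(raw, off) {
  as.double(raw[off]) + 256 * as.double(raw[off + 1L]) +
    65536 * as.double(raw[off + 2L]) + 16777216 * as.double(raw[off + 3L])
}
.tagKey <- function(group, elem) sprintf("%04x,%04x", group, elem)

## VRs that use the 4-byte length form (with 2 reserved bytes) in explicit VR
.longVRs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

## Parse one DICOM file into a list of raw element values keyed by tag.
parseDicomElements <- function(path) {
  n <- file.size(path)
  raw <- readBin(path, "raw", n)
  if (n < 140 || rawToChar(raw[129:132]) != "DICM")
    stopfmt("%s: not a DICOM file (missing DICM magic)", basename(path))
  pos <- 133L
  elements <- list()
  implicit <- FALSE   # file meta group is always explicit VR
  inMeta <- TRUE
  while (pos + 7L <= n) {
    group <- .u16(raw, pos); elem <- .u16(raw, pos + 2L)
    if (inMeta && group != 0x0002) {
      ## meta group done: fix VR mode from the transfer syntax
      inMeta <- FALSE
      tsRaw <- elements[["0002,0010"]]
      if (is.null(tsRaw)) {
        ts <- "1.2.840.10008.1.2.1"
      } else {
        tsRaw <- tsRaw[tsRaw != as.raw(0L) & tsRaw != as.raw(32L)]
        ts <- rawToChar(tsRaw)
      }
      if (ts == "1.2.840.10008.1.2") {
        implicit <- TRUE
      } else if (ts != "1.2.840.10008.1.2.1") {
        stopfmt("%s: unsupported transfer syntax %s", basename(path), ts)
      }
    }
    if (implicit && !inMeta) {
      len <- .u32(raw, pos + 4L)
      dataPos <- pos + 8L
    } else {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .longVRs) {
        len <- .u32(raw, pos + 8L)
        dataPos <- pos + 12L
      } else {
        len <- .u16(raw, pos + 6L)
        dataPos <- pos + 8L
      }
    }
    if (len == 4294967295)
      stopfmt("%s: undefined-length elements are not supported",
              basename(path))
    if (dataPos + len - 1L > n)
      stopfmt("%s: truncated element at offset %d", basename(path), pos)
    key <- .tagKey(group, elem)
    elements[[key]] <- if (len > 0) raw[dataPos:(dataPos + len - 1L)]
                       else raw(0)
    pos <- dataPos + as.integer(len)
  }
  elements
}

.dsValues <- function(rawVal) {
  if (is.null(rawVal)) return(NULL)
  as.numeric(strsplit(sub("\\s+$", "", rawToChar(rawVal)), "\\\\")[[1]])
}
.usValue <- function(rawVal) {
  if (is.null(rawVal)) return(NULL)
  .u16(rawVal, 1L)
}

## Decode one parsed file into image matrix + geometry fields.
decodeDicomSlice <- function(path) {
  el <- parseDicomElements(path)
  rows <- .usValue(el[["0028,0010"]])
  cols <- .usValue(el[["0028,0011"]])
  bits <- .usValue(el[["0028,0100"]]) %||% 16L
  signed <- (.usValue(el[["0028,0103"]]) %||% 0L) == 1L
  px <- el[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(px))
    stopfmt("%s: missing Rows/Columns/PixelData", basename(path))
  if (!bits %in% c(8L, 16L))
    stopfmt("%s: unsupported BitsAllocated %d", basename(path), bits)
  vals <- if (bits == 8L) as.integer(px)
  else readBin(px, "integer", n = length(px) %/% 2L, size = 2L,
               signed = signed, endian = "little")
  if (bits == 16L && !signed) vals <- ifelse(vals < 0, vals + 65536L, vals)
  if (length(vals) != rows * cols)
    stopfmt("%s: pixel data size does not match Rows x Columns",
            basename(path))
  ipp <- .dsValues(el[["0020,0032"]])
  zpos <- if (!is.null(ipp) && length(ipp) >= 3) ipp[3]
          else .dsValues(el[["0020,1041"]])[1]
  list(image = matrix(vals, nrow = rows, ncol = cols, byrow = TRUE),
       z = if (is.null(zpos)) NA_real_ else zpos,
       spacing = .dsValues(el[["0028,0030"]]),
       thickness = .dsValues(el[["0018,0050"]]))
}

#' Read a DICOM series into a SliceStack
#'
#' Reads a directory of single-frame grayscale DICOM files (one file per
#' axial slice, uncompressed little-endian transfer syntax) and assembles
#' them into a [SliceStack-class], sorted by slice position ascending. When
#' position tags (ImagePositionPatient / SliceLocation) are absent the files
#' are kept in filename order with a warning.
#'
#' @param directory path containing the DICOM files.
#' @param pattern filename filter passed to [list.files()].
#' @param zDirection optional override of the scan direction; default assumes
#'   the stack is scanned bottom to top.
#' @return A [SliceStack-class].
#' @export
readDicomSeries <- function(directory, pattern = NULL,
                            zDirection = "bottom_to_top") {
  files <- list.files(directory, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 1L)
    stopfmt("no files found in %s", directory)
  parsed <- lapply(sort(files), decodeDicomSlice)
  dims <- vapply(parsed, function(p) dim(p$image), integer(2))
  if (any(dims != dims[, 1]))
    stopfmt("mixed image shapes in DICOM series (%s)",
            paste(unique(apply(dims, 2, paste, collapse = "x")),
                  collapse = " vs "))
  zs <- vapply(parsed, `[[`, 0, "z")
  if (anyNA(zs)) {
    warnfmt("missing slice position tags; falling back to filename order")
  } else {
    parsed <- parsed[order(zs)]
    zs <- sort(zs)
  }
  sp <- parsed[[1]]$spacing
  th <- parsed[[1]]$thickness
  if (is.null(th) || !length(th) || is.na(th[1])) {
    th <- if (length(zs) > 1 && !anyNA(zs)) median(diff(zs)) else 1
  }
  SliceStack(lapply(parsed, `[[`, "image"),
             pixelSpacing = if (length(sp)) sp[1] else 1,
             sliceThickness = th[1],
             zDirection = zDirection)
}
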