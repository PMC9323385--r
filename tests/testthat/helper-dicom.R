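## Minimal explicit-VR little-endian DICOM writer for test fixtures.

.raw16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                               endian = "little")
.raw32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                               endian = "little")

## one data element; strVal padded to even length (NUL for UI, space else)
dcmElement <- function(group, elem, vr, value) {
  body <- if (vr %in% c("US")) {
    .raw16(value)
  } else if (vr %in% c("UL")) {
    .raw32(value)
  } else if (vr == "OW") {
    value   # already raw
  } else {   # string-valued (DS, UI, CS, ...)
    b <- charToRaw(as.character(value))
    if (length(b) %% 2L == 1L)
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    b
  }
  head <- c(.raw16(group), .raw16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UT", "UN")) {
    c(head, raw(2L), .raw32(length(body)), body)
  } else {
    c(head, .raw16(length(body)), body)
  }
}

## write one single-frame 16-bit grayscale slice
writeMiniDicom <- function(path, mat, z = NULL, spacing = 0.3,
                           thickness = 0.3) {
  tsEl <- dcmElement(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  meta <- c(dcmElement(0x0002, 0x0000, "UL", length(tsEl)), tsEl)
  px <- writeBin(as.integer(t(mat)), raw(), size = 2L, endian = "little")
  ds <- c(
    dcmElement(0x0018, 0x0050, "DS", format(thickness)),
    if (!is.null(z))
      dcmElement(0x0020, 0x0032, "DS", sprintf("0\\0\\%s", format(z))),
    dcmElement(0x0028, 0x0010, "US", nrow(mat)),
    dcmElement(0x0028, 0x0011, "US", ncol(mat)),
    dcmElement(0x0028, 0x0030, "DS", sprintf("%s\\%s", format(spacing),
                                             format(spacing))),
    dcmElement(0x0028, 0x0100, "US", 16L),
    dcmElement(0x0028, 0x0103, "US", 0L),
    dcmElement(0x7fe0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

## write a whole series into a directory; returns the file paths
writeMiniDicomSeries <- function(dir, mats, zs, spacing = 0.3,
                                 thickness = 0.3, names = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names <- names %||% sprintf("slice_%03d.dcm", seq_along(mats))
  paths <- file.path(dir, names)
  for (i in seq_along(mats))
    writeMiniDicom(paths[i], mats[[i]],
                   z = if (is.null(zs)) NULL else zs[i],
                   spacing = spacing, thickness = thickness)
  paths
}

`%||%` <- function(a, b) if (is.null(a)) b else a
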