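## PNG slice-stack IO: a directory of 8-bit grayscale PNGs (one per slice,
## lexicographic filename order = z order) plus a meta.json with the
## geometry. Used by the simulate subcommand and anywhere a DICOM export is
## not available.

#' Write a SliceStack as PNG slices plus JSON metadata
#'
#' Slices are written as 8-bit grayscale PNGs named `slice_0001.png`, ... in
#' z order, with a `meta.json` holding pixel spacing, slice thickness and
#' scan direction. Intensities are clamped to 0-255.
#'
#' @param stack a [SliceStack-class].
#' @param directory output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeImageStack <- function(stack, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nSlices(stack))) {
    m <- clampNum(getSlice(stack, i), 0, 255) / 255
    png::writePNG(m, file.path(directory, sprintf("slice_%04d.png", i)))
  }
  jsonlite::write_json(
    list(pixel_spacing = pixelSpacing(stack),
         slice_thickness = sliceThickness(stack),
         z_direction = zDirection(stack)),
    file.path(directory, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Read a PNG slice stack written by [writeImageStack()]
#' @param directory directory containing the PNGs and `meta.json`.
#' @return A [SliceStack-class] with intensities on the 0-255 scale.
#' @export
readImageStack <- function(directory) {
  metaPath <- file.path(directory, "meta.json")
  meta <- if (file.exists(metaPath)) jsonlite::read_json(metaPath) else list()
  files <- sort(list.files(directory, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stopfmt("no PNG slices found in %s", directory)
  slices <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]   # collapse RGB(A) to gray
    round(m * 255)
  })
  SliceStack(slices,
             pixelSpacing = as.numeric(meta$pixel_spacing %||% 1),
             sliceThickness = as.numeric(meta$slice_thickness %||% 1),
             zDirection = as.character(meta$z_direction %||% "bottom_to_top"))
}
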