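#' @rdname SliceStack-class
#' @export
setMethod("nSlices", "SliceStack", function(x) length(x@slices))

#' @rdname SliceStack-class
#' @export
setMethod("getSlice", "SliceStack", function(x, i) {
  stopifnot(i >= 1L, i <= length(x@slices))
  x@slices[[i]]
})

#' @rdname SliceStack-class
#' @export
setMethod("pixelSpacing", "SliceStack", function(x) x@pixelSpacing)

#' @rdname SliceStack-class
#' @export
setMethod("sliceThickness", "SliceStack", function(x) x@sliceThickness)

#' @rdname SliceStack-class
#' @export
setMethod("zDirection", "SliceStack", function(x) x@zDirection)

#' @rdname SliceStack-class
#' @export
setMethod("dim", "SliceStack", function(x)
  c(dim(x@slices[[1]]), length(x@slices)))

setMethod("show", "SliceStack", function(object) {
  d <- dim(object)
  cat(sprintf(
    "SliceStack: %d slice(s) of %d x %d, %.3g mm pixels, %.3g mm thick, %s\n",
    d[3], d[1], d[2], object@pixelSpacing, object@sliceThickness,
    object@zDirection))
})

#' @rdname LayerLabeling-class
#' @export
setMethod("classLabels", "LayerLabeling", function(x) x@classLabels)

#' @rdname LayerLabeling-class
#' @export
setMethod("layerLabels", "LayerLabeling", function(x) x@layerLabels)

#' @rdname LayerLabeling-class
#' @export
setMethod("boundaries", "LayerLabeling", function(x) x@boundaries)

#' @rdname LayerLabeling-class
#' @export
setMethod("length", "LayerLabeling", function(x) length(x@layerLabels))

setMethod("show", "LayerLabeling", function(object) {
  tab <- table(factor(object@layerLabels, levels = layerLabelNames()))
  cat(sprintf("LayerLabeling: %d slices (%s); switches at [%s]\n",
              length(object@layerLabels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              paste(object@boundaries, collapse = ", ")))
})

#' @rdname LambdaTable-class
#' @export
setMethod("coveredTeeth", "LambdaTable", function(x)
  sort(as.integer(names(x@entries))))

#' @rdname LambdaTable-class
#' @export
setMethod("lambdaEntry", "LambdaTable", function(x, tooth) {
  e <- x@entries[[as.character(tooth)]]
  if (is.null(e))
    stopfmt("lambda table has no entry for tooth %s", tooth)
  e
})

#' @rdname LambdaTable-class
#' @export
setReplaceMethod("lambdaEntry", "LambdaTable", function(x, tooth, value) {
  x@entries[[as.character(tooth)]] <- value
  validObject(x)
  x
})

setMethod("show", "LambdaTable", function(object) {
  nAff <- sum(vapply(object@entries, function(e) !is.null(e$affine), TRUE))
  cat(sprintf("LambdaTable: %d teeth covered (%d with affine override)\n",
              length(object@entries), nAff))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: %d slices of %d x %d, %d tooth records, missing: %s\n",
    length(object@classLabels), object@imageSize, object@imageSize,
    nrow(object@teeth),
    if (length(object@missing)) paste(object@missing, collapse = ", ")
    else "none"))
})
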