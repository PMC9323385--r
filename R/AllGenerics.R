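#' @rdname SliceStack-class
#' @param x,object a `SliceStack`.
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname SliceStack-class
#' @param i slice index.
#' @export
setGeneric("getSlice", function(x, i) standardGeneric("getSlice"))

#' @rdname SliceStack-class
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname SliceStack-class
#' @export
setGeneric("sliceThickness", function(x) standardGeneric("sliceThickness"))

#' @rdname SliceStack-class
#' @export
setGeneric("zDirection", function(x) standardGeneric("zDirection"))

#' @rdname LayerLabeling-class
#' @param x,object a `LayerLabeling`.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname LayerLabeling-class
#' @export
setGeneric("layerLabels", function(x) standardGeneric("layerLabels"))

#' @rdname LayerLabeling-class
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))

#' @rdname LambdaTable-class
#' @param x a `LambdaTable`.
#' @export
setGeneric("coveredTeeth", function(x) standardGeneric("coveredTeeth"))

#' @rdname LambdaTable-class
#' @param tooth FDI code.
#' @export
setGeneric("lambdaEntry", function(x, tooth) standardGeneric("lambdaEntry"))

#' @rdname LambdaTable-class
#' @param value a proportion entry (list with `lt`, `rb`, `enlarge`,
#'   optional `affine`).
#' @export
setGeneric("lambdaEntry<-",
           function(x, tooth, value) standardGeneric("lambdaEntry<-"))
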