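## End-to-end orchestration: classify -> anti-noise switch -> key slices ->
## main area -> blocks -> proportion division -> box propagation.

#' Pipeline configuration
#'
#' @param confirmRun anti-noise switch run length, see [antiNoiseSwitch()].
#' @param scanDirection stack order along z.
#' @param scoreThreshold detector score threshold.
#' @param chirality display convention, see [blockTeeth()].
#' @param missing FDI codes of teeth known to be absent; their boxes are
#'   skipped during division.
#' @param enlarge optional override of the lambda table's per-entry
#'   enlargement fraction.
#' @param classifierPrep whether slices are normalized/resized before the
#'   classifier call, see [classifyStack()].
#' @return A configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(confirmRun = 3L,
                           scanDirection = c("bottom_to_top",
                                             "top_to_bottom"),
                           scoreThreshold = 0.5,
                           chirality = c("radiological", "anatomical"),
                           missing = integer(), enlarge = NULL,
                           classifierPrep = TRUE) {
  list(confirmRun = as.integer(confirmRun),
       scanDirection = match.arg(scanDirection),
       scoreThreshold = scoreThreshold,
       chirality = match.arg(chirality),
       missing = as.integer(missing), enlarge = enlarge,
       classifierPrep = isTRUE(classifierPrep))
}

.stage <- function(name, index, expr) {
  tryCatch(expr, error = function(e)
    stopfmt("pipeline stage '%s'%s failed: %s", name,
            if (is.null(index)) "" else sprintf(" (slice %s)", index),
            conditionMessage(e)))
}

#' Run the whole teeth-detection procedure on a stack
#'
#' Executes the full combined procedure: every slice is classified into the
#' three classes, the anti-noise switch derives the five layer labels, the
#' four key slices (10th and 10th-from-last of each crown region) are
#' selected, the main dental area and the five block boxes are detected on
#' each key slice, each block box is divided into per-tooth FDI boxes by
#' proportion, and the key-slice boxes are propagated to all slices.
#'
#' @param stack a [SliceStack-class].
#' @param classifier a slice classifier `function(image, index)`, e.g.
#'   [oracleClassifier()].
#' @param detector a detector function, e.g. [oracleDetector()] or
#'   [heuristicDetector()].
#' @param table a [LambdaTable-class] (default [defaultLambdaTable()]).
#' @param config a [pipelineConfig()].
#' @return A list with all intermediate artifacts: `classLabels`,
#'   `labeling` ([LayerLabeling-class]), `keySlices`, `mainAreas` (per key
#'   slice), `blocks` (per key slice), `keyToothBoxes` (per key slice) and
#'   `toothBoxes` (per-slice list of data.frames `tooth, L, T, R, B`).
#' @export
runPipeline <- function(stack, classifier, detector,
                        table = defaultLambdaTable(),
                        config = pipelineConfig()) {
  W <- ncol(getSlice(stack, 1)); H <- nrow(getSlice(stack, 1))
  cls <- .stage("classify", NULL,
                classifyStack(stack, classifier, prep = config$classifierPrep))
  labeling <- .stage("anti_noise_switch", NULL,
                     antiNoiseSwitch(cls, config$confirmRun,
                                     config$scanDirection))
  keys <- .stage("select_key_slices", NULL, selectKeySlices(labeling))
  mainAreas <- list(); blockSets <- list(); keyBoxes <- list()
  for (r in seq_len(nrow(keys))) {
    s <- keys$slice[r]; jaw <- keys$jaw[r]
    img <- getSlice(stack, s)
    main <- .stage("detect_main_area", s,
                   detectMainArea(img, detector, config$scoreThreshold,
                                  index = s))
    blk <- .stage("detect_blocks", s,
                  detectBlocks(img, main, detector, jaw,
                               config$scoreThreshold, index = s))
    boxes <- .stage("divide_block", s, {
      parts <- lapply(seq_len(nrow(blk$boxes)), function(b)
        divideBlock(Box(blk$boxes$L[b], blk$boxes$T[b], blk$boxes$R[b],
                        blk$boxes$B[b]),
                    blk$boxes$jaw[b], blk$boxes$block[b], table,
                    missing = config$missing, chirality = config$chirality,
                    imageSize = c(W, H), enlarge = config$enlarge))
      do.call(rbind, parts)
    })
    key <- as.character(s)
    mainAreas[[key]] <- main
    blockSets[[key]] <- blk
    keyBoxes[[key]] <- boxes
  }
  perSlice <- .stage("propagate_boxes", NULL,
                     propagateBoxes(keyBoxes, labeling))
  list(classLabels = cls, labeling = labeling, keySlices = keys,
       mainAreas = mainAreas, blocks = blockSets,
       keyToothBoxes = keyBoxes, toothBoxes = perSlice)
}

#' Flatten a pipeline result into an annotation data.frame
#' @param result the list returned by [runPipeline()].
#' @return An annotation data.frame (one row per tooth box per slice) with
#'   unit scores, suitable for [writeAnnotations()] and
#'   [evaluateDetections()].
#' @export
pipelineAnnotations <- function(result) {
  rows <- lapply(seq_along(result$toothBoxes), function(s) {
    df <- result$toothBoxes[[s]]
    if (is.null(df) || !nrow(df)) return(NULL)
    annotationFrame(slice = s, label = as.character(df$tooth),
                    L = df$L, T = df$T, R = df$R, B = df$B,
                    score = 1, source = "prediction")
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(emptyAnnotations())
  do.call(rbind, rows)
}

#' Mean object inclusion ratio of a pipeline result on a phantom
#'
#' For every slice that carries teeth, computes the OIR of each present,
#' non-missing tooth (ground-truth ellipse mask vs. the slice's propagated
#' box with that FDI label; a tooth with no predicted box scores 0) and
#' averages per slice and overall.
#'
#' @param truth the phantom's [PhantomTruth-class].
#' @param toothBoxesPerSlice per-slice list of tooth-box data.frames (the
#'   `toothBoxes` element of [runPipeline()]'s result).
#' @return A list with `perSlice` (data.frame `slice`, `oir`) and `mean`.
#' @export
phantomOir <- function(truth, toothBoxesPerSlice) {
  slices <- sort(unique(truth@teeth$slice))
  per <- vapply(slices, function(s) {
    tt <- toothBoxes(truth, s)
    tt <- tt[!tt$tooth %in% truth@missing, , drop = FALSE]
    boxes <- toothBoxesPerSlice[[s]]
    vals <- vapply(seq_len(nrow(tt)), function(i) {
      hit <- boxes[boxes$tooth == tt$tooth[i], , drop = FALSE]
      if (!nrow(hit)) return(0)
      oir(toothMask(truth, s, tt$tooth[i]),
          Box(hit$L[1], hit$T[1], hit$R[1], hit$B[1]))
    }, 0)
    mean(vals)
  }, 0)
  list(perSlice = data.frame(slice = slices, oir = per), mean = mean(per))
}
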