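## Annotation IO: Pascal VOC XML (labelImg dialect) and a JSON schema.
##
## Annotations travel as a data.frame with columns
##   slice (int, NA for single-image files), label (chr), L, T, R, B (num),
##   score (num, NA for ground truth), source ("ground_truth"/"prediction").
##
## VOC pixel convention: labelImg writes 1-based inclusive integer
## coordinates. They are converted to the package's 0-based continuous
## half-open convention by L = xmin - 1, T = ymin - 1, R = xmax, B = ymax,
## which preserves widths exactly.

annotationFrame <- function(slice = NA_integer_, label, L, T, R, B,
                            score = NA_real_, source = "ground_truth") {
  data.frame(slice = as.integer(slice), label = as.character(label),
             L = L, T = T, R = R, B = B, score = score, source = source,
             stringsAsFactors = FALSE)
}

emptyAnnotations <- function() {
  data.frame(slice = integer(), label = character(), L = double(),
             T = double(), R = double(), B = double(), score = double(),
             source = character(), stringsAsFactors = FALSE)
}

#' Read Pascal VOC XML annotations
#'
#' Parses a labelImg-style Pascal VOC XML file into an annotation
#' data.frame. VOC's 1-based inclusive integer coordinates are converted to
#' the package's 0-based half-open convention (`L = xmin - 1`,
#' `T = ymin - 1`, `R = xmax`, `B = ymax`).
#'
#' @param path path to the XML file.
#' @param slice optional slice index to record on the annotations.
#' @return A data.frame with one row per `<object>`, in document order.
#' @export
readVocAnnotations <- function(path, slice = NA_integer_) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stopfmt("malformed VOC XML in %s: %s", path, conditionMessage(e)))
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs) == 0L) return(emptyAnnotations())
  rows <- lapply(objs, function(o) {
    nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    bb <- xml2::xml_find_first(o, "./bndbox")
    if (inherits(bb, "xml_missing"))
      stopfmt("VOC object '%s' has no <bndbox> element", nm)
    getNum <- function(tag) {
      v <- suppressWarnings(
        as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0(".//", tag)))))
      if (is.na(v)) stopfmt("VOC object '%s': bad or missing <%s>", nm, tag)
      v
    }
    xmin <- getNum("xmin"); ymin <- getNum("ymin")
    xmax <- getNum("xmax"); ymax <- getNum("ymax")
    if (xmax < xmin || ymax < ymin)
      stopfmt("VOC object '%s': xmax < xmin or ymax < ymin", nm)
    annotationFrame(slice = slice, label = nm,
                    L = xmin - 1, T = ymin - 1, R = xmax, B = ymax)
  })
  do.call(rbind, rows)
}

#' Write annotations to VOC XML or JSON
#'
#' The JSON format is lossless
#' (`{"slices":[{"index":i,"boxes":[{"label","ltrb","score"}]}]}`); the VOC
#' XML format rounds to its 1-based inclusive integer convention, so a
#' round trip agrees to within one pixel.
#'
#' @param annotations annotation data.frame (see [readVocAnnotations()]).
#' @param path output file path.
#' @param format `"json"` or `"voc_xml"`.
#' @param imageSize optional `c(width, height)` recorded in the VOC header.
#' @return The path, invisibly.
#' @export
writeAnnotations <- function(annotations, path,
                             format = c("json", "voc_xml"),
                             imageSize = NULL) {
  format <- match.arg(format)
  if (format == "json") {
    idx <- annotations$slice
    idx[is.na(idx)] <- -1L
    slices <- lapply(sort(unique(idx)), function(s) {
      sub <- annotations[idx == s, , drop = FALSE]
      boxes <- lapply(seq_len(nrow(sub)), function(i) {
        list(label = sub$label[i],
             ltrb = c(sub$L[i], sub$T[i], sub$R[i], sub$B[i]),
             score = if (is.na(sub$score[i])) NULL else sub$score[i])
      })
      list(index = s, boxes = boxes)
    })
    jsonlite::write_json(list(slices = slices), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    doc <- xml2::xml_new_root("annotation")
    if (!is.null(imageSize)) {
      sz <- xml2::xml_add_child(doc, "size")
      xml2::xml_add_child(sz, "width", as.character(imageSize[1]))
      xml2::xml_add_child(sz, "height", as.character(imageSize[2]))
      xml2::xml_add_child(sz, "depth", "1")
    }
    for (i in seq_len(nrow(annotations))) {
      o <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(o, "name", annotations$label[i])
      bb <- xml2::xml_add_child(o, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(round(annotations$L[i]) + 1L))
      xml2::xml_add_child(bb, "ymin", as.character(round(annotations$T[i]) + 1L))
      xml2::xml_add_child(bb, "xmax", as.character(round(annotations$R[i])))
      xml2::xml_add_child(bb, "ymax", as.character(round(annotations$B[i])))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Read annotations from the package JSON schema
#' @param path path to a JSON file written by [writeAnnotations()].
#' @return An annotation data.frame.
#' @export
readJsonAnnotations <- function(path) {
  obj <- jsonlite::read_json(path)
  rows <- list()
  for (sl in obj$slices) {
    for (bx in sl$boxes) {
      ltrb <- as.numeric(unlist(bx$ltrb))
      sc <- if (is.null(bx$score)) NA_real_ else as.numeric(bx$score)
      rows[[length(rows) + 1L]] <- annotationFrame(
        slice = if (sl$index < 0) NA_integer_ else sl$index,
        label = bx$label, L = ltrb[1], T = ltrb[2], R = ltrb[3], B = ltrb[4],
        score = sc,
        source = if (is.na(sc)) "ground_truth" else "prediction")
    }
  }
  if (!length(rows)) return(emptyAnnotations())
  do.call(rbind, rows)
}
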