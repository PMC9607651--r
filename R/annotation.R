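#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an image calibration
#'
#' @param spacingX,spacingY pixel spacing in mm/pixel
#' @param widthPx,heightPx image dimensions in pixels
#' @return an \linkS4class{ImageCalibration}
#' @export
ImageCalibration <- function(spacingX, spacingY, widthPx, heightPx) {
  new("ImageCalibration", spacingX = as.numeric(spacingX),
      spacingY = as.numeric(spacingY), widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx))
}

#' Construct a wall axis
#'
#' @param wall "anterior" or "posterior"
#' @param points n x 2 numeric matrix of mm coordinates, cranio-caudal order
#' @return a \linkS4class{WallAxis}
#' @export
WallAxis <- function(wall, points) {
  new("WallAxis", wall = wall, points = unname(as.matrix(points)))
}

#' Construct a calcified tract
#'
#' @param wall "anterior" or "posterior"
#' @param points n x 2 numeric matrix of mm coordinates
#' @return a \linkS4class{CalcifiedTract}
#' @export
CalcifiedTract <- function(wall, points) {
  new("CalcifiedTract", wall = wall, points = unname(as.matrix(points)))
}

#' Construct a full radiograph annotation
#'
#' @param subjectId,operatorId identifiers
#' @param repetition integer >= 1
#' @param calibration an \linkS4class{ImageCalibration}
#' @param boundaries data.frame with columns label, x0, y0, x1, y1 (mm),
#'   the five labels T12-L1 ... L4-L5 in cranio-caudal order
#' @param walls list of two \linkS4class{WallAxis} (anterior, posterior)
#' @param tracts list of \linkS4class{CalcifiedTract}; may be empty
#' @param svScore optional operator-entered visual score, integer in [0, 24]
#' @return an \linkS4class{AortaAnnotation}
#' @export
AortaAnnotation <- function(subjectId, operatorId, repetition, calibration,
                            boundaries, walls, tracts = list(),
                            svScore = NA_integer_) {
  boundaries$label <- as.character(boundaries$label)
  new("AortaAnnotation", subjectId = as.character(subjectId),
      operatorId = as.character(operatorId),
      repetition = as.integer(repetition), calibration = calibration,
      boundaries = boundaries, walls = walls, tracts = tracts,
      svScore = as.integer(svScore))
}

#' Annotation accessors
#'
#' Read the components of an \linkS4class{AortaAnnotation} (and, for the
#' provenance fields, of a \linkS4class{ScoreTriple}).
#'
#' @param x an \linkS4class{AortaAnnotation} or \linkS4class{ScoreTriple}
#' @param wall "anterior" or "posterior"
#' @name AortaAnnotation-accessors
NULL

#' @rdname AortaAnnotation-accessors
#' @export
setMethod("subjectId", "AortaAnnotation", function(x) x@subjectId)
#' @rdname AortaAnnotation-accessors
#' @export
setMethod("operatorId", "AortaAnnotation", function(x) x@operatorId)
#' @rdname AortaAnnotation-accessors
#' @export
setMethod("repetition", "AortaAnnotation", function(x) x@repetition)
#' @rdname AortaAnnotation-accessors
#' @export
setMethod("svScore", "AortaAnnotation", function(x) x@svScore)
#' @rdname AortaAnnotation-accessors
#' @export
setMethod("calibration", "AortaAnnotation", function(x) x@calibration)
#' @rdname AortaAnnotation-accessors
#' @export
setMethod("boundaryLines", "AortaAnnotation", function(x) x@boundaries)

#' @rdname AortaAnnotation-accessors
#' @export
setMethod("wallAxis", "AortaAnnotation", function(x, wall) {
  wall <- match.arg(wall, AAC_WALLS)
  for (w in x@walls) if (w@wall == wall) return(w)
  stop(sprintf("no %s wall axis", wall))
})

#' @rdname AortaAnnotation-accessors
#' @export
setMethod("calcifiedTracts", "AortaAnnotation", function(x, wall) {
  if (missing(wall)) return(x@tracts)
  wall <- match.arg(wall, AAC_WALLS)
  Filter(function(tr) tr@wall == wall, x@tracts)
})

#' @rdname AortaAnnotation-accessors
#' @export
setMethod("subjectId", "ScoreTriple", function(x) x@subjectId)
#' @rdname AortaAnnotation-accessors
#' @export
setMethod("operatorId", "ScoreTriple", function(x) x@operatorId)
#' @rdname AortaAnnotation-accessors
#' @export
setMethod("repetition", "ScoreTriple", function(x) x@repetition)
#' @rdname AortaAnnotation-accessors
#' @export
setMethod("svScore", "ScoreTriple", function(x) x@sv)

setMethod("show", "AortaAnnotation", function(object) {
  nt <- length(object@tracts)
  cat(sprintf("AortaAnnotation  subject %s  operator %s  repetition %d\n",
              object@subjectId, object@operatorId, object@repetition))
  cat(sprintf("  calibration: %.3f x %.3f mm/px, %d x %d px\n",
              object@calibration@spacingX, object@calibration@spacingY,
              object@calibration@widthPx, object@calibration@heightPx))
  cat(sprintf("  boundaries: %s\n", paste(object@boundaries$label, collapse = ", ")))
  for (w in object@walls)
    cat(sprintf("  %s wall axis: %d points, %.1f mm\n", w@wall, nrow(w@points),
                max(polylineArcLengths(w@points))))
  cat(sprintf("  calcified tracts: %d  |  SV score: %s\n", nt,
              ifelse(is.na(object@svScore), "not entered", object@svScore)))
})

setMethod("show", "ScoreTriple", function(object) {
  cat(sprintf("ScoreTriple  subject %s  operator %s  repetition %d\n",
              object@subjectId, object@operatorId, object@repetition))
  cat(sprintf("  QC (native): %.4f   QC (0-24): %.4f\n", object@qcNative, object@qc))
  cat(sprintf("  SC: %d   SV: %s\n", object@sc,
              ifelse(is.na(object@sv), "not entered", object@sv)))
  m <- rbind(fraction = round(object@segmentFractions, 4),
             tertile = object@segmentTertiles)
  colnames(m) <- names(object@segmentFractions)
  print(m)
})

.jsonFail <- function(path, what) {
  stop(sprintf("invalid annotation at %s: %s", path, what), call. = FALSE)
}

.jsonPoints <- function(x, path) {
  if (is.null(x)) .jsonFail(path, "missing points")
  m <- if (is.matrix(x)) x else do.call(rbind, x)
  if (!is.numeric(m) || ncol(m) != 2) .jsonFail(path, "points must be pairs of numbers")
  m
}

#' Read an annotation JSON file
#'
#' One JSON document per annotation, with top-level keys subject_id,
#' operator_id, repetition, calibration \{spacing_x_mm, spacing_y_mm,
#' width_px, height_px\}, boundaries (array of 5 \{label, p0, p1\} in mm),
#' walls (array of 2 \{wall, points\}), tracts (array of \{wall, points\})
#' and optional sv_score.  All class invariants are validated; the first
#' violation is reported with its JSON path.
#'
#' @param path file path
#' @return an \linkS4class{AortaAnnotation}
#' @export
readAnnotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                           simplifyDataFrame = FALSE)
  for (key in c("subject_id", "operator_id", "repetition", "calibration",
                "boundaries", "walls"))
    if (is.null(j[[key]])) .jsonFail(paste0("$.", key), "missing")
  cal <- j$calibration
  for (key in c("spacing_x_mm", "spacing_y_mm", "width_px", "height_px"))
    if (is.null(cal[[key]])) .jsonFail(paste0("$.calibration.", key), "missing")
  calibration <- tryCatch(
    ImageCalibration(cal$spacing_x_mm, cal$spacing_y_mm, cal$width_px, cal$height_px),
    error = function(e) .jsonFail("$.calibration", conditionMessage(e)))
  if (length(j$boundaries) != 5L)
    .jsonFail("$.boundaries", "need exactly 5 boundary lines")
  bl <- do.call(rbind, lapply(seq_along(j$boundaries), function(i) {
    b <- j$boundaries[[i]]
    p <- paste0("$.boundaries[", i, "]")
    if (is.null(b$label) || is.null(b$p0) || is.null(b$p1))
      .jsonFail(p, "needs label, p0, p1")
    if (length(b$p0) != 2 || length(b$p1) != 2)
      .jsonFail(p, "p0/p1 must be [x, y]")
    data.frame(label = b$label, x0 = b$p0[1], y0 = b$p0[2],
               x1 = b$p1[1], y1 = b$p1[2])
  }))
  walls <- lapply(seq_along(j$walls), function(i) {
    w <- j$walls[[i]]
    p <- paste0("$.walls[", i, "]")
    if (is.null(w$wall)) .jsonFail(p, "missing wall label")
    tryCatch(WallAxis(w$wall, .jsonPoints(w$points, p)),
             error = function(e) .jsonFail(p, conditionMessage(e)))
  })
  tracts <- lapply(seq_along(j$tracts), function(i) {
    tr <- j$tracts[[i]]
    p <- paste0("$.tracts[", i, "]")
    if (is.null(tr$wall)) .jsonFail(p, "missing wall label")
    tryCatch(CalcifiedTract(tr$wall, .jsonPoints(tr$points, p)),
             error = function(e) .jsonFail(p, conditionMessage(e)))
  })
  sv <- if (is.null(j$sv_score)) NA_integer_ else as.integer(j$sv_score)
  tryCatch(
    AortaAnnotation(j$subject_id, j$operator_id, j$repetition, calibration,
                    bl, walls, tracts, sv),
    error = function(e) .jsonFail("$", conditionMessage(e)))
}

#' Write an annotation to JSON
#'
#' Inverse of \code{\link{readAnnotation}}.
#'
#' @param annotation an \linkS4class{AortaAnnotation}
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeAnnotation <- function(annotation, path) {
  b <- annotation@boundaries
  doc <- list(
    subject_id = annotation@subjectId,
    operator_id = annotation@operatorId,
    repetition = annotation@repetition,
    calibration = list(spacing_x_mm = annotation@calibration@spacingX,
                       spacing_y_mm = annotation@calibration@spacingY,
                       width_px = annotation@calibration@widthPx,
                       height_px = annotation@calibration@heightPx),
    boundaries = lapply(seq_len(nrow(b)), function(i)
      list(label = b$label[i], p0 = c(b$x0[i], b$y0[i]), p1 = c(b$x1[i], b$y1[i]))),
    walls = lapply(annotation@walls, function(w)
      list(wall = w@wall, points = unname(w@points))),
    tracts = lapply(annotation@tracts, function(tr)
      list(wall = tr@wall, points = unname(tr@points))))
  if (!is.na(annotation@svScore)) doc$sv_score <- annotation@svScore
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
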