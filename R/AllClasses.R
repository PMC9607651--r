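#' @import methods
NULL

#' Intervertebral boundary labels, cranio-caudal order
#'
#' The five disc-space boundary lines delimiting the scoring region and the
#' four vertebral tracts: T12-L1 down to L4-L5.
#' @export
AAC_BOUNDARY_LABELS <- c("T12-L1", "L1-L2", "L2-L3", "L3-L4", "L4-L5")

#' Vertebral tract (segment) labels
#'
#' The four aortic tracts, each in front of one lumbar vertebra, obtained by
#' partitioning the wall axis at the five boundary lines.
#' @export
AAC_SEGMENT_LABELS <- c("L1", "L2", "L3", "L4")

#' Wall labels
#' @export
AAC_WALLS <- c("anterior", "posterior")

.validPointMatrix <- function(points, what) {
  if (!is.matrix(points) || !is.numeric(points) || ncol(points) != 2L)
    return(sprintf("%s: points must be a numeric matrix with 2 columns", what))
  if (nrow(points) < 2L)
    return(sprintf("%s: polyline needs at least 2 points", what))
  if (any(!is.finite(points)))
    return(sprintf("%s: points must be finite", what))
  d <- diff(points)
  if (any(rowSums(d^2) == 0))
    return(sprintf("%s: consecutive points must be distinct", what))
  TRUE
}

#' Image calibration of a radiograph
#'
#' Pixel spacing (mm/pixel) and pixel dimensions of a calibrated lateral
#' lumbar-spine radiograph.  All annotation geometry is stored in image-space
#' millimetres (pixel indices times spacing, origin top-left, y growing
#' caudally), so scores are independent of the calibration beyond the stored
#' spacing itself.
#'
#' @slot spacingX,spacingY pixel spacing in mm/pixel, strictly positive
#' @slot widthPx,heightPx image dimensions in pixels, strictly positive
#' @export
setClass("ImageCalibration",
  representation(spacingX = "numeric", spacingY = "numeric",
                 widthPx = "integer", heightPx = "integer"))

setValidity("ImageCalibration", function(object) {
  msg <- character()
  if (length(object@spacingX) != 1L || !is.finite(object@spacingX) || object@spacingX <= 0)
    msg <- c(msg, "spacingX must be a single strictly positive number")
  if (length(object@spacingY) != 1L || !is.finite(object@spacingY) || object@spacingY <= 0)
    msg <- c(msg, "spacingY must be a single strictly positive number")
  if (length(object@widthPx) != 1L || is.na(object@widthPx) || object@widthPx <= 0L)
    msg <- c(msg, "widthPx must be a single strictly positive integer")
  if (length(object@heightPx) != 1L || is.na(object@heightPx) || object@heightPx <= 0L)
    msg <- c(msg, "heightPx must be a single strictly positive integer")
  if (length(msg)) msg else TRUE
})

#' Aortic wall axis
#'
#' The anterior or posterior arterial wall drawn as an ordered polyline in mm,
#' oriented cranio-caudal.  Calcified tracts are reduced to arc-length
#' intervals on this axis before scoring.
#'
#' @slot wall "anterior" or "posterior"
#' @slot points ordered 2-column numeric matrix (x, y in mm), >= 2 rows,
#'   consecutive points distinct
#' @export
setClass("WallAxis", representation(wall = "character", points = "matrix"))

setValidity("WallAxis", function(object) {
  msg <- character()
  if (length(object@wall) != 1L || !object@wall %in% AAC_WALLS)
    msg <- c(msg, "wall must be one of \"anterior\", \"posterior\"")
  v <- .validPointMatrix(object@points, "WallAxis")
  if (!isTRUE(v)) msg <- c(msg, v)
  if (length(msg)) msg else TRUE
})

#' Operator-drawn calcified tract
#'
#' One contiguous calcified stretch drawn as a polyline and assigned to one
#' wall.  Distinct calcified stretches are distinct tracts; gaps within one
#' drawing are not inferred.
#'
#' @slot wall "anterior" or "posterior"
#' @slot points ordered 2-column numeric matrix (x, y in mm), >= 2 rows
#' @export
setClass("CalcifiedTract", representation(wall = "character", points = "matrix"))

setValidity("CalcifiedTract", function(object) {
  msg <- character()
  if (length(object@wall) != 1L || !object@wall %in% AAC_WALLS)
    msg <- c(msg, "wall must be one of \"anterior\", \"posterior\"")
  v <- .validPointMatrix(object@points, "CalcifiedTract")
  if (!isTRUE(v)) msg <- c(msg, v)
  if (length(msg)) msg else TRUE
})

#' Full annotation of one radiograph
#'
#' One subject/operator/repetition's complete geometric annotation: image
#' calibration, the five intervertebral boundary lines (T12-L1 ... L4-L5),
#' one anterior and one posterior wall axis, the drawn calcified tracts, and
#' the optional operator-entered visual (SV) score.
#'
#' @slot subjectId,operatorId identifiers
#' @slot repetition integer >= 1
#' @slot calibration an \linkS4class{ImageCalibration}
#' @slot boundaries data.frame with columns label, x0, y0, x1, y1 (mm); the
#'   five labels of \code{AAC_BOUNDARY_LABELS} exactly once each, ordered
#'   cranio-caudal (mean y strictly increasing)
#' @slot walls list of exactly two \linkS4class{WallAxis}, one anterior and
#'   one posterior
#' @slot tracts list of \linkS4class{CalcifiedTract} (possibly empty)
#' @slot svScore integer in [0, 24], or NA when the operator entered none
#' @export
setClass("AortaAnnotation",
  representation(subjectId = "character", operatorId = "character",
                 repetition = "integer", calibration = "ImageCalibration",
                 boundaries = "data.frame", walls = "list", tracts = "list",
                 svScore = "integer"))

setValidity("AortaAnnotation", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || is.na(object@subjectId) || !nzchar(object@subjectId))
    msg <- c(msg, "subjectId must be a non-empty string")
  if (length(object@operatorId) != 1L || is.na(object@operatorId) || !nzchar(object@operatorId))
    msg <- c(msg, "operatorId must be a non-empty string")
  if (length(object@repetition) != 1L || is.na(object@repetition) || object@repetition < 1L)
    msg <- c(msg, "repetition must be a single integer >= 1")
  b <- object@boundaries
  need <- c("label", "x0", "y0", "x1", "y1")
  if (!is.data.frame(b) || !all(need %in% names(b))) {
    msg <- c(msg, "boundaries must be a data.frame with columns label, x0, y0, x1, y1")
  } else if (nrow(b) != 5L || !identical(as.character(b$label), AAC_BOUNDARY_LABELS)) {
    msg <- c(msg, sprintf("boundaries must carry the five labels %s exactly once, in order",
                          paste(AAC_BOUNDARY_LABELS, collapse = ", ")))
  } else {
    if (any(b$x0 == b$x1 & b$y0 == b$y1))
      msg <- c(msg, "each boundary line needs two distinct points")
    ymid <- (b$y0 + b$y1) / 2
    if (any(diff(ymid) <= 0))
      msg <- c(msg, "boundary lines must be ordered cranio-caudal (mean y strictly increasing)")
  }
  if (length(object@walls) != 2L ||
      !all(vapply(object@walls, is, TRUE, "WallAxis"))) {
    msg <- c(msg, "walls must be a list of exactly two WallAxis objects")
  } else {
    wl <- sort(vapply(object@walls, function(w) w@wall, ""))
    if (!identical(wl, sort(AAC_WALLS)))
      msg <- c(msg, "walls must contain one anterior and one posterior axis")
  }
  if (length(object@tracts) &&
      !all(vapply(object@tracts, is, TRUE, "CalcifiedTract")))
    msg <- c(msg, "tracts must be a list of CalcifiedTract objects")
  sv <- object@svScore
  if (length(sv) != 1L || (!is.na(sv) && (sv < 0L || sv > 24L)))
    msg <- c(msg, "svScore must be a single integer in [0, 24] or NA")
  if (length(msg)) msg else TRUE
})

#' Score triple for one annotation
#'
#' The three abdominal-aortic-calcification scores computed from one
#' annotation: the quantitative continuum score (native 0-1 and rescaled
#' 0-24), the back-calculated semiquantitative score (sum of eight per-segment
#' tertiles), and the operator's visual score when entered.  The per-segment
#' calcified fractions and their tertiles (anterior/posterior x L1..L4) are
#' retained for inspection.
#'
#' @slot qcNative relative calcified length in [0, 1]
#' @slot qc 24 x qcNative, never rounded
#' @slot sc integer in [0, 24], sum of the eight tertiles
#' @slot sv integer in [0, 24] or NA (echoed operator input)
#' @slot segmentFractions named numeric of length 8 in [0, 1]
#' @slot segmentTertiles named integer of length 8 in {0, 1, 2, 3}
#' @slot subjectId,operatorId,repetition provenance copied from the annotation
#' @export
setClass("ScoreTriple",
  representation(qcNative = "numeric", qc = "numeric", sc = "integer",
                 sv = "integer", segmentFractions = "numeric",
                 segmentTertiles = "integer", subjectId = "character",
                 operatorId = "character", repetition = "integer"))

setValidity("ScoreTriple", function(object) {
  msg <- character()
  if (object@qcNative < 0 || object@qcNative > 1)
    msg <- c(msg, "qcNative must lie in [0, 1]")
  if (abs(object@qc - 24 * object@qcNative) > 1e-9)
    msg <- c(msg, "qc must equal 24 * qcNative")
  if (is.na(object@sc) || object@sc < 0L || object@sc > 24L)
    msg <- c(msg, "sc must be an integer in [0, 24]")
  if (!is.na(object@sv) && (object@sv < 0L || object@sv > 24L))
    msg <- c(msg, "sv must be an integer in [0, 24] or NA")
  if (length(object@segmentFractions) != 8L || any(object@segmentFractions < 0) ||
      any(object@segmentFractions > 1))
    msg <- c(msg, "segmentFractions must be 8 values in [0, 1]")
  if (length(object@segmentTertiles) != 8L ||
      !all(object@segmentTertiles %in% 0:3))
    msg <- c(msg, "segmentTertiles must be 8 values in {0, 1, 2, 3}")
  if (object@sc != sum(object@segmentTertiles))
    msg <- c(msg, "sc must equal the sum of segmentTertiles")
  if (length(msg)) msg else TRUE
})
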