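#' @include AllClasses.R AllGenerics.R geometry.R annotation.R
NULL

# Relative fractions below this are treated as exactly zero when mapping to
# tertiles, absorbing floating-point dust from the interval arithmetic.
.FRACTION_EPS <- 1e-9

#' Reduce one wall of an annotation to scored geometry
#'
#' Projects the wall's calcified tracts onto its axis, clips the resulting
#' arc intervals to the scoring region [b0, b4) between the T12-L1 and L4-L5
#' boundaries, and merges overlaps.
#'
#' @param annotation an \linkS4class{AortaAnnotation}
#' @param wall "anterior" or "posterior"
#' @return list with \code{positions} (the five boundary arc positions),
#'   \code{region} (c(b0, b4)), \code{segments} (4 x 2 matrix from
#'   \code{\link{segmentPartition}}) and \code{calcified} (merged clipped
#'   interval matrix)
#' @export
wallGeometry <- function(annotation, wall) {
  axis <- wallAxis(annotation, wall)
  pos <- boundaryPositions(axis, annotation@boundaries)
  b0 <- pos[[1]]; b4 <- pos[[5]]
  if (b4 <= b0) stop("degenerate aorta region")
  iv <- lapply(calcifiedTracts(annotation, wall), projectTract, axis = axis)
  iv <- do.call(rbind, c(list(emptyIntervals()), iv))
  calc <- mergeIntervals(clipIntervals(iv, b0, b4))
  list(positions = pos, region = c(b0, b4),
       segments = segmentPartition(pos), calcified = calc)
}

#' Quantitative calcification scores
#'
#' \code{qcNative} is the relative calcified length of the abdominal aorta:
#' the summed merged calcified length on the two walls, clipped to the
#' T12-L1 ... L4-L5 region, divided by the summed region lengths of the two
#' walls.  It lies in [0, 1]: 0 with no calcification, 1 when both walls are
#' fully covered.  \code{qcScore} rescales it to the 0-24 Kauppila range
#' (24 x qcNative, never rounded) for direct comparison with the visual
#' score.
#'
#' @param x an \linkS4class{AortaAnnotation} or a \linkS4class{ScoreTriple}
#' @return a single numeric value
#' @name qcNative
NULL

#' @rdname qcNative
#' @export
setMethod("qcNative", "AortaAnnotation", function(x) {
  num <- den <- 0
  for (wall in AAC_WALLS) {
    g <- wallGeometry(x, wall)
    num <- num + intervalLength(g$calcified)
    den <- den + (g$region[2] - g$region[1])
  }
  if (den <= 0) stop("degenerate aorta region")
  min(num / den, 1)
})

#' @rdname qcNative
#' @export
setMethod("qcScore", "AortaAnnotation", function(x) 24 * qcNative(x))

#' @rdname qcNative
#' @export
setMethod("qcNative", "ScoreTriple", function(x) x@qcNative)

#' @rdname qcNative
#' @export
setMethod("qcScore", "ScoreTriple", function(x) x@qc)

#' Kauppila tertile map
#'
#' Maps a calcified fraction of one wall-segment to its tertile score:
#' absent = 0, less than 1/3 = 1, from 1/3 to 2/3 = 2 (edges closed), more
#' than 2/3 = 3.  Fractions below 1e-9 count as absent.
#'
#' @param f calcified fraction(s) in [0, 1]
#' @return integer tertile(s) in \{0, 1, 2, 3\}
#' @export
tertileMap <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1 + .FRACTION_EPS))
    stop("invalid fraction")
  f <- pmin(f, 1)
  out <- integer(length(f))
  out[f > .FRACTION_EPS] <- 1L
  out[f >= 1 / 3] <- 2L
  out[f > 2 / 3] <- 3L
  out
}

#' Per-segment calcified fractions and tertiles
#'
#' For each wall (anterior, posterior) and each vertebral tract (L1..L4),
#' \code{segmentFractions} returns calcified length within the segment
#' divided by segment length.  \code{segmentTertiles} applies the Kauppila
#' tertile map to those eight fractions.
#'
#' @param x an \linkS4class{AortaAnnotation} or a \linkS4class{ScoreTriple}
#' @return named vector of length 8 (names like "anterior_L2")
#' @name segmentFractions
NULL

#' @rdname segmentFractions
#' @export
setMethod("segmentFractions", "AortaAnnotation", function(x) {
  out <- numeric(0)
  for (wall in AAC_WALLS) {
    g <- wallGeometry(x, wall)
    fr <- vapply(seq_len(nrow(g$segments)), function(i) {
      seg <- g$segments[i, ]
      segLen <- seg[2] - seg[1]
      if (segLen <= 0)
        stop(sprintf("degenerate segment %s, %s", wall, rownames(g$segments)[i]))
      min(intervalLength(clipIntervals(g$calcified, seg[1], seg[2])) / segLen, 1)
    }, 0)
    names(fr) <- paste(wall, rownames(g$segments), sep = "_")
    out <- c(out, fr)
  }
  out
})

#' @rdname segmentFractions
#' @export
setMethod("segmentFractions", "ScoreTriple", function(x) x@segmentFractions)

#' @rdname segmentFractions
#' @export
setMethod("segmentTertiles", "AortaAnnotation", function(x) {
  fr <- segmentFractions(x)
  out <- tertileMap(fr)
  names(out) <- names(fr)
  out
})

#' @rdname segmentFractions
#' @export
setMethod("segmentTertiles", "ScoreTriple", function(x) x@segmentTertiles)

#' Back-calculated semiquantitative (SC) score
#'
#' The Kauppila rules applied to the computer-traced calcified fractions:
#' the sum over the eight wall-segments of the tertile map, an integer in
#' [0, 24].  This isolates the effect of discretisation from that of visual
#' estimation.
#'
#' @param x an \linkS4class{AortaAnnotation} or a \linkS4class{ScoreTriple}
#' @return integer in [0, 24]
#' @name scScore
NULL

#' @rdname scScore
#' @export
setMethod("scScore", "AortaAnnotation", function(x) sum(segmentTertiles(x)))

#' @rdname scScore
#' @export
setMethod("scScore", "ScoreTriple", function(x) x@sc)

#' Compute all three scores for an annotation
#'
#' Assembles the quantitative score (native and 0-24), the back-calculated
#' semiquantitative score with its per-segment fractions and tertiles, and
#' echoes the operator-entered visual score when present.
#'
#' @param x an \linkS4class{AortaAnnotation}
#' @return a \linkS4class{ScoreTriple}
#' @name scoreTriple
NULL

#' @rdname scoreTriple
#' @export
setMethod("scoreTriple", "AortaAnnotation", function(x) {
  fr <- segmentFractions(x)
  tert <- tertileMap(fr)
  names(tert) <- names(fr)
  qn <- qcNative(x)
  new("ScoreTriple", qcNative = qn, qc = 24 * qn, sc = sum(tert),
      sv = x@svScore, segmentFractions = fr, segmentTertiles = tert,
      subjectId = x@subjectId, operatorId = x@operatorId,
      repetition = x@repetition)
})

#' One scores-CSV row for a score triple
#'
#' @param triple a \linkS4class{ScoreTriple}
#' @return one-row data.frame with subject_id, operator_id, repetition,
#'   qc_native, qc, sc, sv, eight fraction columns (frac_<wall>_<seg>) and
#'   eight tertile columns (tert_<wall>_<seg>)
#' @export
scoreRow <- function(triple) {
  fr <- as.list(triple@segmentFractions)
  names(fr) <- paste0("frac_", names(triple@segmentFractions))
  tt <- as.list(triple@segmentTertiles)
  names(tt) <- paste0("tert_", names(triple@segmentTertiles))
  cbind(data.frame(subject_id = triple@subjectId,
                   operator_id = triple@operatorId,
                   repetition = triple@repetition,
                   qc_native = triple@qcNative, qc = triple@qc,
                   sc = triple@sc, sv = triple@sv),
        as.data.frame(fr), as.data.frame(tt))
}

#' Convert score rows to the long measurement-table format
#'
#' Expands a scores data.frame (as written by \code{\link{scoreRow}}) into
#' the long format consumed by the reliability statistics: one row per
#' (subject, operator, repetition, score type), QC on the 0-24 scale.
#' Rows lacking an SV entry contribute no SV record.
#'
#' @param scores data.frame of score rows
#' @return long data.frame with columns subject_id, operator_id, repetition,
#'   score_type, value
#' @export
scoresToMeasurementTable <- function(scores) {
  base <- scores[c("subject_id", "operator_id", "repetition")]
  out <- rbind(
    cbind(base, score_type = "QC", value = scores$qc),
    cbind(base, score_type = "SC", value = as.numeric(scores$sc)),
    cbind(base, score_type = "SV", value = as.numeric(scores$sv)))
  out <- out[!is.na(out$value), ]
  rownames(out) <- NULL
  out
}
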