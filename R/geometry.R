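# Planar polyline and arc-length interval primitives.
#
# All geometry lives in image-space millimetres.  A polyline is an n x 2
# numeric matrix (x, y); an interval set is an m x 2 matrix with columns
# start, end, each row a half-open interval [start, end) of arc-length
# positions on a wall axis.

#' Cumulative arc length of a polyline
#'
#' @param points n x 2 numeric matrix
#' @return numeric vector of length n; position 0 at the first vertex
#' @keywords internal
polylineArcLengths <- function(points) {
  c(0, cumsum(sqrt(rowSums(diff(points)^2))))
}

#' Interpolate points at arc-length positions along a polyline
#'
#' @param points n x 2 polyline
#' @param s arc-length positions, clamped to [0, total length]
#' @return length(s) x 2 matrix of interpolated points
#' @keywords internal
polylinePointAt <- function(points, s) {
  cum <- polylineArcLengths(points)
  s <- pmin(pmax(s, 0), cum[length(cum)])
  x <- stats::approx(cum, points[, 1], xout = s, ties = "ordered")$y
  y <- stats::approx(cum, points[, 2], xout = s, ties = "ordered")$y
  cbind(x, y, deparse.level = 0)
}

#' Empty interval set
#' @keywords internal
emptyIntervals <- function() {
  matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

asIntervals <- function(x) {
  if (is.null(x) || length(x) == 0) return(emptyIntervals())
  m <- matrix(as.numeric(x), ncol = 2)
  colnames(m) <- c("start", "end")
  m
}

#' Arc-length positions of the five boundary lines on a wall axis
#'
#' Intersects each boundary's infinite line with the axis polyline and
#' returns the arc-length position of the intersection.  When a line crosses
#' the polyline more than once the most cranial intersection (smallest arc
#' length) is taken.
#'
#' @param axis a \linkS4class{WallAxis} or an n x 2 polyline matrix
#' @param boundaries data.frame with columns label, x0, y0, x1, y1 in
#'   cranio-caudal order (see \linkS4class{AortaAnnotation})
#' @return named numeric of length 5, strictly increasing, one arc-length
#'   position (mm) per boundary in label order
#' @export
boundaryPositions <- function(axis, boundaries) {
  pts <- if (is(axis, "WallAxis")) axis@points else axis
  wall <- if (is(axis, "WallAxis")) axis@wall else "wall"
  cum <- polylineArcLengths(pts)
  pos <- vapply(seq_len(nrow(boundaries)), function(i) {
    q0 <- c(boundaries$x0[i], boundaries$y0[i])
    d <- c(boundaries$x1[i] - q0[1], boundaries$y1[i] - q0[2])
    # signed side of each vertex w.r.t. the infinite boundary line
    side <- d[1] * (pts[, 2] - q0[2]) - d[2] * (pts[, 1] - q0[1])
    n <- nrow(pts)
    s0 <- side[-n]; s1 <- side[-1]
    hit <- which(s0 * s1 < 0 | s0 == 0 | (s1 == 0 & s0 != 0))
    if (!length(hit))
      stop(sprintf("axis does not span boundary %s", boundaries$label[i]))
    arcs <- vapply(hit, function(k) {
      if (s0[k] == s1[k]) return(cum[k])  # segment collinear with the line
      t <- s0[k] / (s0[k] - s1[k])
      cum[k] + t * (cum[k + 1] - cum[k])
    }, 0)
    min(arcs)
  }, 0)
  names(pos) <- as.character(boundaries$label)
  if (any(diff(pos) <= 0))
    stop(sprintf("boundary order violated on wall %s", wall))
  pos
}

#' Project a calcified tract onto its wall axis
#'
#' Every tract vertex is projected to its nearest point on the axis polyline;
#' the tract's arc-length interval is the [min, max] hull of the projected
#' positions.  A tract whose vertices all project to one point yields an
#' empty interval set carrying attribute \code{zeroWidth = TRUE}.
#'
#' @param tract a \linkS4class{CalcifiedTract} or polyline matrix
#' @param axis a \linkS4class{WallAxis} or polyline matrix; when both carry a
#'   wall label the labels must agree
#' @return 1 x 2 (or 0 x 2) interval matrix with columns start, end
#' @export
projectTract <- function(tract, axis) {
  if (is(tract, "CalcifiedTract") && is(axis, "WallAxis") &&
      tract@wall != axis@wall)
    stop("tract/axis wall labels differ")
  tp <- if (is(tract, "CalcifiedTract")) tract@points else tract
  ap <- if (is(axis, "WallAxis")) axis@points else axis
  arcs <- projectPoints(tp, ap)$arc
  lo <- min(arcs); hi <- max(arcs)
  if (hi - lo <= 1e-9) {
    out <- emptyIntervals()
    attr(out, "zeroWidth") <- TRUE
    return(out)
  }
  out <- asIntervals(c(lo, hi))
  attr(out, "zeroWidth") <- FALSE
  out
}

#' Nearest-point projection of points onto a polyline
#'
#' @param points m x 2 query points
#' @param poly n x 2 polyline
#' @return list with \code{arc} (arc-length positions of the nearest points)
#'   and \code{dist} (distances); first nearest segment wins on ties
#' @keywords internal
projectPoints <- function(points, poly) {
  cum <- polylineArcLengths(poly)
  n <- nrow(poly)
  a <- poly[-n, , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  arc <- dist <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    ap <- cbind(points[i, 1] - a[, 1], points[i, 2] - a[, 2])
    t <- pmin(pmax((ap[, 1] * ab[, 1] + ap[, 2] * ab[, 2]) / len2, 0), 1)
    dx <- ap[, 1] - t * ab[, 1]
    dy <- ap[, 2] - t * ab[, 2]
    d2 <- dx^2 + dy^2
    k <- which.min(d2)
    arc[i] <- cum[k] + t[k] * (cum[k + 1] - cum[k])
    dist[i] <- sqrt(d2[k])
  }
  list(arc = arc, dist = dist)
}

#' Clip intervals to the scoring region
#'
#' Intersects each half-open interval with [b0, b4); intervals falling fully
#' outside the region are dropped (calcified tracts beyond the T12-L1 or
#' L4-L5 boundary are ignored by the scores).
#'
#' @param intervals m x 2 interval matrix
#' @param b0,b4 region bounds in arc length (mm), b0 < b4
#' @return clipped interval matrix
#' @export
clipIntervals <- function(intervals, b0, b4) {
  stopifnot(b0 < b4)
  intervals <- asIntervals(intervals)
  if (!nrow(intervals)) return(emptyIntervals())
  lo <- pmax(intervals[, 1], b0)
  hi <- pmin(intervals[, 2], b4)
  keep <- hi > lo
  asIntervals(cbind(lo[keep], hi[keep]))
}

#' Merge intervals into a disjoint sorted union
#'
#' Returns the union of half-open intervals as maximal disjoint intervals.
#' Adjacent intervals ([0,5) and [5,10)) merge; overlapping drawings are
#' never double-counted.
#'
#' @param intervals m x 2 interval matrix
#' @return sorted disjoint interval matrix
#' @export
mergeIntervals <- function(intervals) {
  intervals <- asIntervals(intervals)
  intervals <- intervals[intervals[, 2] > intervals[, 1], , drop = FALSE]
  if (nrow(intervals) <= 1L) return(asIntervals(intervals))
  o <- order(intervals[, 1], intervals[, 2])
  s <- intervals[o, 1]; e <- intervals[o, 2]
  outS <- s[1]; outE <- e[1]
  for (i in seq_along(s)[-1]) {
    j <- length(outE)
    if (s[i] <= outE[j]) {
      outE[j] <- max(outE[j], e[i])
    } else {
      outS <- c(outS, s[i]); outE <- c(outE, e[i])
    }
  }
  asIntervals(cbind(outS, outE))
}

#' Total length of an interval set
#' @param intervals m x 2 interval matrix
#' @return sum of interval widths (mm); merge first if overlaps are possible
#' @export
intervalLength <- function(intervals) {
  intervals <- asIntervals(intervals)
  if (!nrow(intervals)) return(0)
  sum(intervals[, 2] - intervals[, 1])
}

#' Partition the scoring region into the four vertebral tracts
#'
#' @param positions strictly increasing arc-length positions b0..b4 of the
#'   five boundary lines
#' @return 4 x 2 interval matrix with rows named L1..L4: [b0,b1), [b1,b2),
#'   [b2,b3), [b3,b4), the aortic tract in front of each vertebra
#' @export
segmentPartition <- function(positions) {
  if (length(positions) != 5L || any(diff(positions) <= 0))
    stop("degenerate partition")
  out <- cbind(start = positions[1:4], end = positions[2:5])
  rownames(out) <- AAC_SEGMENT_LABELS
  out
}
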