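# Polyline reductions: boundary intersection, projection, interval algebra.

horizontalBoundaries <- function(ys, x0 = -5, x1 = 15) {
  data.frame(label = AAC_BOUNDARY_LABELS, x0 = x0, y0 = ys, x1 = x1, y1 = ys)
}

test_that("boundary positions on straight axes follow elementary geometry", {
  b <- horizontalBoundaries(c(10, 30, 50, 70, 90))
  vertical <- rbind(c(0, 0), c(0, 100))
  expect_equal(unname(boundaryPositions(vertical, b)), c(10, 30, 50, 70, 90))
  diag45 <- rbind(c(0, 0), c(100, 100))
  expect_equal(unname(boundaryPositions(diag45, b)),
               c(10, 30, 50, 70, 90) * sqrt(2))
})

test_that("boundary positions on a bent axis with oblique boundaries match the resampling oracle", {
  axis <- rbind(c(0, 0), c(3, 40), c(-2, 75), c(1, 105))
  ys <- c(12, 31, 52, 68, 93)
  b <- data.frame(label = AAC_BOUNDARY_LABELS,
                  x0 = -6, y0 = ys - 2, x1 = 14, y1 = ys + 3)
  got <- boundaryPositions(axis, b)
  want <- vapply(seq_len(5), function(i)
    oracleBoundaryPosition(axis, c(b$x0[i], b$y0[i]), c(b$x1[i], b$y1[i])), 0)
  expect_equal(unname(got), want, tolerance = 0.02)
})

test_that("multiple crossings resolve to the most cranial intersection", {
  # S-shaped axis crosses the line y = 30 three times
  axis <- rbind(c(0, 0), c(0, 40), c(5, 40), c(5, 20), c(10, 20), c(10, 100))
  b <- horizontalBoundaries(c(10, 30, 50, 70, 90), x0 = -5, x1 = 20)
  pos <- boundaryPositions(axis, b)
  expect_equal(unname(pos[["L1-L2"]]), 30)   # first crossing, not 55 or 85
})

test_that("boundary position failures carry informative errors", {
  b <- horizontalBoundaries(c(10, 30, 50, 70, 90))
  shortAxis <- rbind(c(0, 0), c(0, 50))
  expect_error(boundaryPositions(shortAxis, b), "does not span boundary L3-L4")
  # oblique lines crossing each other: the axis at x = -5 meets the L1-L2
  # line caudally of the L2-L3 line, violating cranio-caudal order
  bBad <- horizontalBoundaries(c(10, 30, 50, 70, 90))
  bBad$y0 <- c(10, 60, 50, 70, 90)
  expect_error(boundaryPositions(rbind(c(-5, 0), c(-5, 100)), bBad),
               "boundary order violated")
})

test_that("boundary positions are invariant under rigid motion", {
  axis <- rbind(c(0, 0), c(3, 40), c(-2, 75), c(1, 105))
  ys <- c(12, 31, 52, 68, 93)
  b <- data.frame(label = AAC_BOUNDARY_LABELS,
                  x0 = -6, y0 = ys - 2, x1 = 14, y1 = ys + 3)
  ref <- unname(boundaryPositions(axis, b))
  for (seed in 1:5) {
    set.seed(seed)
    th <- runif(1, -pi, pi); tx <- runif(1, -50, 50); ty <- runif(1, -50, 50)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rot <- function(m) sweep(m %*% t(R), 2, c(-tx, -ty))
    a2 <- rot(axis)
    p0 <- rot(cbind(b$x0, b$y0)); p1 <- rot(cbind(b$x1, b$y1))
    b2 <- data.frame(label = b$label, x0 = p0[, 1], y0 = p0[, 2],
                     x1 = p1[, 1], y1 = p1[, 2])
    expect_equal(unname(boundaryPositions(a2, b2)), ref, tolerance = 1e-9)
  }
})

test_that("tract projection reduces to the expected arc intervals", {
  axis <- cbind(0, seq(0, 100, by = 5))
  # identity on a sub-polyline of the axis
  sub <- cbind(0, c(20, 25, 30, 35))
  expect_equal(unname(projectTract(sub, axis)[1, ]), c(20, 35))
  # orthogonal projection of a laterally offset parallel tract
  offset <- cbind(2, c(40, 60))
  expect_equal(unname(projectTract(offset, axis)[1, ]), c(40, 60))
  # zero width flagged as empty
  point <- cbind(2, c(50, 50 + 1e-12))
  got <- projectTract(point, axis)
  expect_identical(nrow(got), 0L)
  expect_true(attr(got, "zeroWidth"))
  # wall mismatch
  expect_error(projectTract(CalcifiedTract("anterior", sub),
                            WallAxis("posterior", axis)),
               "wall labels differ")
})

test_that("zig-zag projection around a curved axis matches the dense-resampling oracle", {
  y <- seq(0, 100, by = 2)
  axis <- cbind(4 * sin(2 * pi * y / 55), y)
  set.seed(10)
  for (i in 1:5) {
    yy <- sort(runif(6, 15, 85))
    tract <- cbind(4 * sin(2 * pi * yy / 55) + runif(6, -2, 2), yy)
    got <- projectTract(tract, axis)
    want <- oracleProjectInterval(tract, axis)
    expect_equal(unname(got[1, ]), want, tolerance = 0.05)
  }
})

test_that("clipping to the scoring region keeps, trims and drops correctly", {
  expect_equal(unname(clipIntervals(rbind(c(5, 15)), 10, 90)),
               matrix(c(10, 15), 1))
  expect_identical(nrow(clipIntervals(rbind(c(0, 8)), 10, 90)), 0L)
  expect_equal(unname(clipIntervals(rbind(c(20, 30)), 10, 90)),
               matrix(c(20, 30), 1))
  expect_identical(nrow(clipIntervals(matrix(numeric(0), ncol = 2), 10, 90)), 0L)
})

test_that("interval union merges overlaps and adjacency, and matches the raster oracle", {
  expect_equal(unname(mergeIntervals(rbind(c(0, 10), c(5, 15)))),
               matrix(c(0, 15), 1))
  expect_equal(unname(mergeIntervals(rbind(c(0, 5), c(5, 10)))),
               matrix(c(0, 10), 1))
  for (seed in 1:4) {
    set.seed(seed)
    s <- runif(50, 0, 90)
    iv <- cbind(s, s + runif(50, 0.01, 15))
    merged <- mergeIntervals(iv)
    expect_equal(intervalLength(merged),
                 rasterUnionLength(iv, 0, 110), tolerance = 0.06)
    # disjoint and sorted
    expect_true(all(diff(as.vector(t(merged))) > 0))
    # idempotent and order-independent
    expect_equal(mergeIntervals(merged), merged)
    expect_equal(mergeIntervals(iv[sample(50), ]), merged)
  }
})

test_that("clipping commutes with merging", {
  set.seed(3)
  s <- runif(30, 0, 100)
  iv <- cbind(s, s + runif(30, 0.1, 20))
  a <- mergeIntervals(clipIntervals(iv, 10, 90))
  b <- clipIntervals(mergeIntervals(iv), 10, 90)
  expect_equal(a, b)
})

test_that("segment partition splits the region at the boundary positions", {
  p <- segmentPartition(c(10, 30, 50, 70, 90))
  expect_identical(rownames(p), c("L1", "L2", "L3", "L4"))
  expect_equal(unname(p), cbind(c(10, 30, 50, 70), c(30, 50, 70, 90)))
  expect_equal(sum(p[, 2] - p[, 1]), 90 - 10)
  q <- segmentPartition(c(0, 25, 50, 75, 100))
  expect_equal(unname(q[, 2] - q[, 1]), rep(25, 4))
  expect_error(segmentPartition(c(10, 30, 30, 70, 90)), "degenerate partition")
})
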