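# Independent oracles and fixture builders.  Everything here is written from
# first principles (rasterization, dense resampling, sums of squares,
# exhaustive enumeration) and never calls the package code paths it checks.

# --- rasterization oracle for interval arithmetic -------------------------

# Length of the union of half-open intervals inside [lo, hi), measured by
# membership of grid-cell midpoints on a `step` mm grid.
rasterUnionLength <- function(intervals, lo, hi, step = 0.001) {
  xs <- seq(lo + step / 2, hi, by = step)
  member <- rep(FALSE, length(xs))
  if (length(intervals))
    for (i in seq_len(nrow(intervals)))
      member <- member | (xs >= intervals[i, 1] & xs < intervals[i, 2])
  sum(member) * step
}

# --- dense-resampling geometry oracles ------------------------------------

# Interpolate a polyline at arc positions (self-contained).
oracleResample <- function(points, arcs) {
  cum <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  cbind(approx(cum, points[, 1], xout = arcs, ties = "ordered")$y,
        approx(cum, points[, 2], xout = arcs, ties = "ordered")$y)
}

# Boundary position by dense resampling (0.01 mm) and nearest sign-change
# search on the signed side of the boundary's infinite line.
oracleBoundaryPosition <- function(axisPoints, p0, p1, step = 0.01) {
  cum <- c(0, cumsum(sqrt(rowSums(diff(axisPoints)^2))))
  arcs <- seq(0, cum[length(cum)], by = step)
  pts <- oracleResample(axisPoints, arcs)
  d <- p1 - p0
  side <- d[1] * (pts[, 2] - p0[2]) - d[2] * (pts[, 1] - p0[1])
  k <- which(side[-length(side)] * side[-1] <= 0 &
               !(side[-length(side)] == 0 & side[-1] == 0))[1]
  if (is.na(k)) stop("oracle: no crossing")
  s0 <- side[k]; s1 <- side[k + 1]
  if (s0 == s1) return(arcs[k])
  arcs[k] + (arcs[k + 1] - arcs[k]) * s0 / (s0 - s1)
}

# Projection interval by brute force: resample the tract, then for each
# sample find the nearest densely resampled axis point.
oracleProjectInterval <- function(tractPoints, axisPoints,
                                  nTract = 200, axisStep = 0.02) {
  cumT <- c(0, cumsum(sqrt(rowSums(diff(tractPoints)^2))))
  tp <- oracleResample(tractPoints, seq(0, cumT[length(cumT)], length.out = nTract))
  cumA <- c(0, cumsum(sqrt(rowSums(diff(axisPoints)^2))))
  arcsA <- seq(0, cumA[length(cumA)], by = axisStep)
  ap <- oracleResample(axisPoints, arcsA)
  arcs <- vapply(seq_len(nrow(tp)), function(i) {
    arcsA[which.min((ap[, 1] - tp[i, 1])^2 + (ap[, 2] - tp[i, 2])^2)]
  }, 0)
  c(min(arcs), max(arcs))
}

# --- statistics oracles ----------------------------------------------------

# ICC(2,1) from the definition: sums of squares computed directly.
oracleIcc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  MSR <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  MSC <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  SSE <- sum((m - grand)^2) -
    k * sum((rowMeans(m) - grand)^2) - n * sum((colMeans(m) - grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# Exact two-sided signed-rank p-value by exhaustive enumeration of all 2^n
# sign assignments (expand.grid), n <= 12.
oracleWilcoxonExact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- signs %*% r
  pLe <- mean(Ws <= W + 1e-12)
  pGe <- mean(Ws >= W - 1e-12)
  min(1, 2 * min(pLe, pGe))
}

# --- fixture builders ------------------------------------------------------

# Hand-checkable annotation: straight vertical walls at x = 0 (anterior) and
# x = 10 (posterior) from y = 0 to y = 100 so arc length equals y; horizontal
# boundaries at y = 10, 30, 50, 70, 90 (region [10, 90), 20 mm segments).
# Tracts are given as arc (= y) intervals per wall.
straightAnnotation <- function(anterior = NULL, posterior = NULL,
                               sv = NA_integer_, posteriorShift = 0) {
  boundaries <- data.frame(label = AAC_BOUNDARY_LABELS,
                           x0 = -5, y0 = c(10, 30, 50, 70, 90),
                           x1 = 15, y1 = c(10, 30, 50, 70, 90))
  axisA <- cbind(0, seq(0, 100, by = 5))
  axisP <- cbind(10, seq(0, 100, by = 5) + posteriorShift)
  mkTracts <- function(iv, x, wall, yOff = 0) {
    if (is.null(iv)) return(list())
    lapply(seq_len(nrow(iv)), function(i)
      CalcifiedTract(wall, cbind(x, c(iv[i, 1], iv[i, 2]) + yOff)))
  }
  AortaAnnotation("subj", "op", 1L, ImageCalibration(0.2, 0.2, 512L, 1024L),
                  boundaries,
                  list(WallAxis("anterior", axisA), WallAxis("posterior", axisP)),
                  c(mkTracts(asIntervalMatrix(anterior), 0, "anterior"),
                    mkTracts(asIntervalMatrix(posterior), 10, "posterior",
                             yOff = posteriorShift)),
                  svScore = sv)
}

asIntervalMatrix <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.matrix(x)) x else matrix(x, ncol = 2, byrow = TRUE)
}

# Noise-free measurement table from per-subject true values, identical for
# every operator and repetition.
constantTable <- function(values, nOperators = 3, nRepetitions = 2,
                          scoreType = "QC") {
  g <- expand.grid(s = seq_along(values), o = seq_len(nOperators),
                   r = seq_len(nRepetitions))
  data.frame(subject_id = paste0("S", g$s), operator_id = paste0("O", g$o),
             repetition = g$r, score_type = scoreType, value = values[g$s])
}
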