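# Synthetic annotations and measurement tables with known ground truth.
#
# The generator stands in for the study radiographs: it builds calibrated
# annotations whose relative calcified length equals a requested target, an
# operator-noise model (arc-length endpoint jitter, tract misses, visual
# entry error) for redrawn tracts, and two-way variance-components score
# tables matching the random-effects model assumed by ICC(2,1).

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive a per-entity child seed from a root seed
#'
#' Children follow a documented counter scheme,
#' child = (root * 48271 + counter) mod (2^31 - 1), so adding entities never
#' shifts the draws of existing ones.
#'
#' @param root root seed (integer)
#' @param counter non-negative integer counter
#' @return integer seed in [1, 2^31 - 2]
#' @export
deriveSeed <- function(root, counter) {
  as.integer(((abs(as.numeric(root)) %% 2147483647) * 48271 + counter) %% 2147483646 + 1)
}

#' Configuration for a synthetic annotation
#'
#' @param seed integer RNG seed
#' @param wallLengthMm length of the scoring region (T12-L1 to L4-L5) along
#'   each wall axis, mm; used when \code{boundarySpacing = "equal"}
#' @param boundarySpacing "equal" or 5 strictly increasing arc positions
#'   (mm, first 0) of the boundary lines along the region
#' @param targetFraction requested relative calcified length in [0, 1]
#' @param nTracts number of calcified tracts to draw
#' @param tractPlacement "uniform" (random non-overlapping placement) or
#'   "boundary_straddling" (each tract centred on an internal intervertebral
#'   boundary, the mechanism that inflates discrete scores relative to the
#'   continuum score)
#' @param axisCurvature amplitude (mm) of a sinusoidal lateral bend of the
#'   wall axes; 0 gives straight vertical walls
#' @return validated config list of class \code{annotationSimConfig}
#' @export
annotationSimConfig <- function(seed = 1L, wallLengthMm = 100,
                                boundarySpacing = "equal",
                                targetFraction = 0, nTracts = 0L,
                                tractPlacement = c("uniform", "boundary_straddling"),
                                axisCurvature = 0) {
  tractPlacement <- match.arg(tractPlacement)
  if (identical(boundarySpacing, "equal")) {
    positions <- seq(0, wallLengthMm, length.out = 5)
  } else {
    positions <- as.numeric(boundarySpacing)
    if (length(positions) != 5 || any(diff(positions) <= 0))
      stop("boundarySpacing must be \"equal\" or 5 strictly increasing positions")
  }
  if (positions[5] - positions[1] <= 0) stop("lengths must be positive")
  if (targetFraction < 0 || targetFraction > 1)
    stop("targetFraction must lie in [0, 1]")
  if (nTracts < 0) stop("nTracts must be >= 0")
  if (targetFraction > 0 && nTracts == 0)
    stop("infeasible configuration: positive targetFraction needs tracts")
  structure(list(seed = as.integer(seed), positions = positions,
                 targetFraction = targetFraction, nTracts = as.integer(nTracts),
                 tractPlacement = tractPlacement, axisCurvature = axisCurvature),
            class = "annotationSimConfig")
}

#' Operator noise configuration
#'
#' @param endpointJitterSd SD (mm) of centred normal jitter applied to each
#'   tract endpoint along the wall arc when an operator redraws
#' @param detectionMissProb probability a tract is missed entirely
#' @param svEntrySd SD (score points) of the visual-score entry error
#' @return validated config list of class \code{operatorNoiseConfig}
#' @export
operatorNoiseConfig <- function(endpointJitterSd = 0, detectionMissProb = 0,
                                svEntrySd = 0) {
  if (endpointJitterSd < 0 || svEntrySd < 0)
    stop("noise SDs must be >= 0")
  if (detectionMissProb < 0 || detectionMissProb > 1)
    stop("detectionMissProb must lie in [0, 1]")
  structure(list(endpointJitterSd = endpointJitterSd,
                 detectionMissProb = detectionMissProb,
                 svEntrySd = svEntrySd), class = "operatorNoiseConfig")
}

#' Variance-components configuration for score tables
#'
#' @param mu grand mean (score points, 0-24 scale)
#' @param sigmaSubject,sigmaOperator,sigmaError SDs of the subject, operator
#'   and residual components
#' @param nSubjects,nOperators,nRepetitions design counts
#' @param seed integer RNG seed
#' @return validated config list of class \code{varianceComponentsConfig}
#' @export
varianceComponentsConfig <- function(mu = 12, sigmaSubject = 3,
                                     sigmaOperator = 0, sigmaError = 1,
                                     nSubjects = 20L, nOperators = 5L,
                                     nRepetitions = 2L, seed = 1L) {
  if (any(c(sigmaSubject, sigmaOperator, sigmaError) < 0))
    stop("sigmas must be >= 0")
  if (any(c(nSubjects, nOperators, nRepetitions) < 1))
    stop("counts must be >= 1")
  structure(list(mu = mu, sigmaSubject = sigmaSubject,
                 sigmaOperator = sigmaOperator, sigmaError = sigmaError,
                 nSubjects = as.integer(nSubjects),
                 nOperators = as.integer(nOperators),
                 nRepetitions = as.integer(nRepetitions),
                 seed = as.integer(seed)),
            class = "varianceComponentsConfig")
}

# Wall axis polyline: vertical at x0, optional sinusoidal lateral bend,
# extending 10 mm beyond the region at both ends, sampled every 1 mm.
.simAxisPoints <- function(x0, yTop, yBottom, curvature) {
  y <- seq(yTop - 10, yBottom + 10, by = 1)
  if (y[length(y)] < yBottom + 10) y <- c(y, yBottom + 10)
  x <- x0 + curvature * sin(2 * pi * (y - yTop) / 60)
  cbind(x, y, deparse.level = 0)
}

# Build a tract polyline lying exactly on the axis between two arc positions,
# keeping interior axis vertices so curvature is followed.
.liftInterval <- function(axisPoints, s, e) {
  cum <- polylineArcLengths(axisPoints)
  inside <- which(cum > s & cum < e)
  arcs <- c(s, cum[inside], e)
  polylinePointAt(axisPoints, arcs)
}

# Place k non-overlapping intervals with the given lengths uniformly in
# [b0, b4): gaps drawn as a normalised uniform split of the free space.
.placeUniform <- function(lengths, b0, b4) {
  k <- length(lengths)
  free <- (b4 - b0) - sum(lengths)
  gaps <- stats::runif(k + 1)
  gaps <- gaps / sum(gaps) * free
  starts <- b0 + cumsum(gaps)[seq_len(k)] + c(0, cumsum(lengths))[seq_len(k)]
  cbind(starts, starts + lengths, deparse.level = 0)
}

#' Generate a synthetic annotation with known calcified fraction
#'
#' Builds a calibrated annotation (five horizontal boundary lines, two wall
#' axes, calcified tracts lying on the axes) whose relative calcified length
#' equals \code{targetFraction} to within 1e-6: intervals are placed by arc
#' length on each wall, then lifted to polyline tracts on the axis.  The
#' operator-visual score slot is filled with the annotation's own
#' back-calculated semiquantitative score (a perfectly accurate visual
#' reading); operator noise is added separately by
#' \code{\link{perturbAnnotation}}.
#'
#' @param config an \code{\link{annotationSimConfig}}
#' @param subjectId,operatorId,repetitionId identifiers stamped on the result
#' @return an \linkS4class{AortaAnnotation}
#' @export
generateAnnotation <- function(config, subjectId = "sim", operatorId = "op1",
                               repetitionId = 1L) {
  stopifnot(inherits(config, "annotationSimConfig"))
  withSeed(config$seed, {
    pos <- config$positions
    yTop <- 20
    yB <- yTop + pos
    xA <- 20; xP <- 32
    boundaries <- data.frame(label = AAC_BOUNDARY_LABELS,
                             x0 = xA - 15, y0 = yB, x1 = xP + 15, y1 = yB)
    axisA <- .simAxisPoints(xA, yB[1], yB[5], config$axisCurvature)
    axisP <- .simAxisPoints(xP, yB[1], yB[5], config$axisCurvature)
    walls <- list(WallAxis("anterior", axisA), WallAxis("posterior", axisP))
    # arc-length region per wall (curvature makes arc length exceed |y|)
    bA <- boundaryPositions(axisA, boundaries)
    bP <- boundaryPositions(axisP, boundaries)
    LA <- bA[5] - bA[1]; LP <- bP[5] - bP[1]
    f <- config$targetFraction
    n <- config$nTracts
    tracts <- list()
    if (f > 0 && n > 0) {
      plan <- list()   # per wall: total length + tract count
      if (n == 1L) {
        need <- f * (LA + LP)
        if (need > LA + 1e-9)
          stop("infeasible configuration: single tract exceeds anterior region")
        plan$anterior <- list(total = need, k = 1L, b = bA, axis = axisA)
      } else {
        kA <- ceiling(n / 2); kP <- n - kA
        plan$anterior <- list(total = f * LA, k = kA, b = bA, axis = axisA)
        plan$posterior <- list(total = f * LP, k = kP, b = bP, axis = axisP)
      }
      for (wall in names(plan)) {
        p <- plan[[wall]]
        if (p$k == 0L) next
        if (p$total > (p$b[5] - p$b[1]) + 1e-9)
          stop("infeasible configuration: coverage exceeds wall region")
        if (config$tractPlacement == "uniform") {
          props <- stats::runif(p$k, 0.5, 1.5)
          lens <- p$total * props / sum(props)
          iv <- .placeUniform(lens, p$b[1], p$b[5])
        } else {
          # centre tract i on an internal boundary, middle (L2/L3) first
          len <- p$total / p$k
          ctr <- p$b[c(3L, 2L, 4L)[(seq_len(p$k) - 1) %% 3 + 1]]
          iv <- cbind(ctr - len / 2, ctr + len / 2)
          iv[, 1] <- pmax(iv[, 1], p$b[1])
          iv[, 2] <- pmin(iv[, 2], p$b[5])
        }
        for (i in seq_len(nrow(iv)))
          tracts[[length(tracts) + 1]] <-
            CalcifiedTract(wall, .liftInterval(p$axis, iv[i, 1], iv[i, 2]))
      }
    }
    ann <- AortaAnnotation(subjectId, operatorId, repetitionId,
                           ImageCalibration(0.2, 0.2, 512L, 1024L),
                           boundaries, walls, tracts)
    ann@svScore <- as.integer(scScore(ann))
    ann
  })
}

#' Perturb an annotation with operator noise
#'
#' Emulates an operator redrawing: each tract is reduced to its arc-length
#' interval on its wall axis, both endpoints receive centred normal jitter of
#' the configured SD along the arc, and the tract is redrawn on the axis;
#' each tract is missed entirely with the configured probability; the
#' operator-visual score, when present, receives rounded normal entry error.
#' Boundaries and wall axes are left unchanged.  Deterministic given the
#' seed.
#'
#' @param annotation an \linkS4class{AortaAnnotation}
#' @param noise an \code{\link{operatorNoiseConfig}}
#' @param seed integer RNG seed
#' @param operatorId,repetitionId identifiers stamped on the result
#' @return a new \linkS4class{AortaAnnotation}
#' @export
perturbAnnotation <- function(annotation, noise, seed,
                              operatorId = NULL, repetitionId = NULL) {
  stopifnot(inherits(noise, "operatorNoiseConfig"))
  if (is.null(operatorId)) operatorId <- annotation@operatorId
  if (is.null(repetitionId)) repetitionId <- annotation@repetition
  withSeed(seed, {
    axes <- list(anterior = wallAxis(annotation, "anterior")@points,
                 posterior = wallAxis(annotation, "posterior")@points)
    totals <- lapply(axes, function(p) max(polylineArcLengths(p)))
    tracts <- list()
    for (tr in annotation@tracts) {
      miss <- stats::runif(1) < noise$detectionMissProb
      jit <- stats::rnorm(2, 0, noise$endpointJitterSd)
      if (miss) next
      iv <- projectTract(tr@points, axes[[tr@wall]])
      if (!nrow(iv)) next
      ends <- sort(c(iv[1, 1] + jit[1], iv[1, 2] + jit[2]))
      ends <- pmin(pmax(ends, 0), totals[[tr@wall]])
      if (ends[2] - ends[1] <= 1e-6) next
      tracts[[length(tracts) + 1]] <-
        CalcifiedTract(tr@wall, .liftInterval(axes[[tr@wall]], ends[1], ends[2]))
    }
    sv <- annotation@svScore
    if (!is.na(sv) && noise$svEntrySd > 0)
      sv <- as.integer(min(24, max(0, round(sv + stats::rnorm(1, 0, noise$svEntrySd)))))
    out <- annotation
    out@operatorId <- as.character(operatorId)
    out@repetition <- as.integer(repetitionId)
    out@tracts <- tracts
    out@svScore <- sv
    validObject(out)
    out
  })
}

#' Generate a two-way variance-components measurement table
#'
#' value(s, o, r) = mu + S_s + O_o + e_sor with independent centred normal
#' components of the configured SDs, clamped to the [0, 24] score range (the
#' clamp count is recorded in attribute \code{n_clamped}).  This is exactly
#' the two-way random-effects model under which ICC(2,1) estimates
#' sigma_s^2 / (sigma_s^2 + sigma_o^2 + sigma_e^2) and the within-cell SEM
#' estimates sigma_e.
#'
#' @param config a \code{\link{varianceComponentsConfig}}
#' @param scoreType score-type label for the rows, default "QC"
#' @return long measurement table (data.frame) with attribute
#'   \code{n_clamped}
#' @export
generateMeasurementTable <- function(config, scoreType = "QC") {
  stopifnot(inherits(config, "varianceComponentsConfig"))
  withSeed(config$seed, {
    nS <- config$nSubjects; nO <- config$nOperators; nR <- config$nRepetitions
    S <- stats::rnorm(nS, 0, config$sigmaSubject)
    O <- stats::rnorm(nO, 0, config$sigmaOperator)
    g <- expand.grid(subject = seq_len(nS), operator = seq_len(nO),
                     repetition = seq_len(nR))
    value <- config$mu + S[g$subject] + O[g$operator] +
      stats::rnorm(nrow(g), 0, config$sigmaError)
    clamped <- sum(value < 0 | value > 24)
    value <- pmin(pmax(value, 0), 24)
    out <- data.frame(subject_id = sprintf("S%03d", g$subject),
                      operator_id = sprintf("O%d", g$operator),
                      repetition = g$repetition,
                      score_type = scoreType, value = value)
    attr(out, "n_clamped") <- clamped
    out
  })
}

#' Generate a full synthetic cohort of annotations
#'
#' Emulates the study design: for each subject one base annotation with a
#' severity (target calcified fraction) drawn from \code{severityRange}, then
#' one perturbed redraw per operator and repetition under the given noise
#' model.  Seeds are derived from the root seed by the counter scheme of
#' \code{\link{deriveSeed}}.
#'
#' @param nSubjects number of subjects
#' @param nOperators number of operators (default 5)
#' @param nRepetitions repetitions per operator (default 2)
#' @param severityRange range of target calcified fractions, uniform draw
#' @param nTracts tracts per base annotation
#' @param tractPlacement passed to \code{\link{annotationSimConfig}}
#' @param axisCurvature passed to \code{\link{annotationSimConfig}}
#' @param noise an \code{\link{operatorNoiseConfig}}
#' @param seed root seed
#' @return list with \code{annotations} (nested list subject -> "op.rep") and
#'   \code{scores} (data.frame of \code{\link{scoreRow}} rows for every
#'   perturbed annotation)
#' @export
generateCohort <- function(nSubjects, nOperators = 5L, nRepetitions = 2L,
                           severityRange = c(0.1, 0.6), nTracts = 6L,
                           tractPlacement = "uniform", axisCurvature = 0,
                           noise = operatorNoiseConfig(endpointJitterSd = 1),
                           seed = 1L) {
  annotations <- list()
  scores <- list()
  counter <- 0L
  for (s in seq_len(nSubjects)) {
    counter <- counter + 1L
    sid <- sprintf("S%03d", s)
    f <- withSeed(deriveSeed(seed, counter),
                  stats::runif(1, severityRange[1], severityRange[2]))
    base <- generateAnnotation(
      annotationSimConfig(seed = deriveSeed(seed, counter + 100000L),
                          targetFraction = f, nTracts = nTracts,
                          tractPlacement = tractPlacement,
                          axisCurvature = axisCurvature),
      subjectId = sid)
    subj <- list()
    for (o in seq_len(nOperators)) {
      for (r in seq_len(nRepetitions)) {
        counter <- counter + 1L
        ann <- perturbAnnotation(base, noise, deriveSeed(seed, counter + 200000L),
                                 operatorId = sprintf("O%d", o),
                                 repetitionId = r)
        ann@subjectId <- sid
        subj[[sprintf("O%d.%d", o, r)]] <- ann
        scores[[length(scores) + 1]] <- scoreRow(scoreTriple(ann))
      }
    }
    annotations[[sid]] <- subj
  }
  list(annotations = annotations, scores = do.call(rbind, scores))
}
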