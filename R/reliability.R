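# Repeatability / reproducibility statistics for 0-24 calcification scores:
# Bland-Altman, repetition regression, ICC(2,1) with F-based CI, SEM, MDD,
# exact paired Wilcoxon signed-rank, and between-score agreement.

#' Validate a long-format measurement table
#'
#' The exchange format for all statistics: one row per (subject, operator,
#' repetition, score type) with a value on the 0-24 scale.
#'
#' @param table data.frame with columns subject_id, operator_id, repetition,
#'   score_type (QC/SC/SV), value
#' @return the table, invisibly, after checking column presence, the
#'   uniqueness of (subject, operator, repetition, score_type) and the
#'   value range
#' @export
validateMeasurementTable <- function(table) {
  need <- c("subject_id", "operator_id", "repetition", "score_type", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(table$score_type %in% c("QC", "SC", "SV")))
    stop("score_type must be one of QC, SC, SV")
  key <- interaction(table$subject_id, table$operator_id, table$repetition,
                     table$score_type, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (subject, operator, repetition, score_type) rows")
  v <- table$value
  if (any(!is.finite(v)) || any(v < 0) || any(v > 24))
    stop("values must lie in [0, 24]")
  invisible(table)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements the differences d = x2 - x1 are summarised by
#' their mean, SD (n - 1 denominator) and the 95\% limits of agreement
#' mean +/- 1.96 SD.  \code{ci_width} is the width of the limits-of-agreement
#' interval, 3.92 SD, the "95\% CI" figure used when comparing score
#' repeatability on the 0-24 range.
#'
#' @param x1,x2 paired measurements (e.g. repetition 1 and 2)
#' @return list with n, mean_diff, sd_diff, loa_low, loa_high, ci_width
#' @export
blandAltman <- function(x1, x2) {
  ok <- is.finite(x1) & is.finite(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 2) stop("insufficient pairs")
  d <- x2 - x1
  m <- mean(d)
  s <- stats::sd(d)
  list(n = n, mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       ci_width = 2 * 1.96 * s)
}

#' Regression of repetition 2 on repetition 1
#'
#' Ordinary least squares of the second measurement on the first; the
#' determination coefficient R^2 quantifies how much variance is common to
#' the two repetitions.
#'
#' @param x1,x2 paired measurements
#' @return list with slope, intercept, r_squared, n
#' @export
repetitionRegression <- function(x1, x2) {
  ok <- is.finite(x1) & is.finite(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  if (length(x1) < 3) stop("insufficient pairs")
  if (stats::var(x1) == 0) stop("degenerate regressor")
  fit <- stats::lm(x2 ~ x1)
  # R^2 of simple OLS is the squared sample correlation; computing it
  # directly avoids summary.lm() noise on perfect (noise-free) fits
  r2 <- if (stats::var(x2) == 0) 1 else stats::cor(x1, x2)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = length(x1))
}

#' ICC(2,1): two-way random effects, absolute agreement, single measures
#'
#' Computes the intraclass correlation coefficient for a complete
#' subjects x raters matrix from the two-way ANOVA mean squares
#' (rows MSR, columns MSC, error MSE):
#' ICC = (MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n).
#' The 95\% confidence interval uses the F-based procedure for two-way
#' random-effects absolute agreement with a Satterthwaite-approximated
#' denominator degrees of freedom.  Rows with missing cells are dropped
#' (complete-case reduction) and counted in \code{n_excluded}.
#'
#' @param m numeric matrix, one row per subject, one column per rater
#' @param conf confidence level, default 0.95
#' @return list with icc, ci_low, ci_high, n_subjects, n_raters,
#'   n_excluded, degenerate (TRUE when total variance is zero, icc NA)
#' @export
icc21 <- function(m, conf = 0.95) {
  m <- as.matrix(m)
  complete <- stats::complete.cases(m)
  nExcluded <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop("insufficient data")
  if (stats::var(as.vector(m)) == 0)
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_subjects = n, n_raters = k, n_excluded = nExcluded,
                degenerate = TRUE))
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  # only the mean squares are used; the perfect-fit warning anova.lm emits
  # when MSE = 0 (identical raters) is irrelevant here
  av <- suppressWarnings(stats::anova(stats::aov(y ~ subject + rater, data = df)))
  MSR <- av["subject", "Mean Sq"]
  MSC <- av["rater", "Mean Sq"]
  MSE <- av["Residuals", "Mean Sq"]
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - conf
  if (abs(1 - icc) < 1e-12) {
    ciLow <- ciHigh <- icc
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    ciLow <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    ciHigh <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  }
  list(icc = icc, ci_low = ciLow, ci_high = ciHigh, n_subjects = n,
       n_raters = k, n_excluded = nExcluded, degenerate = FALSE)
}

#' Standard error of measurement from repeated measurements
#'
#' \code{method = "anova"} (default): the within-cell root mean square error
#' of the two-way (subject x operator) layout with repetitions as
#' replicates, SEM = sqrt(sum over cells of sum((y - cell mean)^2) /
#' sum(r_cell - 1)).  This estimates the measurement-error SD independently
#' of the between-subject variance of the sample.
#' \code{method = "icc"}: the sensitivity-analysis variant
#' SEM = SD_pooled * sqrt(1 - ICC), with ICC(2,1) computed on the
#' subject x (operator, repetition) single-measurement matrix.
#'
#' @param table long measurement table (see
#'   \code{\link{validateMeasurementTable}})
#' @param scoreType "QC", "SC" or "SV"
#' @param method "anova" or "icc"
#' @return list with sem, n_cells (replicated cells used), n_excluded
#'   (unreplicated cells dropped), method
#' @export
semPooled <- function(table, scoreType, method = c("anova", "icc")) {
  method <- match.arg(method)
  validateMeasurementTable(table)
  t <- table[table$score_type == scoreType, ]
  if (!nrow(t)) stop("no rows for score type ", scoreType)
  cell <- interaction(t$subject_id, t$operator_id, drop = TRUE)
  reps <- tapply(t$value, cell, length)
  replicated <- names(reps)[reps >= 2]
  if (length(replicated) < 3) stop("SEM requires repeated measurements")
  nExcluded <- sum(reps < 2)
  if (method == "anova") {
    keep <- cell %in% replicated
    y <- t$value[keep]; g <- droplevels(cell[keep])
    ss <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    dfree <- sum(tapply(y, g, length) - 1)
    sem <- sqrt(ss / dfree)
  } else {
    # single-measurement ICC over operator x repetition "raters", so that
    # SD_pooled * sqrt(1 - ICC) targets the same error SD as the ANOVA route
    rater <- interaction(t$operator_id, t$repetition, drop = TRUE)
    subj <- sort(unique(t$subject_id))
    m <- matrix(NA_real_, length(subj), nlevels(rater))
    m[cbind(match(t$subject_id, subj), as.integer(rater))] <- t$value
    fit <- icc21(m)
    if (fit$degenerate) return(list(sem = 0, n_cells = length(replicated),
                                    n_excluded = nExcluded, method = method))
    sem <- stats::sd(t$value) * sqrt(1 - fit$icc)
  }
  list(sem = sem, n_cells = length(replicated), n_excluded = nExcluded,
       method = method)
}

#' Minimum detectable difference from a SEM
#'
#' MDD = 1.96 sqrt(2) SEM: the smallest between-measurement change that
#' exceeds measurement noise at 95\% confidence.  For discrete scores the
#' rounded variant (nearest integer) is the operational figure.
#'
#' @param sem standard error of measurement, >= 0
#' @return list with sem, mdd, mdd_rounded
#' @export
mdd <- function(sem) {
  if (!is.finite(sem) || sem < 0) stop("invalid SEM")
  m <- 1.96 * sqrt(2) * sem
  list(sem = sem, mdd = m, mdd_rounded = as.integer(round(m)))
}

# Exact null distribution of the signed-rank statistic: subset sums of the
# doubled ranks (doubling keeps midranks integral), one polynomial
# convolution per rank, uniform over the 2^n sign assignments.
.signRankDistribution <- function(ranks2) {
  f <- 1
  for (r in ranks2) {
    g <- c(f, numeric(r))
    g[(r + 1):(r + length(f))] <- g[(r + 1):(r + length(f))] + f
    f <- g
  }
  f / sum(f)
}

#' Paired Wilcoxon signed-rank test for test-retest data
#'
#' Two-sided signed-rank test of the per-subject differences retest - test.
#' Zero differences are dropped (their count is reported).  For n <= 25
#' non-zero differences the p-value is exact: the statistic's null
#' distribution is enumerated over all 2^n sign assignments of the observed
#' (mid)ranks, so ties are handled exactly.  Above 25 the normal
#' approximation with the tie-corrected variance is used.
#'
#' @param test,retest paired score values per subject
#' @return list with statistic (W, sum of positive ranks), p_value, n_used,
#'   n_zero_dropped, method ("exact" or "normal"), degenerate (TRUE when all
#'   differences are zero; p reported as 1)
#' @export
wilcoxonTestRetest <- function(test, retest) {
  ok <- is.finite(test) & is.finite(retest)
  d <- retest[ok] - test[ok]
  nZero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p_value = 1.0, n_used = 0,
                n_zero_dropped = nZero, method = "degenerate",
                degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))
    dist <- .signRankDistribution(r2)
    w2 <- as.integer(round(2 * W))
    pLe <- sum(dist[seq_len(w2 + 1)])
    pGe <- sum(dist[(w2 + 1):length(dist)])
    p <- min(1, 2 * min(pLe, pGe))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p_value = p, n_used = n, n_zero_dropped = nZero,
       method = method, degenerate = FALSE)
}

#' Between-score agreement
#'
#' Bland-Altman analysis of the per-row differences a - b between two score
#' types measured on the same (subject, operator, repetition), plus the OLS
#' slope of the difference against the pair mean (trend of disagreement with
#' calcification severity).
#'
#' @param table long measurement table
#' @param typeA,typeB score types to compare ("QC", "SC", "SV"); differences
#'   are typeA - typeB
#' @param repetition which repetition to analyse (default 2, the one free of
#'   learning effects)
#' @return list with the \code{\link{blandAltman}} fields plus trend_slope
#' @export
scoreAgreement <- function(table, typeA, typeB, repetition = 2L) {
  validateMeasurementTable(table)
  t <- table[table$repetition == repetition, ]
  a <- t[t$score_type == typeA, c("subject_id", "operator_id", "value")]
  b <- t[t$score_type == typeB, c("subject_id", "operator_id", "value")]
  m <- merge(a, b, by = c("subject_id", "operator_id"),
             suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no paired observations")
  ba <- blandAltman(m$value_b, m$value_a)   # differences a - b
  d <- m$value_a - m$value_b
  avg <- (m$value_a + m$value_b) / 2
  slope <- if (stats::var(avg) > 0)
    unname(stats::coef(stats::lm(d ~ avg))[2]) else 0
  c(ba, list(trend_slope = slope))
}

.reportRow <- function(statistic, scoreType, stratum, n, value,
                       ciLow = NA_real_, ciHigh = NA_real_) {
  data.frame(statistic = statistic, score_type = scoreType,
             stratum = stratum, n = n, value = value,
             ci_low = ciLow, ci_high = ciHigh)
}

#' Full repeatability and reproducibility report
#'
#' Assembles, per score type present in the table: pooled and per-operator
#' intra-operator Bland-Altman statistics (repetition 2 vs repetition 1),
#' pooled and per-operator repetition regression, inter-operator ICC(2,1)
#' with 95\% CI per repetition, and the pooled SEM and MDD.  Analyses use
#' listwise deletion: pairs/cells with a missing member are dropped and
#' counted in the exclusion log.
#'
#' @param table long measurement table with 2 repetitions and >= 2 operators
#' @return object of class \code{aacReliabilityReport}: list with
#'   \code{table} (data.frame: statistic, score_type, stratum, n, value,
#'   ci_low, ci_high) and \code{exclusions} (named counts per analysis)
#' @export
reliabilityReport <- function(table) {
  validateMeasurementTable(table)
  reps <- sort(unique(table$repetition))
  if (length(reps) < 2) stop("requires 2 repetitions")
  if (length(unique(table$operator_id)) < 2) stop("requires >= 2 operators")
  r1 <- reps[1]; r2 <- reps[2]
  rows <- list()
  exclusions <- integer(0)
  for (st in intersect(c("QC", "SC", "SV"), unique(table$score_type))) {
    t <- table[table$score_type == st, ]
    w <- merge(t[t$repetition == r1, c("subject_id", "operator_id", "value")],
               t[t$repetition == r2, c("subject_id", "operator_id", "value")],
               by = c("subject_id", "operator_id"), suffixes = c("_1", "_2"))
    nDrop <- length(unique(interaction(t$subject_id, t$operator_id))) - nrow(w)
    exclusions[paste0(st, "_unpaired_cells")] <- nDrop
    ba <- blandAltman(w$value_1, w$value_2)
    rows[[length(rows) + 1]] <- .reportRow(
      c("ba_mean_diff", "ba_sd_diff", "ba_loa_low", "ba_loa_high", "ba_ci_width"),
      st, "pooled", ba$n,
      c(ba$mean_diff, ba$sd_diff, ba$loa_low, ba$loa_high, ba$ci_width))
    reg <- repetitionRegression(w$value_1, w$value_2)
    rows[[length(rows) + 1]] <- .reportRow(
      c("regression_slope", "regression_intercept", "regression_r_squared"),
      st, "pooled", reg$n, c(reg$slope, reg$intercept, reg$r_squared))
    for (op in sort(unique(w$operator_id))) {
      wo <- w[w$operator_id == op, ]
      if (nrow(wo) < 3) next
      bao <- blandAltman(wo$value_1, wo$value_2)
      rego <- repetitionRegression(wo$value_1, wo$value_2)
      rows[[length(rows) + 1]] <- .reportRow(
        c("ba_mean_diff", "ba_ci_width", "regression_r_squared"),
        st, paste0("operator:", op), bao$n,
        c(bao$mean_diff, bao$ci_width, rego$r_squared))
    }
    for (r in c(r1, r2)) {
      tr <- t[t$repetition == r, ]
      m <- .subjectOperatorMatrix(tr)
      fit <- icc21(m)
      exclusions[paste0(st, "_icc_rep", r, "_incomplete_subjects")] <- fit$n_excluded
      rows[[length(rows) + 1]] <- .reportRow(
        "icc_2_1", st, paste0("repetition:", r), fit$n_subjects,
        if (fit$degenerate) NA_real_ else fit$icc, fit$ci_low, fit$ci_high)
    }
    s <- semPooled(table, st)
    exclusions[paste0(st, "_sem_unreplicated_cells")] <- s$n_excluded
    md <- mdd(s$sem)
    rows[[length(rows) + 1]] <- .reportRow(
      c("sem", "mdd", "mdd_rounded"), st, "pooled", s$n_cells,
      c(md$sem, md$mdd, md$mdd_rounded))
  }
  out <- list(table = do.call(rbind, rows), exclusions = exclusions)
  rownames(out$table) <- NULL
  class(out) <- "aacReliabilityReport"
  out
}

.subjectOperatorMatrix <- function(t) {
  subj <- sort(unique(t$subject_id))
  ops <- sort(unique(t$operator_id))
  m <- matrix(NA_real_, length(subj), length(ops),
              dimnames = list(subj, ops))
  m[cbind(match(t$subject_id, subj), match(t$operator_id, ops))] <- t$value
  m
}

#' @export
print.aacReliabilityReport <- function(x, ...) {
  cat("Reliability report (", nrow(x$table), " statistics)\n", sep = "")
  print(x$table, row.names = FALSE)
  drops <- x$exclusions[x$exclusions > 0]
  if (length(drops)) {
    cat("Exclusions:\n")
    for (nm in names(drops)) cat(sprintf("  %s: %d\n", nm, drops[[nm]]))
  }
  invisible(x)
}
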