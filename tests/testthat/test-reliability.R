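# Bland-Altman, regression, ICC(2,1), SEM, MDD, Wilcoxon, agreement.

test_that("Bland-Altman statistics follow their definitions", {
  x <- c(3, 7, 11, 18)
  same <- blandAltman(x, x)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(same$ci_width, 0)
  shift <- blandAltman(x, x + 2.5)
  expect_equal(shift$mean_diff, 2.5)
  expect_equal(shift$sd_diff, 0)
  hand <- blandAltman(c(0, 2, 4, 6), c(1, 1, 5, 5))  # d = (1,-1,1,-1)
  expect_equal(hand$mean_diff, 0)
  expect_equal(hand$sd_diff, sqrt(4 / 3))
  expect_equal(hand$ci_width, 3.92 * sqrt(4 / 3))
  expect_equal(hand$loa_low, -1.96 * sqrt(4 / 3))
  expect_error(blandAltman(1, 2), "insufficient pairs")
})

test_that("swapping the Bland-Altman pair negates the mean and keeps the SD", {
  set.seed(4)
  x1 <- runif(20, 0, 24); x2 <- x1 + rnorm(20)
  a <- blandAltman(x1, x2); b <- blandAltman(x2, x1)
  expect_equal(b$mean_diff, -a$mean_diff)
  expect_equal(b$sd_diff, a$sd_diff)
})

test_that("repetition regression matches the normal equations", {
  x <- c(1, 3, 5, 8, 13, 20)
  perfect <- repetitionRegression(x, 2 * x + 1)
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$intercept, 1)
  expect_equal(perfect$r_squared, 1)
  set.seed(8)
  y <- 0.8 * x + rnorm(6)
  fit <- repetitionRegression(x, y)
  # closed-form normal equations
  bHat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  aHat <- mean(y) - bHat * mean(x)
  expect_equal(fit$slope, bHat)
  expect_equal(fit$intercept, aHat)
  expect_equal(fit$r_squared, cor(x, y)^2)
  expect_error(repetitionRegression(rep(3, 5), 1:5), "degenerate regressor")
})

test_that("large-sample regression of independent repetitions has vanishing R^2", {
  set.seed(15)
  n <- 2000
  fit <- repetitionRegression(runif(n, 0, 24), runif(n, 0, 24))
  expect_lt(fit$r_squared, (3 / sqrt(n))^2)
})

test_that("ICC(2,1) agrees with the two-way random-effects reference", {
  # frozen reference: pingouin.intraclass_corr ICC(A,1) on this matrix
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), 6, 4, byrow = TRUE)
  fit <- icc21(m)
  expect_equal(fit$icc, 0.28976377952755916, tolerance = 1e-12)
  # reference CI printed to two decimals: [0.02, 0.76]
  expect_identical(round(fit$ci_low, 2), 0.02)
  expect_identical(round(fit$ci_high, 2), 0.76)
  expect_identical(fit$n_subjects, 6L)
  expect_identical(fit$n_raters, 4L)
})

test_that("ICC(2,1) equals the sums-of-squares definition on random matrices", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(5:10, 1); k <- sample(3:5, 1)
    m <- matrix(rnorm(n * k, 12, 4), n, k) +
      rnorm(n, 0, 3)            # subject effect recycled down columns
    expect_equal(icc21(m)$icc, oracleIcc21(m), tolerance = 1e-10)
  }
})

test_that("ICC(2,1) is 1 for identical raters and drops under a rater offset", {
  m <- matrix(rep(c(2, 8, 15, 21, 11), 3), 5, 3)
  fit <- icc21(m)
  expect_equal(fit$icc, 1)
  shifted <- m; shifted[, 2] <- shifted[, 2] + 3
  expect_lt(icc21(shifted)$icc, 1)
})

test_that("ICC(2,1) is invariant under common location and scale changes", {
  set.seed(5)
  m <- matrix(rnorm(24, 10, 3), 8, 3) + rnorm(8, 0, 2)
  base <- icc21(m)$icc
  expect_equal(icc21(m + 7)$icc, base, tolerance = 1e-12)
  expect_equal(icc21(m * 3.2)$icc, base, tolerance = 1e-12)
})

test_that("ICC handles incomplete and degenerate input", {
  m <- matrix(rnorm(15, 10, 2), 5, 3)
  m[2, 3] <- NA
  fit <- icc21(m)
  expect_identical(fit$n_excluded, 1L)
  expect_identical(fit$n_subjects, 4L)
  expect_true(icc21(matrix(5, 5, 3))$degenerate)
  expect_error(icc21(matrix(rnorm(4), 2, 2)), "insufficient data")
})

test_that("SEM is the within-cell root mean square of replicated measurements", {
  identical_reps <- constantTable(c(4, 9, 15, 20))
  expect_equal(semPooled(identical_reps, "QC")$sem, 0)
  # every cell holds two reps differing by exactly 2 -> SEM = sqrt(2)
  tab <- constantTable(c(4, 9, 15, 20))
  tab$value <- tab$value + ifelse(tab$repetition == 2, 2, 0)
  expect_equal(semPooled(tab, "QC")$sem, sqrt(2))
  expect_error(semPooled(constantTable(1:4, nRepetitions = 1), "QC"),
               "repeated measurements")
})

test_that("SEM estimates the error SD consistently and scales linearly", {
  tab <- generateMeasurementTable(varianceComponentsConfig(
    mu = 12, sigmaSubject = 3, sigmaOperator = 0.5, sigmaError = 1,
    nSubjects = 150L, nOperators = 5L, nRepetitions = 2L, seed = 7L))
  s <- semPooled(tab, "QC")$sem
  expect_equal(s, 1, tolerance = 3 / sqrt(2 * 750))
  tabHalf <- tab; tabHalf$value <- tabHalf$value / 2
  expect_equal(semPooled(tabHalf, "QC")$sem, s / 2, tolerance = 1e-12)
})

test_that("the ICC-based SEM variant is available for sensitivity analysis", {
  tab <- generateMeasurementTable(varianceComponentsConfig(
    mu = 12, sigmaSubject = 3, sigmaOperator = 0, sigmaError = 1,
    nSubjects = 150L, nOperators = 5L, nRepetitions = 2L, seed = 9L))
  s <- semPooled(tab, "QC", method = "icc")
  expect_identical(s$method, "icc")
  expect_equal(s$sem, 1, tolerance = 0.15)
})

test_that("MDD applies the 1.96 sqrt(2) multiplier and rounds for discrete scores", {
  expect_equal(mdd(0)$mdd, 0)
  expect_equal(mdd(1)$mdd, 2.7719, tolerance = 1e-4)
  expect_identical(mdd(1.5)$mdd_rounded, 4L)   # 4.158 -> 4
  expect_error(mdd(-1), "invalid SEM")
})

test_that("exact Wilcoxon signed-rank p-values match base R and enumeration", {
  # symmetric differences put W at its mean -> p = 1
  sym <- wilcoxonTestRetest(c(0, 0, 0, 0), c(1, -1, 2, -2))
  expect_equal(sym$p_value, 1)
  # all-positive n = 6 -> 2 / 2^6
  allpos <- wilcoxonTestRetest(rep(0, 6), 1:6)
  expect_equal(allpos$p_value, 0.03125)
  expect_identical(allpos$method, "exact")
  # tie-free cases against wilcox.test's exact distribution
  set.seed(12)
  for (i in 1:5) {
    n <- sample(6:12, 1)
    x <- rnorm(n); y <- x + rnorm(n)
    ours <- wilcoxonTestRetest(x, y)
    ref <- wilcox.test(y, x, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value)
  }
})

test_that("exact Wilcoxon handles ties and zeros via enumeration", {
  set.seed(19)
  for (n in 3:12) {
    d <- sample(c(-3:-1, 1:3), n, replace = TRUE)   # heavy ties
    ours <- wilcoxonTestRetest(rep(0, n), d)
    expect_equal(ours$p_value, oracleWilcoxonExact(d))
    expect_gt(ours$p_value, 0)
    expect_lte(ours$p_value, 1)
  }
  withZero <- wilcoxonTestRetest(c(5, 5, 5, 5, 5), c(5, 6, 7, 8, 9))
  expect_identical(withZero$n_zero_dropped, 1L)
  expect_identical(withZero$n_used, 4L)
  degenerate <- wilcoxonTestRetest(c(1, 2, 3), c(1, 2, 3))
  expect_true(degenerate$degenerate)
  expect_equal(degenerate$p_value, 1)
})

test_that("the large-sample Wilcoxon branch approximates the exact branch", {
  set.seed(77)
  x <- rnorm(30); y <- x + rnorm(30, 0.3)
  approxRes <- wilcoxonTestRetest(x, y)
  expect_identical(approxRes$method, "normal")
  ref <- wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(approxRes$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("between-score agreement recovers constructed relationships", {
  subj <- paste0("S", 1:12)
  a <- seq(2, 24, by = 2)
  tab <- rbind(
    data.frame(subject_id = subj, operator_id = "O1", repetition = 2,
               score_type = "SV", value = a),
    data.frame(subject_id = subj, operator_id = "O1", repetition = 2,
               score_type = "QC", value = a))
  eq <- scoreAgreement(tab, "SV", "QC", 2)
  expect_equal(eq$mean_diff, 0)
  expect_equal(eq$sd_diff, 0)
  expect_equal(eq$trend_slope, 0)
  tab$value[tab$score_type == "QC"] <- a / 2
  prop <- scoreAgreement(tab, "SV", "QC", 2)
  expect_equal(prop$trend_slope, 2 / 3)   # d = a/2, mean = 3a/4
  expect_error(scoreAgreement(tab, "SV", "SC", 2), "no paired observations")
})

test_that("the reliability report is complete and exact on noise-free data", {
  cohort <- generateCohort(nSubjects = 4, nOperators = 3, seed = 31,
                           noise = operatorNoiseConfig())
  tab <- scoresToMeasurementTable(cohort$scores)
  rep <- reliabilityReport(tab)
  t <- rep$table
  for (st in c("QC", "SC", "SV")) {
    icc <- t[t$statistic == "icc_2_1" & t$score_type == st, ]
    expect_identical(nrow(icc), 2L)
    expect_equal(icc$value, c(1, 1))
    expect_equal(t[t$statistic == "sem" & t$score_type == st, "value"], 0)
    expect_equal(t[t$statistic == "mdd" & t$score_type == st, "value"], 0)
    expect_equal(t[t$statistic == "ba_ci_width" & t$score_type == st &
                     t$stratum == "pooled", "value"], 0)
  }
  expect_true(all(c("statistic", "score_type", "stratum", "n", "value",
                    "ci_low", "ci_high") %in% names(t)))
  expect_true(all(t$n > 0))
  oneRep <- tab[tab$repetition == 1, ]
  expect_error(reliabilityReport(oneRep), "requires 2 repetitions")
})
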