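test_that("error and MSE primitives match hand arithmetic and oracles", {
  expect_equal(predictionErrors(c(1, 2), c(2, 0)), c(1, 2))
  expect_equal(predictionErrors(1:4, 1:4), rep(0, 4))
  set.seed(61)
  yhat <- rnorm(4000); yobs <- yhat + rnorm(4000)
  expect_lt(abs(mean(predictionErrors(yobs, yhat, signed = TRUE))), 0.05)
  expect_error(predictionErrors(1:3, 1:2), "length")

  expect_equal(mse(1:3, 1:3), 0)
  expect_equal(mse(c(0, 1, 2), c(0, 0, 0)), 5 / 3)
  a <- rnorm(50); b <- rnorm(50)
  twoPass <- sum((a - b)^2) / 50
  expect_equal(mse(a, b), twoPass, tolerance = 1e-12)
  expect_error(mse(numeric(), numeric()), "empty")

  expect_equal(overfittingGap(1.2, 0.2), 1.0)
  expect_equal(overfittingGap(3, 3), 0)
  expect_equal(overfittingGap(2, 5), -overfittingGap(5, 2))
})

test_that("test power follows the sample-size algebra", {
  set.seed(62)
  e1 <- abs(rnorm(40, 1)); e2 <- abs(rnorm(40, 1.4))
  # equal means: power collapses to pnorm(-z_{alpha/2}) ~ 0.025
  p0 <- testPower(e1, e1 + (mean(e1) - mean(e1)), alpha = 0.05)
  expect_equal(p0$power, stats::pnorm(-stats::qnorm(0.975)), tolerance = 1e-12)
  # enormous mean difference: power -> 1
  expect_gt(testPower(e1, e1 - 100, alpha = 0.05)$power, 1 - 1e-12)
  # inversion round-trip: N at target power recovers the target
  N <- requiredSampleSize(e1, e2, alpha = 0.05, power = 0.8)
  expect_equal(testPower(e1, e2, alpha = 0.05, n = N)$power, 0.8,
               tolerance = 1e-9)
  # monotone in the mean gap and in N
  gaps <- seq(0.1, 1, by = 0.1)
  pw <- vapply(gaps, function(g)
    testPower(e1, e1 - g, alpha = 0.05)$power, numeric(1))
  expect_true(all(diff(pw) > 0))
  ns <- seq(10, 200, by = 10)
  pw2 <- vapply(ns, function(n)
    testPower(e1, e2, alpha = 0.05, n = n)$power, numeric(1))
  expect_true(all(diff(pw2) > 0))
})

test_that("the non-inferiority margin has its closed form and inverts", {
  # worked example: equal means, unit variances, N = 2
  eb <- c(0.5, 0.5 + sqrt(2))
  es <- eb + 0.25 - 0.25
  d <- nonInferiorityMargin(eb, es, alpha = 0.05, power = 0.8, n = 2)
  expect_equal(d, stats::qnorm(0.975) + stats::qnorm(0.8), tolerance = 1e-9)
  expect_equal(d, 2.801585, tolerance = 1e-6)

  set.seed(63)
  e1 <- abs(rnorm(30, 0.5)); e2 <- abs(rnorm(30, 0.3))
  # scale equivariance
  d1 <- nonInferiorityMargin(e1, e2)
  d2 <- nonInferiorityMargin(3 * e1, 3 * e2)
  expect_equal(d2, 3 * d1, tolerance = 1e-12)
  # inserting the margin into the sample-size relation returns N
  expect_equal(requiredSampleSize(e1, e2, delta = d1), 30, tolerance = 1e-9)
})

test_that("signed-rank p-values match exhaustive enumeration", {
  # T = 6 with X = (1, 2, 3): only the all-positive orthant reaches it
  w <- signedRankTest(c(1, 2, 3), c(0, 0, 0), alternative = "greater")
  expect_equal(w$statistic, 6)
  expect_equal(w$pValue, 1 / 8, tolerance = 1e-12)
  expect_equal(enumSignedRankP(c(1, 2, 3), "greater"), 1 / 8)

  set.seed(64)
  for (i in 1:12) {
    n <- sample(5:12, 1)
    x <- round(rnorm(n), 6)
    x <- x[x != 0]
    for (alt in c("greater", "less", "two.sided")) {
      w <- signedRankTest(x, rep(0, length(x)), alternative = alt)
      expect_equal(w$pValue, enumSignedRankP(x, alt), tolerance = 1e-10)
    }
  }

  # symmetric differences: one-sided p in the 0.5 neighborhood
  xs <- c(-3, -2, -1, 1, 2, 3) / 10
  ws <- signedRankTest(xs, rep(0, 6), alternative = "greater")
  expect_gt(ws$pValue, 0.3); expect_lt(ws$pValue, 0.7)

  expect_error(signedRankTest(c(1, 1), c(1, 1)), "zero")
})

test_that("signed-rank inference agrees with the reference implementation", {
  set.seed(65)
  for (i in 1:5) {
    a <- rnorm(15); b <- rnorm(15)
    w <- signedRankTest(a, b, mu = 0.1, alternative = "greater")
    ref <- suppressWarnings(stats::wilcox.test(a - b, mu = 0.1,
                                               alternative = "greater",
                                               conf.int = TRUE))
    expect_equal(w$pValue, ref$p.value, tolerance = 1e-10)
    w2 <- signedRankTest(a, b, alternative = "two.sided")
    ref2 <- suppressWarnings(stats::wilcox.test(a - b, conf.int = TRUE))
    expect_equal(c(w2$ciLower, w2$ciUpper), as.numeric(ref2$conf.int),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(w2$estimate, unname(ref2$estimate), tolerance = 1e-10)
  }
  # tied data go through the corrected normal approximation
  a <- c(1, 2, 2, 3, 3, 3, 4, 4, 5, 6, 7, 8) / 10
  b <- rep(0.25, 12)
  w <- signedRankTest(a, b, alternative = "greater")
  ref <- suppressWarnings(stats::wilcox.test(a - 0.25, alternative = "greater",
                                             exact = FALSE, correct = TRUE))
  expect_equal(w$pValue, ref$p.value, tolerance = 1e-10)
})

test_that("outcome classification covers the three regimes exclusively", {
  for (rule in c("rejection", "ciBounds")) {
    expect_equal(classifyOutcome(0.1, 0.5, 0.2, rule), "SUPERIOR")
    expect_equal(classifyOutcome(-0.1, 0.3, 0.2, rule), "EQUIVALENT")
    expect_equal(classifyOutcome(-0.5, -0.1, 0.2, rule), "INFERIOR")
  }
  # the disputed cell: significant but within-margin deficit
  expect_equal(classifyOutcome(-0.1, -0.01, 0.2, "rejection"), "EQUIVALENT")
  expect_equal(classifyOutcome(-0.1, -0.01, 0.2, "ciBounds"), "INFERIOR")
  # exhaustive mutual exclusivity on a grid, both rules
  grid <- expand.grid(lb = seq(-1, 1, by = 0.1), ub = seq(-1, 1, by = 0.1),
                      delta = c(0.05, 0.3, 1.5))
  grid <- grid[grid$lb <= grid$ub, ]
  sup <- grid$lb > 0
  outR <- mapply(classifyOutcome, grid$lb, grid$ub, grid$delta,
                 MoreArgs = list(rule = "rejection"))
  equR <- !sup & grid$lb > -grid$delta
  expect_identical(unname(outR),
                   ifelse(sup, "SUPERIOR", ifelse(equR, "EQUIVALENT",
                                                  "INFERIOR")))
  outC <- mapply(classifyOutcome, grid$lb, grid$ub, grid$delta,
                 MoreArgs = list(rule = "ciBounds"))
  equC <- !sup & grid$lb > -grid$delta & grid$ub > 0
  expect_identical(unname(outC),
                   ifelse(sup, "SUPERIOR", ifelse(equC, "EQUIVALENT",
                                                  "INFERIOR")))
  expect_error(classifyOutcome(0, 1, 0), "positive")
})

test_that("the KS normality check is calibrated and has power", {
  set.seed(66)
  rej <- vapply(1:200, function(i)
    ksNormality(rnorm(200), alpha = 0.05)$reject, logical(1))
  # plug-in parameters make the test conservative: at or below the level
  expect_lte(mean(rej), 0.07)
  expect_true(ksNormality(rexp(200), alpha = 0.05)$reject)
  expect_error(ksNormality(rep(1, 10)), "variance")
  expect_error(ksNormality(rnorm(3)), "at least 5")
})

test_that("the linearity RSS diagnostic separates additive from dominant", {
  # perfectly collinear class means: RSS = 0
  v <- matrix(rep(c(-1L, 0L, 1L), each = 4), 12, 2)
  dimnames(v) <- list(sprintf("s%02d", 1:12), c("m1", "m2"))
  G <- genotypeMatrix(v)
  y <- as.numeric(v[, 1L]) * 0.7
  t <- traitVector(stats::setNames((y - mean(y)) / stats::sd(y), rownames(v)))
  t@standardized <- TRUE
  expect_equal(linearityRSS(G, t, markerSubset = 1:2), 0, tolerance = 1e-20)

  # displaced heterozygote mean: RSS > 0
  y2 <- ifelse(v[, 1L] == 0L, 1.5, as.numeric(v[, 1L]))
  t2 <- traitVector(stats::setNames((y2 - mean(y2)) / stats::sd(y2),
                                    rownames(v)))
  t2@standardized <- TRUE
  expect_gt(linearityRSS(G, t2, markerSubset = 1:2), 0.01)

  expect_error(linearityRSS(G, traitVector(stats::setNames(y, rownames(v)))),
               "standardized")
})

test_that("outcome aggregation is a proportion count", {
  expect_equal(unname(aggregateOutcomes(rep("SUPERIOR", 4))), c(1, 0, 0))
  expect_equal(unname(aggregateOutcomes(c("SUPERIOR", "EQUIVALENT",
                                          "INFERIOR"))),
               rep(1 / 3, 3))
  set.seed(67)
  labs <- sample(c("SUPERIOR", "EQUIVALENT", "INFERIOR"), 30, replace = TRUE)
  expect_equal(unname(aggregateOutcomes(labs)),
               as.vector(table(factor(labs, c("SUPERIOR", "EQUIVALENT",
                                              "INFERIOR"))) / 30))
  expect_equal(sum(aggregateOutcomes(labs)), 1, tolerance = 1e-12)
})

test_that("the experiment runner is reproducible and complete", {
  G <- randomGenotypes(50, 40, seed = 68)
  t <- linearTrait(G, seed = 68)$trait
  specs <- list(baseModelSpec("rrblup"),
                baseModelSpec("bayesC", nIter = 150, burnIn = 50))
  res <- runExperiment(G, t, specs, k = 3, nTrials = 1,
                       metaCfg = metaConfig(epochs = 60), baseSeed = 4,
                       testUnit = "sampleErrors")
  expect_equal(nrow(res$metrics), 3L)          # stack + two base models
  expect_equal(length(res$reports), 2L)
  expect_true(all(res$metrics$mseTest >= 0 & res$metrics$mseTrain >= 0))
  expect_length(res$powers, 2L)
  expect_error(runExperiment(G, t, specs, nTrials = 2), "nTrials >= 5")

  res2 <- runExperiment(G, t, specs, k = 3, nTrials = 1,
                        metaCfg = metaConfig(epochs = 60), baseSeed = 4,
                        testUnit = "sampleErrors")
  expect_identical(res$metrics, res2$metrics)
  expect_identical(vapply(res$reports, outcome, character(1)),
                   vapply(res2$reports, outcome, character(1)))
})
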