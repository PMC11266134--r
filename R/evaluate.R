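#' Prediction errors
#'
#' Absolute errors `|y_obs - y_hat|` by default; the signed differences are
#' available with `signed = TRUE`. All downstream power/margin/signed-rank
#' machinery consumes absolute errors (signed errors have mean near zero for
#' any unbiased predictor, which degenerates the sample-size algebra).
#'
#' @param yObs,yHat numeric vectors of equal length.
#' @param signed return signed differences instead of absolute errors.
#' @return numeric vector of errors.
#' @export
predictionErrors <- function(yObs, yHat, signed = FALSE) {
  if (length(yObs) != length(yHat))
    stop("observed and predicted vectors differ in length")
  d <- as.numeric(yObs) - as.numeric(yHat)
  if (signed) d else abs(d)
}

#' Mean squared error
#'
#' @param yObs,yHat numeric vectors of equal, non-zero length.
#' @return mean of squared errors.
#' @export
mse <- function(yObs, yHat) {
  if (!length(yObs)) stop("empty input")
  if (length(yObs) != length(yHat)) stop("length mismatch")
  mean((as.numeric(yObs) - as.numeric(yHat))^2)
}

#' Overfitting gap
#'
#' `O = MSE_test - MSE_train`; may be negative. Larger values indicate
#' heavier over-tuning to the training data.
#'
#' @param mseTest,mseTrain finite reals.
#' @return their difference.
#' @export
overfittingGap <- function(mseTest, mseTrain) {
  stopifnot(is.finite(mseTest), is.finite(mseTrain))
  mseTest - mseTrain
}

#' Power of the two-sample comparison at a fixed sample size
#'
#' Inverts the sample-size relation
#' `N = 2 (Z_{a/2} + Z_{1-b})^2 Sp^2 / (e_base - e_stack)^2` with
#' `Sp^2 = (S2_base + S2_stack) / 2`:
#' `Z_{1-b} = |e_base - e_stack| sqrt(N / (S2_base + S2_stack)) - Z_{a/2}`,
#' and reports `power = pnorm(Z_{1-b})`.
#'
#' @param eBase,eStack error vectors of equal length >= 2.
#' @param alpha type-I error level, default 0.05.
#' @param n sample size N; defaults to the vector length.
#' @return list with `zPower`, `power`, `n`, `alpha`.
#' @export
testPower <- function(eBase, eStack, alpha = 0.05, n = length(eBase)) {
  if (length(eBase) != length(eStack)) stop("length mismatch")
  if (length(eBase) < 2L) stop("need at least two paired errors")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  s2 <- stats::var(eBase) + stats::var(eStack)
  if (s2 < 1e-24) stop("zero pooled variance")
  z <- abs(mean(eBase) - mean(eStack)) * sqrt(n / s2) -
    stats::qnorm(1 - alpha / 2)
  list(zPower = z, power = stats::pnorm(z), n = as.integer(n), alpha = alpha)
}

#' Required sample size for a non-inferiority comparison
#'
#' `N = 2 (Z_{a/2} + Z_{1-b})^2 Sp^2 / (e_base - e_stack - delta)^2`; with
#' `delta = 0` this is the plain two-sample relation. Exposed mainly because
#' it is the exact algebraic inverse of [nonInferiorityMargin].
#'
#' @param eBase,eStack error vectors.
#' @param alpha,power type-I error and target power.
#' @param delta non-inferiority margin (0 for the plain relation).
#' @return the (real-valued) sample size N.
#' @export
requiredSampleSize <- function(eBase, eStack, alpha = 0.05, power = 0.8,
                               delta = 0) {
  sp2 <- (stats::var(eBase) + stats::var(eStack)) / 2
  zsum <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  den <- (mean(eBase) - mean(eStack) - delta)^2
  if (den < 1e-24) stop("degenerate sample-size relation: zero mean offset")
  2 * zsum^2 * sp2 / den
}

#' Non-inferiority margin from a fixed sample size
#'
#' `Delta = e_base - e_stack + sqrt((S2_base + S2_stack) / N) *
#' (Z_{a/2} + Z_{1-b})`, under the restriction `Delta > 0`: a non-positive
#' margin is clipped (with a warning) to the second term alone, which is
#' always positive.
#'
#' @param eBase,eStack error vectors of equal length >= 2.
#' @param alpha type-I error level, default 0.05.
#' @param power target power, default 0.8.
#' @param n sample size N; defaults to the vector length.
#' @return the margin Delta (> 0).
#' @export
nonInferiorityMargin <- function(eBase, eStack, alpha = 0.05, power = 0.8,
                                 n = length(eBase)) {
  if (length(eBase) != length(eStack)) stop("length mismatch")
  if (n < 2L) stop("need n >= 2")
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1))
    stop("alpha and power must lie in (0, 1)")
  s2 <- stats::var(eBase) + stats::var(eStack)
  dm <- mean(eBase) - mean(eStack)
  spread <- sqrt(s2 / n) * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))
  if (s2 < 1e-24 && abs(dm) < 1e-24)
    stop("degenerate margin: equal means and zero variances")
  delta <- dm + spread
  if (delta <= 0) {
    warning("non-positive margin clipped to the variability term")
    delta <- spread
  }
  delta
}

#' Wilcoxon signed-rank test with a location shift and Hodges-Lehmann interval
#'
#' Tests the paired differences `X_i = eBase_i - eStack_i` shifted by `mu`:
#' zero differences are dropped, tied absolute values receive average ranks,
#' and the statistic is the signed-rank sum `T = sum sign(X_i) R_i`. The
#' p-value is exact (via the signed-rank null distribution) when `n <= 25`
#' and there are no ties, and a normal approximation with continuity and tie
#' corrections otherwise. The confidence interval is the Hodges-Lehmann
#' pseudomedian interval on the un-shifted differences.
#'
#' @param eBase,eStack paired error vectors.
#' @param mu location shift under the null (e.g. the margin Delta).
#' @param alternative `"greater"` (default; H1: difference > mu),
#'   `"less"` or `"two.sided"`.
#' @param confLevel confidence level of the Hodges-Lehmann interval.
#' @return list with `statistic` (T), `pValue`, `ciLower`, `ciUpper`,
#'   `estimate` (the pseudomedian) and `nPairs`.
#' @export
signedRankTest <- function(eBase, eStack, mu = 0,
                           alternative = c("greater", "less", "two.sided"),
                           confLevel = 0.95) {
  alternative <- match.arg(alternative)
  if (length(eBase) != length(eStack)) stop("length mismatch")
  d0 <- as.numeric(eBase) - as.numeric(eStack)     # un-shifted differences
  x <- d0 - mu
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) stop("all shifted differences are zero")
  r <- rank(abs(x))
  T <- sum(sign(x) * r)
  V <- sum(r[x > 0])                               # positive-rank sum
  ties <- any(duplicated(abs(x)))
  if (n <= 25L && !ties) {
    pGreater <- stats::psignrank(V - 1, n, lower.tail = FALSE)
    pLess <- stats::psignrank(V, n)
    p <- switch(alternative, greater = pGreater, less = pLess,
                two.sided = min(1, 2 * min(pGreater, pLess)))
  } else {
    ev <- n * (n + 1) / 4
    tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    zG <- (V - ev - 0.5) / sqrt(sigma2)
    zL <- (V - ev + 0.5) / sqrt(sigma2)
    pGreater <- stats::pnorm(zG, lower.tail = FALSE)
    pLess <- stats::pnorm(zL)
    p <- switch(alternative, greater = pGreater, less = pLess,
                two.sided = min(1, 2 * min(pGreater, pLess)))
  }
  ci <- .hodgesLehmann(d0[d0 != 0], confLevel)
  list(statistic = T, pValue = p, ciLower = ci[1L], ciUpper = ci[2L],
       estimate = ci[3L], nPairs = n)
}

# Hodges-Lehmann pseudomedian and two-sided CI from the Walsh averages.
.hodgesLehmann <- function(d, confLevel) {
  n <- length(d)
  if (n == 0L) return(c(NA_real_, NA_real_, NA_real_))
  w <- outer(d, d, "+")[upper.tri(diag(n), diag = TRUE)] / 2
  w <- sort(w)
  m <- length(w)                                   # n (n + 1) / 2
  est <- stats::median(w)
  alpha <- 1 - confLevel
  if (n <= 25L) {
    q <- stats::qsignrank(alpha / 2, n)
  } else {
    ev <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    q <- floor(ev + stats::qnorm(alpha / 2) * sigma)
  }
  q <- max(q, 0)
  lo <- if (q >= 1) w[q + 0] else -Inf
  hi <- if (q >= 1) w[m + 1 - q] else Inf
  # wilcox.test uses the achieved level qsignrank(alpha/2) which may sit one
  # step off; take the conservative bracket [q, m + 1 - q] with q >= 1
  if (q < 1) { lo <- w[1L]; hi <- w[m] }
  c(lo, hi, est)
}

#' Classify a non-inferiority outcome from confidence bounds
#'
#' SUPERIOR when the lower bound of the error-difference interval (comparator
#' minus candidate) exceeds 0. INFERIOR when the non-inferiority null cannot
#' be rejected - the lower bound does not exceed `-delta` - and rejection
#' yields EQUIVALENT otherwise (`rule = "rejection"`, the default, matching
#' the convention that failure to reject the non-inferiority null is what
#' establishes inferiority). The alternative `rule = "ciBounds"` additionally
#' requires the upper bound to exceed 0 for equivalence, so an interval
#' entirely inside `(-delta, 0]` - a significant but within-margin deficit -
#' is labelled INFERIOR instead of EQUIVALENT. The regimes are exhaustive and
#' mutually exclusive for any `lb <= ub` and `delta > 0` under either rule.
#'
#' @param ciLower,ciUpper confidence bounds with `ciLower <= ciUpper`.
#' @param delta positive non-inferiority margin.
#' @param rule `"rejection"` (default) or `"ciBounds"` (see above).
#' @return `"SUPERIOR"`, `"EQUIVALENT"` or `"INFERIOR"`.
#' @export
classifyOutcome <- function(ciLower, ciUpper, delta,
                            rule = c("rejection", "ciBounds")) {
  rule <- match.arg(rule)
  if (delta <= 0) stop("delta must be positive")
  if (ciLower > ciUpper) stop("ciLower exceeds ciUpper")
  if (ciLower > 0) return("SUPERIOR")
  equivalent <- if (rule == "rejection") ciLower > -delta
                else ciLower > -delta && ciUpper > 0
  if (equivalent) "EQUIVALENT" else "INFERIOR"
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test against a normal distribution with the sample's own
#' mean and standard deviation plugged in (as commonly practiced; this makes
#' the test conservative). A Lilliefors-style parametric-bootstrap correction
#' is available with `lilliefors = TRUE`.
#'
#' @param values numeric vector, length >= 5.
#' @param alpha significance level for the reject flag, default 0.05.
#' @param lilliefors use a parametric bootstrap (500 replicates) for the
#'   p-value, correcting for the estimated parameters.
#' @param nBoot bootstrap replicates for the Lilliefors variant.
#' @return list with `statistic`, `pValue`, `reject`.
#' @export
ksNormality <- function(values, alpha = 0.05, lilliefors = FALSE,
                        nBoot = 500L) {
  x <- as.numeric(values)
  if (length(x) < 5L) stop("need at least 5 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) stop("zero variance")
  ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s))
  p <- ks$p.value
  if (lilliefors) {
    n <- length(x)
    stat0 <- ks$statistic
    boots <- vapply(seq_len(nBoot), function(i) {
      xb <- stats::rnorm(n)
      suppressWarnings(stats::ks.test(xb, "pnorm", mean(xb),
                                      stats::sd(xb))$statistic)
    }, numeric(1))
    p <- mean(boots >= stat0)
  }
  list(statistic = unname(ks$statistic), pValue = p, reject = p < alpha)
}

#' Genotype-phenotype linearity diagnostic (class-mean RSS)
#'
#' For each selected marker, the mean standardized phenotype is computed
#' within each genotype class and a straight line of class mean versus
#' genotype code is fitted for that marker; the residual sums of squares are
#' summed over the selected markers. Perfectly additive class means give
#' RSS = 0; a displaced heterozygote mean (dominance) inflates it, since a
#' line through the three class means then cannot pass through all of them.
#' Markers with fewer than two observed classes contribute nothing (markers
#' with exactly two are fitted exactly and contribute zero).
#'
#' @param G a GenotypeMatrix without missing entries.
#' @param t a standardized TraitVector aligned to `G`.
#' @param markerSubset marker ids or indices to use; when `NULL`,
#'   `nMarkers` markers are drawn at random under `seed`.
#' @param nMarkers number of random markers when `markerSubset` is `NULL`
#'   (default 5).
#' @param seed RNG seed for the random marker draw.
#' @return the residual sum of squares of the pooled linear fit.
#' @export
linearityRSS <- function(G, t, markerSubset = NULL, nMarkers = 5L, seed = 1L) {
  if (!t@standardized)
    stop("linearityRSS expects a standardized trait (see standardizeTrait)")
  yv <- .asTraitValues(t, G)
  Z <- genotypes(G)
  if (is.null(markerSubset)) {
    set.seed(seed)
    markerSubset <- sample.int(ncol(Z), min(nMarkers, ncol(Z)))
  }
  used <- 0L
  rss <- 0
  for (j in markerSubset) {
    zj <- Z[, j]
    classes <- sort(unique(zj))
    if (length(classes) < 2L) next
    mns <- vapply(classes, function(cl) mean(yv[zj == cl]), numeric(1))
    fit <- stats::lm(mns ~ as.numeric(classes))
    rss <- rss + sum(stats::residuals(fit)^2)
    used <- used + 1L
  }
  if (!used)
    stop("all selected markers have fewer than two genotype classes")
  rss
}

#' Aggregate non-inferiority outcomes into proportions
#'
#' @param reports list of [NonInferiorityReport-class] objects (or a character
#'   vector of outcome labels).
#' @return named numeric vector of the three outcome proportions (sums to 1).
#' @export
aggregateOutcomes <- function(reports) {
  if (!length(reports)) stop("no reports to aggregate")
  labs <- if (is.character(reports)) reports
          else vapply(reports, outcome, character(1))
  c(prop_superior = mean(labs == "SUPERIOR"),
    prop_equivalent = mean(labs == "EQUIVALENT"),
    prop_inferior = mean(labs == "INFERIOR"))
}

.trialMetrics <- function(name, yTest, predTest, yTrain, predTrain, seed) {
  mTest <- mse(yTest, predTest)
  mTrain <- mse(yTrain, predTrain)
  data.frame(model = name, mseTest = mTest, mseTrain = mTrain,
             overfit = overfittingGap(mTest, mTrain),
             pearsonR = suppressWarnings(stats::cor(yTest, predTest)),
             trialSeed = seed)
}

#' Repeated-trial stacking experiment with non-inferiority evaluation
#'
#' Per trial: a seeded random split into training and test fractions, trait
#' standardization on the training split, the full stacking run plus every
#' base model's own refit (reused from the stack's step 2b), and test/train
#' MSE, overfitting gap and Pearson r for the stack and each base model.
#' Optional comparators (`"rkhs"`, `"bagging"`) are evaluated the same way.
#'
#' The non-inferiority evaluation then produces, per comparator model, the
#' margin at (`alpha`, `powerTarget`), the location-shifted signed-rank test,
#' and the three-way outcome classification. Two pairing units are offered:
#' \describe{
#'   \item{`"trialMSE"` (default)}{one test per comparator pairing the
#'     per-trial test MSEs across the `nTrials` repetitions (requires
#'     `nTrials >= 5`); the margin uses the per-sample absolute errors pooled
#'     over trials with N fixed at the dataset sample size. This is the unit
#'     under which per-trial MSEs, not individual samples, are the test
#'     statistic's data.}
#'   \item{`"sampleErrors"`}{one test per comparator per trial pairing the
#'     per-sample absolute test errors within that trial. Note that with
#'     strongly correlated predictors this pairing detects arbitrarily small
#'     systematic deficits.}
#' }
#'
#' @param G,t the full dataset (complete cases).
#' @param modelSpecs list of [baseModelSpec] objects.
#' @param k CV folds inside the stack, default 5.
#' @param metaCfg meta-model configuration.
#' @param nTrials number of independent trials, default 20.
#' @param trainFraction fraction of samples used for training, default 0.8.
#' @param alpha,powerTarget margin parameters, defaults 0.05 and 0.8.
#' @param baseSeed master seed; trial seeds derive from it.
#' @param comparators character subset of `c("rkhs", "bagging")`.
#' @param testUnit `"trialMSE"` or `"sampleErrors"` (see above).
#' @return list with `metrics` (data.frame over trials x models), `reports`
#'   (list of [NonInferiorityReport-class]), `powers` (named test powers from
#'   the pooled errors), and `outcomeRatios`.
#' @export
runExperiment <- function(G, t, modelSpecs, k = 5L, metaCfg = metaConfig(),
                          nTrials = 20L, trainFraction = 0.8, alpha = 0.05,
                          powerTarget = 0.8, baseSeed = 1L,
                          comparators = character(),
                          testUnit = c("trialMSE", "sampleErrors")) {
  testUnit <- match.arg(testUnit)
  if (nTrials < 1L) stop("nTrials must be >= 1")
  if (testUnit == "trialMSE" && nTrials < 5L)
    stop("testUnit = 'trialMSE' needs nTrials >= 5; use 'sampleErrors'")
  if (!(trainFraction > 0 && trainFraction < 1))
    stop("trainFraction must be in (0, 1)")
  if (length(comparators))
    comparators <- match.arg(comparators, c("rkhs", "bagging"),
                             several.ok = TRUE)
  n <- nSamples(G)
  set.seed(baseSeed)
  trialSeeds <- sample.int(.Machine$integer.max - 1L, nTrials)
  metrics <- list(); reports <- list(); errs <- list()
  for (tr in seq_len(nTrials)) {
    sd <- trialSeeds[tr]
    res <- tryCatch(
      .runOneTrial(G, t, modelSpecs, k, metaCfg, trainFraction, sd,
                   comparators),
      error = function(e)
        stop(sprintf("trial %d failed: %s", tr, conditionMessage(e)),
             call. = FALSE))
    res$metrics$trial <- tr
    metrics[[tr]] <- res$metrics
    errs[[tr]] <- res$errors
    if (testUnit == "sampleErrors") {
      for (nm in setdiff(names(res$errors), "stack"))
        reports[[length(reports) + 1L]] <-
          .makeNiReport(nm, res$errors[[nm]], res$errors$stack,
                        res$errors[[nm]], res$errors$stack,
                        alpha, powerTarget, n = length(res$errors$stack))
    }
  }
  metrics <- do.call(rbind, metrics)
  modelNames <- setdiff(names(errs[[1L]]), "stack")
  pooled <- lapply(c("stack", modelNames), function(nm)
    unlist(lapply(errs, `[[`, nm), use.names = FALSE))
  names(pooled) <- c("stack", modelNames)
  if (testUnit == "trialMSE") {
    for (nm in modelNames) {
      mseBase <- metrics$mseTest[metrics$model == nm]
      mseStack <- metrics$mseTest[metrics$model == "stack"]
      reports[[length(reports) + 1L]] <-
        .makeNiReport(nm, mseBase, mseStack, pooled[[nm]], pooled$stack,
                      alpha, powerTarget, n = n)
    }
  }
  powers <- vapply(modelNames, function(nm)
    testPower(pooled[[nm]], pooled$stack, alpha = alpha, n = n)$power,
    numeric(1))
  list(metrics = metrics, reports = reports, powers = powers,
       outcomeRatios = aggregateOutcomes(reports))
}

# Margin from the (pooled) per-sample errors at sample size n; signed-rank
# test and CI on the pairing vectors (trial MSEs or per-sample errors).
.makeNiReport <- function(name, pairBase, pairStack, eBase, eStack, alpha,
                          powerTarget, n) {
  delta <- nonInferiorityMargin(eBase, eStack, alpha = alpha,
                                power = powerTarget, n = n)
  wt <- signedRankTest(pairBase, pairStack, mu = delta,
                       alternative = "greater", confLevel = 1 - alpha)
  new("NonInferiorityReport",
      baseModel = name, delta = delta, alpha = alpha,
      powerTarget = powerTarget, statistic = wt$statistic,
      pValue = wt$pValue, ciLower = wt$ciLower, ciUpper = wt$ciUpper,
      outcome = classifyOutcome(wt$ciLower, wt$ciUpper, delta),
      nPairs = as.integer(wt$nPairs))
}

.runOneTrial <- function(G, t, modelSpecs, k, metaCfg, trainFraction, seed,
                         comparators) {
  n <- nSamples(G)
  set.seed(seed)
  trainIdx <- sort(sample.int(n, round(trainFraction * n)))
  testIdx <- setdiff(seq_len(n), trainIdx)
  ts <- standardizeTrait(t, trainIdx)
  yAll <- traitValues(ts)
  Gtr <- G[trainIdx, ]; Gte <- G[testIdx, ]
  yTr <- yAll[trainIdx]; yTe <- yAll[testIdx]

  stack <- runStacking(Gtr, yTr, Gte, modelSpecs, k = k, metaCfg = metaCfg,
                       seed = seed)
  stackTest <- finalPredictions(stack)
  stackTrain <- predict(stack@metaModel, stack@metaTrainFeatures)
  metrics <- list(.trialMetrics("stack", yTe, stackTest, yTr, stackTrain, seed))
  errors <- list(stack = predictionErrors(yTe, stackTest))

  addModel <- function(name, predTest, predTrain) {
    metrics[[length(metrics) + 1L]] <<-
      .trialMetrics(name, yTe, predTest, yTr, predTrain, seed)
    errors[[name]] <<- predictionErrors(yTe, predTest)
  }
  for (nm in names(stack@refitModels)) {
    fit <- stack@refitModels[[nm]]
    addModel(nm, predict(fit, Gte), predict(fit, Gtr))
  }
  if ("rkhs" %in% comparators) {
    fit <- fitRKHS(Gtr, yTr)
    addModel("rkhs", predict(fit, Gte), predict(fit, Gtr))
  }
  if ("bagging" %in% comparators) {
    predTe <- runBagging(Gtr, yTr, Gte, modelSpecs, seed = seed + 7L)
    predTr <- runBagging(Gtr, yTr, Gtr, modelSpecs, seed = seed + 7L)
    addModel("bagging", predTe, predTr)
  }
  list(metrics = do.call(rbind, metrics), errors = errors)
}
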