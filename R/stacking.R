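#' Specify a base model for stacking
#'
#' A base-model spec names one of the built-in models together with any fit
#' arguments; a custom `fitFun(G, y, seed)` returning an object with a
#' `predict(object, GenotypeMatrix)` method can be supplied instead (useful
#' for stubs and comparators).
#'
#' @param model one of `"rrblup"`, `"gblup"`, `"bayesA"`, `"bayesB"`,
#'   `"bayesC"`, `"bayesL"`, `"rkhs"`; ignored as a fitter when `fitFun` is
#'   given (but still used as the label).
#' @param ... fit arguments forwarded to the fitter (e.g. `hyper`, `nIter`
#'   via a prebuilt hyper object, `bandwidth`).
#' @param label column label in the feature matrices (defaults to `model`).
#' @param fitFun optional custom fitting function `function(G, y, seed)`.
#' @return a list of class `BaseModelSpec`.
#' @export
baseModelSpec <- function(model = c("rrblup", "gblup", "bayesA", "bayesB",
                                    "bayesC", "bayesL", "rkhs"),
                          ..., label = NULL, fitFun = NULL) {
  if (is.null(fitFun)) model <- match.arg(model)
  structure(list(model = model, args = list(...),
                 label = if (is.null(label)) model else label,
                 fitFun = fitFun),
            class = "BaseModelSpec")
}

#' Default panel of the six base models
#'
#' @param nIter,burnIn,thin Gibbs controls shared by the four Bayesian models.
#' @return list of [baseModelSpec] objects.
#' @export
defaultBaseModels <- function(nIter = 1500L, burnIn = 500L, thin = 5L) {
  gibbs <- list(nIter = nIter, burnIn = burnIn, thin = thin)
  c(list(baseModelSpec("rrblup"), baseModelSpec("gblup")),
    lapply(c("bayesA", "bayesB", "bayesC", "bayesL"), function(m)
      do.call(baseModelSpec, c(list(model = m), gibbs))))
}

#' Fit one base model from its spec
#'
#' @param spec a [baseModelSpec].
#' @param G,y training data.
#' @param seed RNG seed (used by the Bayesian samplers).
#' @return a fitted model with a `predict` method.
#' @export
fitBaseModel <- function(spec, G, y, seed = 1L) {
  stopifnot(inherits(spec, "BaseModelSpec"))
  if (!is.null(spec$fitFun)) return(spec$fitFun(G, y, seed))
  a <- spec$args
  switch(spec$model,
    rrblup = do.call(fitRRBLUP, c(list(G = G, y = y), a)),
    gblup = do.call(fitGBLUP, c(list(G = G, y = y), a)),
    rkhs = do.call(fitRKHS, c(list(G = G, y = y), a)),
    {
      gibbs <- a[intersect(names(a), c("nIter", "burnIn", "thin"))]
      rest <- a[setdiff(names(a), c("nIter", "burnIn", "thin"))]
      if (is.null(rest$hyper) && length(gibbs))
        rest$hyper <- do.call(bayesHyperDefaults,
                              c(list(y = y, G = G, model = spec$model), gibbs))
      do.call(fitBayes, c(list(G = G, y = y, model = spec$model, seed = seed),
                          rest))
    })
}

#' Random k-fold assignment of training samples
#'
#' A seeded random permutation split into k near-equal folds (sizes differ by
#' at most 1).
#'
#' @param n number of training samples.
#' @param k number of folds, `2 <= k <= n`.
#' @param seed RNG seed.
#' @return list with `foldOf` (integer vector of fold labels 1..k), `k`,
#'   `seed`.
#' @export
makeFolds <- function(n, k, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k cannot exceed the number of samples")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  list(foldOf = fold, k = as.integer(k), seed = as.integer(seed))
}

.foldSeeds <- function(seed, s, k) {
  set.seed(seed)
  matrix(sample.int(.Machine$integer.max - 1L, s * (k + 1L)), s, k + 1L)
}

#' Out-of-fold feature matrix for the meta-model (stacking step 2a)
#'
#' For every base model and fold, the model is fitted on the other k-1 folds
#' and predicts the held-out fold, so each training sample receives exactly
#' one out-of-fold prediction per model and exactly `k * s` base fits are
#' performed.
#'
#' @param G,y training data.
#' @param modelSpecs list of [baseModelSpec] objects.
#' @param folds a [makeFolds] assignment for `nSamples(G)`.
#' @param seed RNG seed from which per-(model, fold) sampler seeds are drawn.
#' @return list with `features` (n x s matrix, columns labelled by spec) and
#'   `fitLog` (one row per fit: model, fold, trainN, seed).
#' @export
buildMetaTraining <- function(G, y, modelSpecs, folds, seed = 1L) {
  if (!length(modelSpecs)) stop("modelSpecs must be non-empty")
  yv <- .asTraitValues(y, G)
  n <- nSamples(G); s <- length(modelSpecs); k <- folds$k
  if (length(folds$foldOf) != n) stop("fold assignment does not match n")
  seeds <- .foldSeeds(seed, s, k)
  feats <- matrix(NA_real_, n, s,
                  dimnames = list(sampleIds(G),
                                  vapply(modelSpecs, `[[`, "", "label")))
  log <- vector("list", s * k)
  for (si in seq_len(s)) {
    for (f in seq_len(k)) {
      tr <- folds$foldOf != f
      fit <- tryCatch(
        fitBaseModel(modelSpecs[[si]], G[tr, ], yv[tr], seed = seeds[si, f]),
        error = function(e)
          stop(sprintf("base fit failed (model '%s', fold %d): %s",
                       modelSpecs[[si]]$label, f, conditionMessage(e)),
               call. = FALSE))
      feats[!tr, si] <- predict(fit, G[!tr, ])
      log[[(si - 1L) * k + f]] <- data.frame(
        model = modelSpecs[[si]]$label, fold = f, trainN = sum(tr),
        seed = seeds[si, f])
    }
  }
  list(features = feats, fitLog = do.call(rbind, log))
}

#' Test feature matrix for the meta-model (stacking step 2b)
#'
#' Each base model is refit once on the full training set and predicts all m
#' test samples.
#'
#' @param G,y full training data.
#' @param Gtest test genotypes on the same markers.
#' @param modelSpecs list of [baseModelSpec] objects.
#' @param seed RNG seed (per-model refit seeds derive from it).
#' @return list with `features` (m x s matrix) and `models` (the refit base
#'   models, named by label).
#' @export
buildMetaTest <- function(G, y, Gtest, modelSpecs, seed = 1L) {
  if (!length(modelSpecs)) stop("modelSpecs must be non-empty")
  yv <- .asTraitValues(y, G)
  s <- length(modelSpecs)
  seeds <- .foldSeeds(seed, s, 1L)[, 2L]
  labels <- vapply(modelSpecs, `[[`, "", "label")
  models <- stats::setNames(vector("list", s), labels)
  feats <- matrix(NA_real_, nSamples(Gtest), s,
                  dimnames = list(sampleIds(Gtest), labels))
  for (si in seq_len(s)) {
    fit <- tryCatch(
      fitBaseModel(modelSpecs[[si]], G, yv, seed = seeds[si]),
      error = function(e)
        stop(sprintf("base refit failed (model '%s'): %s", labels[si],
                     conditionMessage(e)), call. = FALSE))
    models[[si]] <- fit
    feats[, si] <- predict(fit, Gtest)
  }
  list(features = feats, models = models)
}

#' Run the three-step stacked-generalization procedure
#'
#' Step 1: seeded fold assignment of the (externally supplied) training split.
#' Step 2: the out-of-fold training features ([buildMetaTraining]) and the
#' refit test features ([buildMetaTest]). Step 3: the perceptron meta-model is
#' trained on the out-of-fold features against the training phenotypes and
#' applied to the test features.
#'
#' @param Gtrain,ytrain training genotypes and phenotype.
#' @param Gtest test genotypes (same markers).
#' @param modelSpecs list of [baseModelSpec] objects (s >= 1).
#' @param k number of CV folds, default 5.
#' @param metaCfg a [metaConfig]; its seed is overridden by `seed` unless
#'   `keepMetaSeed = TRUE`.
#' @param seed master seed for folds, samplers and the meta-model.
#' @param keepMetaSeed keep `metaCfg$seed` instead of deriving it from `seed`.
#' @return a [StackingResult-class].
#' @export
runStacking <- function(Gtrain, ytrain, Gtest, modelSpecs, k = 5L,
                        metaCfg = metaConfig(), seed = 1L,
                        keepMetaSeed = FALSE) {
  yv <- .asTraitValues(ytrain, Gtrain)
  folds <- makeFolds(nSamples(Gtrain), k, seed = seed)
  oof <- buildMetaTraining(Gtrain, yv, modelSpecs, folds, seed = seed + 1L)
  ref <- buildMetaTest(Gtrain, yv, Gtest, modelSpecs, seed = seed + 2L)
  if (!keepMetaSeed) metaCfg$seed <- seed + 3L
  meta <- trainMLP(oof$features, yv, metaCfg)
  final <- predict(meta, ref$features)
  names(final) <- sampleIds(Gtest)
  new("StackingResult", metaTrainFeatures = oof$features,
      metaTrainTargets = yv, metaTestFeatures = ref$features,
      metaModel = meta, finalPredictions = final,
      baseTestPredictions = ref$features,
      fitCount = as.integer(nrow(oof$fitLog)), fitLog = oof$fitLog,
      refitModels = ref$models)
}

#' Bagging comparator: average the base models' test predictions
#'
#' Each base model is trained once - on a seeded bootstrap resample of the
#' training set when `bootstrap = TRUE` (the default), on the full set
#' otherwise - and the test predictions are averaged with equal weights.
#'
#' @inheritParams runStacking
#' @param bootstrap resample the training set per model.
#' @return numeric vector of m averaged predictions.
#' @export
runBagging <- function(Gtrain, ytrain, Gtest, modelSpecs, bootstrap = TRUE,
                       seed = 1L) {
  if (!length(modelSpecs)) stop("modelSpecs must be non-empty")
  yv <- .asTraitValues(ytrain, Gtrain)
  s <- length(modelSpecs)
  n <- nSamples(Gtrain)
  seeds <- .foldSeeds(seed, s, 1L)
  preds <- matrix(NA_real_, nSamples(Gtest), s)
  for (si in seq_len(s)) {
    if (bootstrap) {
      set.seed(seeds[si, 1L])
      idx <- sample.int(n, n, replace = TRUE)
      v <- genotypes(Gtrain)[idx, , drop = FALSE]
      rownames(v) <- make.unique(rownames(v))   # resampled rows need unique ids
      Gb <- genotypeMatrix(v)
    } else {
      idx <- seq_len(n)
      Gb <- Gtrain
    }
    fit <- fitBaseModel(modelSpecs[[si]], Gb, yv[idx], seed = seeds[si, 2L])
    preds[, si] <- predict(fit, Gtest)
  }
  stats::setNames(rowMeans(preds), sampleIds(Gtest))
}
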