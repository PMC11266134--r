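#' Genomic relationship matrix (VanRaden scaling)
#'
#' Columns of the -1/0/1 genotype matrix are centered by `2 p_j - 1` (the mean
#' under Hardy-Weinberg given allele frequency `p_j`) and the cross-product is
#' scaled by `k = 1 / (2 sum_j p_j (1 - p_j))`, giving `G = k Zc Zc'`.
#'
#' @param G a GenotypeMatrix without missing entries.
#' @return list with `values` (the n x n PSD kernel), `k`, and `centerFreq`
#'   (the per-marker centering constants `2 p_j - 1`).
#' @export
computeGRM <- function(G) {
  Z <- genotypes(G)
  if (anyNA(Z)) stop("computeGRM requires complete genotypes")
  p <- colMeans(Z + 1L) / 2                       # allele frequency of A
  het <- sum(p * (1 - p))
  if (het < 1e-12)
    stop("all markers are monomorphic: the GRM scale constant is undefined")
  k <- 1 / (2 * het)
  ctr <- 2 * p - 1
  Zc <- sweep(matrix(as.numeric(Z), nrow(Z), ncol(Z)), 2L, ctr)
  K <- k * tcrossprod(Zc)
  dimnames(K) <- list(rownames(Z), rownames(Z))
  list(values = (K + t(K)) / 2, k = k, centerFreq = ctr)
}

.scaledDesign <- function(Z, centerFreq, scaleFactor) {
  scaleFactor * sweep(matrix(as.numeric(Z), nrow(Z), ncol(Z),
                             dimnames = dimnames(Z)), 2L, centerFreq)
}

#' Ridge-regression BLUP
#'
#' Fits `y = mu + W u + e` with `u ~ N(0, varU I)`, estimating
#' `lambda = varE / varU` by REML through the spectral decomposition of `W W'`
#' and solving the ridge normal equations for the marker effects. By default
#' `W` is the VanRaden-centered and k-scaled genotype design, which makes the
#' fit exactly the marker-effect view of [fitGBLUP] (the two are equivalent
#' under matched scaling).
#'
#' @param G training GenotypeMatrix.
#' @param y a TraitVector aligned to `G` (or a bare numeric vector).
#' @param lambda optional fixed variance ratio; when `NULL` (default) it is
#'   estimated by REML over `[1e-5, 1e5]` with tolerance 1e-8.
#' @param scaling `"grm"` (default; VanRaden centering and scaling) or
#'   `"none"` (raw -1/0/1 codes).
#' @return a [MarkerEffectModel-class].
#' @export
fitRRBLUP <- function(G, y, lambda = NULL, scaling = c("grm", "none")) {
  scaling <- match.arg(scaling)
  yv <- .asTraitValues(y, G)
  Z <- genotypes(G)
  if (anyNA(Z)) stop("fitRRBLUP requires complete genotypes")
  if (scaling == "grm") {
    grm <- computeGRM(G)
    ctr <- grm$centerFreq; sf <- sqrt(grm$k)
  } else {
    ctr <- rep(0, ncol(Z)); sf <- 1
  }
  W <- .scaledDesign(Z, ctr, sf)
  fit <- remlKernel(tcrossprod(W), yv, lambda = lambda)
  u <- drop(crossprod(W, fit$alpha))
  names(u) <- colnames(Z)
  new("MarkerEffectModel", modelName = "rrblup", intercept = fit$mu,
      varE = fit$varE, varU = fit$varU, effects = u, center = ctr,
      scaleFactor = sf,
      diagnostics = list(lambda = fit$lambda, logLik = fit$logLik,
                         converged = fit$converged))
}

#' GBLUP: mixed-model prediction on the genomic relationship matrix
#'
#' Fits `y = mu + m + e` with `m ~ N(0, varU * GRM)` by the same REML
#' machinery as [fitRRBLUP]; no marker effects are estimated. Prediction for
#' new samples goes through the cross-kernel `k Zc_new Zc_train'`.
#'
#' @inheritParams fitRRBLUP
#' @return a [KernelModel-class].
#' @export
fitGBLUP <- function(G, y, lambda = NULL) {
  yv <- .asTraitValues(y, G)
  grm <- computeGRM(G)
  fit <- remlKernel(grm$values, yv, lambda = lambda)
  new("KernelModel", modelName = "gblup", intercept = fit$mu,
      varE = fit$varE, varU = fit$varU, alpha = fit$alpha,
      trainValues = genotypes(G), kind = "GRM", k = grm$k,
      centerFreq = grm$centerFreq, lambda = fit$lambda,
      diagnostics = list(logLik = fit$logLik, converged = fit$converged))
}

#' RKHS regression with a Gaussian genotype kernel
#'
#' The kernel is `K_ij = exp(-bandwidth * d2_ij)` on squared Euclidean
#' genotype distances scaled by their sample mean (off-diagonal mean), fitted
#' with the same REML mixed-model machinery as [fitGBLUP] with `K` in place of
#' the GRM. The kernel can track genotype-class structure that the linear
#' models cannot.
#'
#' @inheritParams fitRRBLUP
#' @param bandwidth positive kernel bandwidth on the scaled distances
#'   (default 1).
#' @return a [KernelModel-class].
#' @export
fitRKHS <- function(G, y, bandwidth = 1, lambda = NULL) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  yv <- .asTraitValues(y, G)
  Z <- matrix(as.numeric(genotypes(G)), nSamples(G), nMarkers(G),
              dimnames = dimnames(genotypes(G)))
  D2 <- .sqDist(Z, Z)
  n <- nrow(Z)
  off <- D2[upper.tri(D2)]
  d2s <- if (length(off) && mean(off) > 0) mean(off) else 1
  K <- exp(-bandwidth * D2 / d2s)
  fit <- remlKernel(K, yv)
  new("KernelModel", modelName = "rkhs", intercept = fit$mu,
      varE = fit$varE, varU = fit$varU, alpha = fit$alpha,
      trainValues = genotypes(G), kind = "GAUSSIAN", bandwidth = bandwidth,
      d2Scale = d2s, lambda = fit$lambda,
      diagnostics = list(logLik = fit$logLik, converged = fit$converged))
}

.sqDist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

.asTraitValues <- function(y, G) {
  if (is(y, "TraitVector")) {
    yv <- traitValues(y)
    if (!is.null(names(yv)) && !is.null(sampleIds(G))) {
      if (!all(sampleIds(G) %in% names(yv)))
        stop("trait is missing values for some genotype samples")
      yv <- yv[sampleIds(G)]
    }
  } else yv <- as.numeric(y)
  if (length(yv) != nSamples(G))
    stop("phenotype length does not match the genotype sample count")
  if (anyNA(yv)) stop("phenotype contains missing values; run dropMissing first")
  yv
}

#' Default Bayesian hyper-parameters from the variance partition rule
#'
#' A proportion `R2` of the phenotypic variance is assigned a priori to the
#' marker effects and the rest to the residual: the residual prior scale is
#' set so its mode equals `(1 - R2) Var(y)`, and the marker-effect scale so
#' the implied genetic variance `sum_j Var(Z_j) E[beta_j^2]` equals
#' `R2 Var(y)` under the model's prior (with `E[beta^2]` divided by `pi` for
#' the variable-selection models BayesB/C). The Bayesian-lasso penalty's Gamma
#' prior (shape 1.1) is centered analogously.
#'
#' @param y TraitVector or numeric phenotype.
#' @param G training GenotypeMatrix.
#' @param R2 variance fraction for markers, in (0, 1); default 0.5.
#' @param model one of `"bayesA"`, `"bayesB"`, `"bayesC"`, `"bayesL"`.
#' @param pi proportion of non-null effects (BayesB/C), default 0.5.
#' @param nu scaled-t / inverse-chi-square degrees of freedom, default 5.
#' @param nIter,burnIn,thin Gibbs chain controls (defaults 1500/500/5).
#' @param updateSbeta whether the Gamma hyper-prior update on the
#'   marker-effect scale is active (BayesA/B), default TRUE.
#' @return a [BayesHyper-class].
#' @export
bayesHyperDefaults <- function(y, G, R2 = 0.5,
                               model = c("bayesA", "bayesB", "bayesC", "bayesL"),
                               pi = 0.5, nu = 5, nIter = 1500L, burnIn = 500L,
                               thin = 5L, updateSbeta = TRUE) {
  model <- match.arg(model)
  yv <- if (is(y, "TraitVector")) traitValues(y) else as.numeric(y)
  vy <- stats::var(yv)
  if (!is.finite(vy) || vy < 1e-12) stop("zero phenotypic variance")
  Z <- genotypes(G)
  msx <- sum(apply(Z, 2L, stats::var))
  if (msx < 1e-12) stop("all markers monomorphic: marker variance sum is zero")
  dfE <- 5
  Se <- vy * (1 - R2) * (dfE + 2)         # prior mode (1 - R2) Var(y)
  piEff <- if (model %in% c("bayesB", "bayesC")) pi else 1
  # E[beta^2] targets: t / scaled-inv-chi2 families have E[beta^2] = S/(nu-2)
  Sb <- R2 * vy * (nu - 2) / (msx * piEff)
  lam2 <- 2 * (1 - R2) * msx / (R2)       # E[beta^2] = 2 varE / lambda2
  l2shape <- 1.1
  structure(new("BayesHyper", nu = nu, Sbeta = Sb, pi = piEff,
                piPrior = c(2, 2), SbetaGamma = c(1.1, 1.1 / Sb),
                lambda2 = lam2, lambda2Gamma = c(l2shape, (l2shape - 1) / lam2),
                dfE = dfE, Se = Se, R2 = R2, nIter = as.integer(nIter),
                burnIn = as.integer(burnIn), thin = as.integer(thin),
                updateSbeta = updateSbeta, varEFixed = NA_real_,
                varBFixed = NA_real_))
}

#' Fit a Bayesian alphabet model by single-site Gibbs sampling
#'
#' Runs the conjugate single-site sampler for the chosen prior family:
#' \describe{
#'   \item{bayesA}{per-marker variance, scaled-inverse-chi-square(nu + 1, .)
#'     update, with a Gamma hyper-prior update on the scale `Sbeta`.}
#'   \item{bayesB}{BayesA plus a per-marker inclusion indicator (drawn from
#'     the marginal likelihood with the effect integrated out) and a Beta
#'     update for `pi`.}
#'   \item{bayesC}{common slab variance (scaled-inverse-chi-square) plus
#'     indicators and the Beta update for `pi`.}
#'   \item{bayesL}{Bayesian lasso via the exponential-mixture representation
#'     (per-marker tau^2, inverse-Gaussian update) with a Gamma update for
#'     lambda^2.}
#' }
#' Posterior means of the marker effects and intercept are accumulated from
#' post-burn-in thinned draws. The sampler uses R's RNG, so `seed` makes the
#' fit bit-reproducible.
#'
#' @param G training GenotypeMatrix.
#' @param y TraitVector or numeric phenotype.
#' @param model `"bayesA"`, `"bayesB"`, `"bayesC"` or `"bayesL"`.
#' @param hyper a [BayesHyper-class]; defaults to
#'   `bayesHyperDefaults(y, G, model = model)`.
#' @param seed integer RNG seed.
#' @param keepTrace retain the thinned draws of the marker effects in
#'   `diagnostics$betaTrace` (memory-heavy for large p; meant for small
#'   conjugate checks).
#' @return a [MarkerEffectModel-class] with posterior-mean effects.
#' @export
fitBayes <- function(G, y, model = c("bayesA", "bayesB", "bayesC", "bayesL"),
                     hyper = NULL, seed = 1L, keepTrace = FALSE) {
  model <- match.arg(model)
  yv <- .asTraitValues(y, G)
  Z <- genotypes(G)
  if (anyNA(Z)) stop("fitBayes requires complete genotypes")
  if (is.null(hyper)) hyper <- bayesHyperDefaults(yv, G, model = model)
  validObject(hyper)
  modelCode <- match(model, c("bayesA", "bayesB", "bayesC", "bayesL"))
  set.seed(seed)
  res <- gibbs_sampler(matrix(as.numeric(Z), nrow(Z), ncol(Z)), yv,
                       modelCode, hyper@nu, hyper@Sbeta, hyper@updateSbeta,
                       hyper@SbetaGamma[1L], hyper@SbetaGamma[2L],
                       hyper@pi, hyper@piPrior[1L], hyper@piPrior[2L],
                       model %in% c("bayesB", "bayesC") && hyper@pi < 1,
                       hyper@lambda2, hyper@lambda2Gamma[1L],
                       hyper@lambda2Gamma[2L], hyper@dfE, hyper@Se,
                       ifelse(is.na(hyper@varEFixed), -1, hyper@varEFixed),
                       ifelse(is.na(hyper@varBFixed), -1, hyper@varBFixed),
                       hyper@nIter, hyper@burnIn, hyper@thin, keepTrace)
  eff <- drop(res$beta)
  names(eff) <- colnames(Z)
  diag <- list(nSaved = res$nSaved, piMean = res$piMean,
               varETrace = drop(res$varETrace), hyper = hyper, seed = seed)
  if (keepTrace) diag$betaTrace <- res$betaTrace
  new("MarkerEffectModel", modelName = model, intercept = res$mu,
      varE = res$varE, varU = max(res$varB, 0), effects = eff,
      center = rep(0, ncol(Z)), scaleFactor = 1, diagnostics = diag)
}

#' Choose the marker-variance fraction R2 by k-fold cross-validation
#'
#' Runs a grid of `R2` values through `k`-fold CV of the given Bayesian model
#' and returns the value minimizing mean out-of-fold MSE; ties break toward
#' the smaller `R2`.
#'
#' @param G,y training data.
#' @param grid numeric vector of candidate `R2` values in (0, 1).
#' @param k number of folds (default 5).
#' @param model Bayesian model name passed to [fitBayes].
#' @param seed RNG seed controlling folds and samplers.
#' @param ... further arguments to [bayesHyperDefaults] (e.g. `nIter`).
#' @return the selected `R2` value.
#' @export
tuneR2 <- function(G, y, grid = c(0.1, 0.3, 0.5, 0.7, 0.9), k = 5L,
                   model = "bayesC", seed = 1L, ...) {
  if (!length(grid)) stop("empty R2 grid")
  if (k < 2L) stop("k must be at least 2")
  grid <- sort(unique(grid))
  yv <- .asTraitValues(y, G)
  folds <- makeFolds(nSamples(G), k, seed)
  cvMse <- vapply(grid, function(r2) {
    errs <- unlist(lapply(seq_len(k), function(f) {
      tr <- folds$foldOf != f; te <- !tr
      hy <- bayesHyperDefaults(yv[tr], G[tr, ], R2 = r2, model = model, ...)
      fit <- tryCatch(fitBayes(G[tr, ], yv[tr], model = model, hyper = hy,
                               seed = seed + f),
                      error = function(e)
                        stop(sprintf("R2 = %g failed in fold %d: %s", r2, f,
                                     conditionMessage(e)), call. = FALSE))
      (yv[te] - predict(fit, G[te, ]))^2
    }))
    mean(errs)
  }, numeric(1))
  grid[which.min(cvMse)]                  # which.min takes the first (smallest R2)
}

#' Predict phenotypes for new samples
#'
#' Marker-effect models predict `intercept + f(Z_new) effects`; kernel models
#' predict `intercept + K_cross alpha` with the cross-kernel computed against
#' the retained training genotypes. Marker ids of `newdata` must match the
#' training panel.
#'
#' @param object a fitted [GsModel-class].
#' @param newdata a GenotypeMatrix on the same markers.
#' @param ... ignored.
#' @return numeric vector of predictions named by sample id.
#' @name predict-GsModel
NULL

.checkMarkers <- function(object, newdata, trainIds) {
  ids <- markerIds(newdata)
  if (!is.null(trainIds) && !identical(ids, trainIds)) {
    missing <- setdiff(trainIds, ids)
    if (length(missing))
      stop("newdata is missing training markers: ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) ", ..." else "")
    stop("marker order of newdata differs from the training panel")
  }
}

#' @rdname predict-GsModel
#' @export
setMethod("predict", "MarkerEffectModel", function(object, newdata, ...) {
  .checkMarkers(object, newdata, names(object@effects))
  W <- .scaledDesign(genotypes(newdata), object@center, object@scaleFactor)
  stats::setNames(drop(object@intercept + W %*% object@effects),
                  sampleIds(newdata))
})

#' @rdname predict-GsModel
#' @export
setMethod("predict", "KernelModel", function(object, newdata, ...) {
  .checkMarkers(object, newdata, colnames(object@trainValues))
  Znew <- matrix(as.numeric(genotypes(newdata)), nSamples(newdata),
                 nMarkers(newdata), dimnames = dimnames(genotypes(newdata)))
  Ztr <- matrix(as.numeric(object@trainValues), nrow(object@trainValues),
                ncol(object@trainValues))
  if (object@kind == "GRM") {
    Zc <- sweep(Znew, 2L, object@centerFreq)
    Zt <- sweep(Ztr, 2L, object@centerFreq)
    Kx <- object@k * tcrossprod(Zc, Zt)
  } else {
    Kx <- exp(-object@bandwidth * .sqDist(Znew, Ztr) / object@d2Scale)
  }
  stats::setNames(drop(object@intercept + Kx %*% object@alpha),
                  sampleIds(newdata))
})
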