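#' @import methods
NULL

GENOTYPE_CODES <- c(-1L, 0L, 1L)

#' GenotypeMatrix: integer-coded SNP markers for a set of samples
#'
#' Samples are rows, markers are columns. The canonical internal coding is
#' -1/0/1 for the aa/Aa/AA genotype classes; matrices supplied in 0/1/2 dosage
#' coding are shifted by -1 on construction. Missing genotypes are stored as
#' `NA`.
#'
#' @slot values integer matrix (samples x markers) with unique dimnames.
#' @slot coding character, always `"MINUS1_0_1"` after construction.
#'
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(values = "matrix", coding = "character"))

setValidity("GenotypeMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.integer(v)) msg <- c(msg, "genotype values must be an integer matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "sample and marker identifiers (dimnames) are required")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate marker ids")
  }
  if (!identical(object@coding, "MINUS1_0_1"))
    msg <- c(msg, "internal coding must be MINUS1_0_1")
  bad <- !is.na(v) & !(v %in% GENOTYPE_CODES)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf("entry outside {-1,0,1} at sample '%s', marker '%s'",
                          rownames(v)[idx[1L]], colnames(v)[idx[2L]]))
  }
  if (length(msg)) msg else TRUE
})

#' TraitVector: one quantitative phenotype aligned to samples
#'
#' @slot values named numeric vector (names are sample ids).
#' @slot traitName character scalar.
#' @slot standardized logical; TRUE when training-split statistics have been
#'   removed.
#' @slot center,scale numeric; the statistics used for standardization (0/1
#'   when unstandardized).
#'
#' @aliases TraitVector-class
#' @exportClass TraitVector
setClass("TraitVector",
  representation(values = "numeric", traitName = "character",
                 standardized = "logical", center = "numeric",
                 scale = "numeric"),
  prototype(standardized = FALSE, center = 0, scale = 1))

setValidity("TraitVector", function(object) {
  msg <- character()
  if (is.null(names(object@values)))
    msg <- c(msg, "trait values must be named by sample id")
  else if (anyDuplicated(names(object@values)))
    msg <- c(msg, "duplicate sample ids in trait")
  if (length(object@traitName) != 1L) msg <- c(msg, "traitName must be scalar")
  if (length(object@scale) == 1L && !is.na(object@scale) && object@scale <= 0)
    msg <- c(msg, "scale must be positive")
  if (length(msg)) msg else TRUE
})

#' BayesHyper: hyper-parameters of the Bayesian alphabet samplers
#'
#' The penalized hyper-parameters are derived from the variance partition rule:
#' a proportion `R2` of the phenotypic variance is assigned a priori to the
#' marker effects and `1 - R2` to the residual.
#'
#' @slot nu degrees of freedom of the scaled-t / scaled-inverse-chi-square
#'   components (default 5).
#' @slot Sbeta scale of the marker-effect prior.
#' @slot pi proportion of non-null effects (BayesB/C); initial value when the
#'   Beta update is active.
#' @slot piPrior numeric(2), the Beta(a, b) prior on pi.
#' @slot SbetaGamma numeric(2), shape and rate of the Gamma hyper-prior on
#'   Sbeta (BayesA/B).
#' @slot lambda2 initial value of the Bayesian-lasso penalty lambda^2.
#' @slot lambda2Gamma numeric(2), shape and rate of its Gamma prior
#'   (shape 1.1 by default).
#' @slot dfE,Se residual-variance prior degrees of freedom and scale.
#' @slot R2 variance fraction assigned to markers, in (0,1).
#' @slot nIter,burnIn,thin Gibbs chain controls.
#' @slot updateSbeta logical, whether the Gamma hyper-prior update on Sbeta is
#'   active.
#' @slot varEFixed,varBFixed optional fixed variances (NA = sampled); used for
#'   conjugate-reduction checks.
#'
#' @aliases BayesHyper-class
#' @exportClass BayesHyper
setClass("BayesHyper",
  representation(nu = "numeric", Sbeta = "numeric", pi = "numeric",
                 piPrior = "numeric", SbetaGamma = "numeric",
                 lambda2 = "numeric", lambda2Gamma = "numeric",
                 dfE = "numeric", Se = "numeric", R2 = "numeric",
                 nIter = "integer", burnIn = "integer", thin = "integer",
                 updateSbeta = "logical", varEFixed = "numeric",
                 varBFixed = "numeric"))

setValidity("BayesHyper", function(object) {
  msg <- character()
  if (!(object@pi > 0 && object@pi <= 1)) msg <- c(msg, "pi must be in (0, 1]")
  if (!(object@R2 > 0 && object@R2 < 1)) msg <- c(msg, "R2 must be in (0, 1)")
  if (!(object@burnIn > 0 && object@burnIn < object@nIter))
    msg <- c(msg, "need 0 < burnIn < nIter")
  if (object@thin < 1L) msg <- c(msg, "thin must be >= 1")
  if (object@nu <= 2) msg <- c(msg, "nu must exceed 2 for a finite prior variance")
  if (length(msg)) msg else TRUE
})

#' Virtual parent of all fitted genomic-prediction models
#'
#' @slot modelName one of rrblup, gblup, bayesA, bayesB, bayesC, bayesL, rkhs.
#' @slot intercept fitted overall mean (the only fixed effect).
#' @slot varE,varU residual and genetic variance components (REML estimates or
#'   posterior means).
#'
#' @aliases GsModel-class
#' @exportClass GsModel
setClass("GsModel",
  representation("VIRTUAL", modelName = "character", intercept = "numeric",
                 varE = "numeric", varU = "numeric"))

#' Marker-effect model: prediction via estimated per-marker effects
#'
#' Covers rrBLUP and the Bayesian alphabet models. Prediction for new samples
#' is `intercept + f(Z_new) %*% effects`, where `f` applies the stored
#' column centering and scaling.
#'
#' @slot effects per-marker effect estimates, named by marker id.
#' @slot center per-marker centering applied to genotype columns before the
#'   effects act (zero vector for the Bayesian fits on raw codes).
#' @slot scaleFactor scalar multiplier on the centered genotype columns.
#' @slot diagnostics list (sampler traces, REML log-likelihood, ...).
#'
#' @aliases MarkerEffectModel-class
#' @exportClass MarkerEffectModel
setClass("MarkerEffectModel", contains = "GsModel",
  representation(effects = "numeric", center = "numeric",
                 scaleFactor = "numeric", diagnostics = "list"))

#' Kernel model: prediction via retained training genotypes and a kernel
#'
#' Covers GBLUP (genomic relationship matrix) and RKHS (Gaussian kernel).
#' Prediction for new samples is `intercept + K_cross %*% alpha` with the
#' cross-kernel computed against the retained training genotypes.
#'
#' @slot alpha training-sample coefficients, `(K + lambda I)^{-1} (y - mu)`.
#' @slot trainValues training genotype matrix retained for cross-kernels.
#' @slot kind "GRM" or "GAUSSIAN".
#' @slot k GRM scale constant `1 / (2 * sum p_j (1 - p_j))` (GRM only).
#' @slot centerFreq per-marker allele-frequency centering `2 p_j - 1` (GRM only).
#' @slot bandwidth Gaussian kernel bandwidth (RKHS only).
#' @slot d2Scale mean squared distance used to scale RKHS distances.
#' @slot lambda REML variance ratio `varE / varU`.
#' @slot diagnostics list.
#'
#' @aliases KernelModel-class
#' @exportClass KernelModel
setClass("KernelModel", contains = "GsModel",
  representation(alpha = "numeric", trainValues = "matrix", kind = "character",
                 k = "numeric", centerFreq = "numeric", bandwidth = "numeric",
                 d2Scale = "numeric", lambda = "numeric",
                 diagnostics = "list"),
  prototype(k = NA_real_, bandwidth = NA_real_, d2Scale = NA_real_))

setValidity("GsModel", function(object) {
  msg <- character()
  if (length(object@varE) == 1L && !is.na(object@varE) && object@varE < 0)
    msg <- c(msg, "varE must be nonnegative")
  if (length(object@varU) == 1L && !is.na(object@varU) && object@varU < 0)
    msg <- c(msg, "varU must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Single-hidden-layer perceptron meta-model
#'
#' @slot W1,b1 input-to-hidden weights and biases.
#' @slot W2,b2 hidden-to-output weights and bias.
#' @slot lossCurve per-epoch full-data training MSE.
#' @slot config the MetaConfig-style list used for training.
#'
#' @aliases MetaModel-class
#' @exportClass MetaModel
setClass("MetaModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 lossCurve = "numeric", config = "list"))

setValidity("MetaModel", function(object) {
  msg <- character()
  if (ncol(object@W1) != nrow(object@W2))
    msg <- c(msg, "hidden-layer dimensions of W1 and W2 disagree")
  if (ncol(object@W2) != 1L) msg <- c(msg, "output layer must have one node")
  if (length(object@b1) != ncol(object@W1))
    msg <- c(msg, "b1 length must match hidden width")
  if (length(msg)) msg else TRUE
})

#' Result of the three-step stacking procedure
#'
#' @slot metaTrainFeatures n x s out-of-fold base-model predictions.
#' @slot metaTrainTargets training phenotypes (length n).
#' @slot metaTestFeatures m x s test predictions from the refit base models.
#' @slot metaModel the trained MetaModel.
#' @slot finalPredictions meta-model output on the test features (length m).
#' @slot baseTestPredictions alias of metaTestFeatures retained for the
#'   comparators.
#' @slot fitCount number of base fits in the cross-validation stage (k * s).
#' @slot fitLog data.frame with one row per base fit (model, fold, seed).
#' @slot refitModels list of base models refit on the full training set.
#'
#' @aliases StackingResult-class
#' @exportClass StackingResult
setClass("StackingResult",
  representation(metaTrainFeatures = "matrix", metaTrainTargets = "numeric",
                 metaTestFeatures = "matrix", metaModel = "MetaModel",
                 finalPredictions = "numeric", baseTestPredictions = "matrix",
                 fitCount = "integer", fitLog = "data.frame",
                 refitModels = "list"))

setValidity("StackingResult", function(object) {
  msg <- character()
  if (nrow(object@metaTrainFeatures) != length(object@metaTrainTargets))
    msg <- c(msg, "meta training features and targets disagree in length")
  if (ncol(object@metaTrainFeatures) != ncol(object@metaTestFeatures))
    msg <- c(msg, "train and test feature matrices have different model counts")
  if (length(object@finalPredictions) != nrow(object@metaTestFeatures))
    msg <- c(msg, "one final prediction per test sample is required")
  if (length(msg)) msg else TRUE
})

#' Non-inferiority test report for one stack-vs-base comparison
#'
#' @slot baseModel name of the comparator model.
#' @slot delta non-inferiority margin (> 0).
#' @slot alpha type-I error level.
#' @slot powerTarget target power used in the margin.
#' @slot statistic signed-rank sum T = sum sign(X_i) R_i.
#' @slot pValue p-value of the location-shifted signed-rank test.
#' @slot ciLower,ciUpper Hodges-Lehmann confidence bounds on the error
#'   difference (base minus stack).
#' @slot outcome "SUPERIOR", "EQUIVALENT" or "INFERIOR".
#' @slot nPairs number of non-zero paired differences used.
#'
#' @aliases NonInferiorityReport-class
#' @exportClass NonInferiorityReport
setClass("NonInferiorityReport",
  representation(baseModel = "character", delta = "numeric", alpha = "numeric",
                 powerTarget = "numeric", statistic = "numeric",
                 pValue = "numeric", ciLower = "numeric", ciUpper = "numeric",
                 outcome = "character", nPairs = "integer"))

setValidity("NonInferiorityReport", function(object) {
  msg <- character()
  if (object@delta <= 0) msg <- c(msg, "delta must be positive")
  if (object@ciLower > object@ciUpper) msg <- c(msg, "ciLower exceeds ciUpper")
  if (!object@outcome %in% c("SUPERIOR", "EQUIVALENT", "INFERIOR"))
    msg <- c(msg, "unknown outcome label")
  if (length(msg)) msg else TRUE
})
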