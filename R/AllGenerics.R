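#' @rdname GenotypeMatrix-class
#' @param values integer-like matrix, samples x markers, with dimnames.
#' @param coding input coding; `"ZERO_1_2"` dosages are shifted to the
#'   canonical -1/0/1 coding.
#' @return a validated [GenotypeMatrix-class] object.
#' @export
#' @examples
#' m <- matrix(c(-1L, 1L, 0L, 1L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("m1", "m2")))
#' genotypeMatrix(m)
genotypeMatrix <- function(values, coding = c("MINUS1_0_1", "ZERO_1_2")) {
  coding <- match.arg(coding)
  v <- as.matrix(values)
  storage.mode(v) <- "integer"
  if (coding == "ZERO_1_2") v <- v - 1L
  new("GenotypeMatrix", values = v, coding = "MINUS1_0_1")
}

#' @rdname TraitVector-class
#' @param values numeric vector named by sample id.
#' @param traitName name of the trait.
#' @param standardized,center,scale standardization state and statistics.
#' @return a [TraitVector-class] object.
#' @export
traitVector <- function(values, traitName = "trait", standardized = FALSE,
                        center = 0, scale = 1) {
  v <- as.numeric(values)
  names(v) <- names(values)
  new("TraitVector", values = v, traitName = traitName,
      standardized = standardized, center = center, scale = scale)
}

#' Accessors for GenotypeMatrix and TraitVector
#'
#' `genotypes` returns the integer sample x marker matrix, `sampleIds` and
#' `markerIds` its dimnames, `nSamples`/`nMarkers` its dimensions, and
#' `traitValues` the named phenotype vector.
#'
#' @param x a [GenotypeMatrix-class] or [TraitVector-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setMethod("genotypes", "GenotypeMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("sampleIds", "TraitVector", function(x) names(x@values))

#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("nSamples", "TraitVector", function(x) length(x@values))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname accessors
#' @export
setMethod("nMarkers", "GenotypeMatrix", function(x) ncol(x@values))

#' @rdname accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))
#' @rdname accessors
#' @export
setMethod("traitValues", "TraitVector", function(x) x@values)

#' Subset a GenotypeMatrix by samples and/or markers
#'
#' @param x a GenotypeMatrix.
#' @param i,j sample and marker indices (integer, logical or character).
#' @param ... ignored.
#' @param drop ignored; the result is always a GenotypeMatrix.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("GenotypeMatrix", values = v, coding = "MINUS1_0_1")
})

#' Subset a TraitVector by samples
#'
#' @param x a TraitVector.
#' @param i sample indices.
#' @param ... ignored.
#' @export
setMethod("[", "TraitVector", function(x, i, ...) {
  new("TraitVector", values = x@values[i], traitName = x@traitName,
      standardized = x@standardized, center = x@center, scale = x@scale)
})

#' Accessors for stacking and evaluation results
#'
#' @param x a [StackingResult-class] or [NonInferiorityReport-class].
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
setGeneric("finalPredictions", function(x) standardGeneric("finalPredictions"))
#' @rdname result-accessors
#' @export
setMethod("finalPredictions", "StackingResult", function(x) x@finalPredictions)

#' @rdname result-accessors
#' @export
setGeneric("fitCount", function(x) standardGeneric("fitCount"))
#' @rdname result-accessors
#' @export
setMethod("fitCount", "StackingResult", function(x) x@fitCount)

#' @rdname result-accessors
#' @export
setGeneric("metaTrainFeatures", function(x) standardGeneric("metaTrainFeatures"))
#' @rdname result-accessors
#' @export
setMethod("metaTrainFeatures", "StackingResult", function(x) x@metaTrainFeatures)

#' @rdname result-accessors
#' @export
setGeneric("metaTestFeatures", function(x) standardGeneric("metaTestFeatures"))
#' @rdname result-accessors
#' @export
setMethod("metaTestFeatures", "StackingResult", function(x) x@metaTestFeatures)

#' @rdname result-accessors
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))
#' @rdname result-accessors
#' @export
setMethod("outcome", "NonInferiorityReport", function(x) x@outcome)

#' @rdname result-accessors
#' @export
setGeneric("markerEffects", function(x) standardGeneric("markerEffects"))
#' @rdname result-accessors
#' @export
setMethod("markerEffects", "MarkerEffectModel", function(x) x@effects)

setMethod("show", "GenotypeMatrix", function(object) {
  v <- object@values
  cat(sprintf("GenotypeMatrix: %d samples x %d markers (coding -1/0/1)\n",
              nrow(v), ncol(v)))
  nmiss <- sum(is.na(v))
  if (nmiss) cat(sprintf("  %d missing entries\n", nmiss))
})

setMethod("show", "TraitVector", function(object) {
  cat(sprintf("TraitVector '%s': %d samples%s\n", object@traitName,
              length(object@values),
              if (object@standardized) " (standardized)" else ""))
})

setMethod("show", "GsModel", function(object) {
  cat(sprintf("%s fit: intercept %.4g, varU %.4g, varE %.4g\n",
              object@modelName, object@intercept, object@varU, object@varE))
})

setMethod("show", "StackingResult", function(object) {
  cat(sprintf(paste0("StackingResult: %d training samples x %d base models, ",
                     "%d test predictions (%d CV fits)\n"),
              nrow(object@metaTrainFeatures), ncol(object@metaTrainFeatures),
              length(object@finalPredictions), object@fitCount))
})

setMethod("show", "NonInferiorityReport", function(object) {
  cat(sprintf(paste0("Non-inferiority vs %s: %s (T = %.1f, p = %.3g, ",
                     "CI [%.3g, %.3g], margin %.3g)\n"),
              object@baseModel, object@outcome, object@statistic,
              object@pValue, object@ciLower, object@ciUpper, object@delta))
})

setMethod("show", "MetaModel", function(object) {
  cat(sprintf("MetaModel: %d -> %d -> 1 perceptron, final training MSE %.4g\n",
              nrow(object@W1), ncol(object@W1),
              utils::tail(object@lossCurve, 1L)))
})
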