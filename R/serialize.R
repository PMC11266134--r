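#' Save and load fitted models as JSON
#'
#' Serializes [MarkerEffectModel-class], [KernelModel-class] and
#' [MetaModel-class] objects to a single JSON document (scalars, hyper
#' settings and numeric arrays together) and restores them with full
#' double precision, so `predict` on a reloaded model reproduces the
#' original predictions.
#'
#' @param model a fitted model.
#' @param path output / input file path.
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   restored model object.
#' @export
saveModel <- function(model, path) {
  obj <- if (is(model, "MarkerEffectModel")) {
    list(class = "MarkerEffectModel", modelName = model@modelName,
         intercept = model@intercept, varE = model@varE, varU = model@varU,
         effects = as.list(model@effects), center = model@center,
         scaleFactor = model@scaleFactor)
  } else if (is(model, "KernelModel")) {
    list(class = "KernelModel", modelName = model@modelName,
         intercept = model@intercept, varE = model@varE, varU = model@varU,
         alpha = model@alpha, kind = model@kind, k = model@k,
         centerFreq = model@centerFreq, bandwidth = model@bandwidth,
         d2Scale = model@d2Scale, lambda = model@lambda,
         trainValues = model@trainValues,
         trainDimnames = dimnames(model@trainValues))
  } else if (is(model, "MetaModel")) {
    list(class = "MetaModel", W1 = model@W1, b1 = model@b1, W2 = model@W2,
         b2 = model@b2, lossCurve = model@lossCurve, config = model@config)
  } else stop("unsupported model class: ", class(model))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              na = "null"), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  switch(o$class,
    MarkerEffectModel = new("MarkerEffectModel", modelName = o$modelName,
      intercept = o$intercept, varE = o$varE, varU = o$varU,
      effects = unlist(o$effects), center = o$center,
      scaleFactor = o$scaleFactor, diagnostics = list()),
    KernelModel = {
      tv <- as.matrix(o$trainValues)
      dimnames(tv) <- o$trainDimnames
      new("KernelModel", modelName = o$modelName, intercept = o$intercept,
          varE = o$varE, varU = o$varU, alpha = o$alpha, kind = o$kind,
          k = if (is.null(o$k)) NA_real_ else o$k,
          centerFreq = as.numeric(unlist(o$centerFreq)),
          bandwidth = if (is.null(o$bandwidth)) NA_real_ else o$bandwidth,
          d2Scale = if (is.null(o$d2Scale)) NA_real_ else o$d2Scale,
          lambda = o$lambda, trainValues = tv, diagnostics = list())
    },
    MetaModel = new("MetaModel", W1 = as.matrix(o$W1), b1 = o$b1,
                    W2 = as.matrix(o$W2), b2 = o$b2,
                    lossCurve = o$lossCurve, config = as.list(o$config)),
    stop("unknown serialized class: ", o$class))
}
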