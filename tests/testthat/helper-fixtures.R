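# Shared fixtures: all data are generated in code under fixed seeds.

randomGenotypes <- function(n, p, seed = 1L, freqs = c(0.45, 0.36, 0.19)) {
  set.seed(seed)
  v <- matrix(sample(c(-1L, 0L, 1L), n * p, replace = TRUE, prob = freqs),
              n, p, dimnames = list(sprintf("s%03d", seq_len(n)),
                                    sprintf("m%03d", seq_len(p))))
  genotypeMatrix(v)
}

linearTrait <- function(G, h2 = 0.5, seed = 1L, effectSd = 0.3) {
  set.seed(seed)
  Z <- matrix(as.numeric(genotypes(G)), nSamples(G), nMarkers(G))
  beta <- rnorm(ncol(Z), 0, effectSd)
  g <- drop(Z %*% beta)
  e <- rnorm(nrow(Z), 0, sqrt(max(var(g), 1e-8) * (1 - h2) / h2))
  list(trait = traitVector(stats::setNames(g + e, sampleIds(G))),
       beta = beta, g = g)
}

# Deterministic stub base model: predicts the training mean everywhere.
# Used to count fits and exercise stacking plumbing without model cost.
meanStubSpec <- function(label = "stub") {
  baseModelSpec("rrblup", label = label, fitFun = function(G, y, seed) {
    structure(list(mu = mean(y)), class = "meanStub")
  })
}

predict.meanStub <- function(object, newdata, ...) {
  stats::setNames(rep(object$mu, nSamples(newdata)), sampleIds(newdata))
}
registerS3method("predict", "meanStub", predict.meanStub,
                 envir = asNamespace("stats"))

# Stub predicting a fixed offset from the mean (for averaging identities).
offsetStubSpec <- function(offset, label = paste0("off", offset)) {
  baseModelSpec("rrblup", label = label, fitFun = function(G, y, seed) {
    structure(list(mu = mean(y), off = offset), class = "offsetStub")
  })
}
predict.offsetStub <- function(object, newdata, ...) {
  stats::setNames(rep(object$mu + object$off, nSamples(newdata)),
                  sampleIds(newdata))
}
registerS3method("predict", "offsetStub", predict.offsetStub,
                 envir = asNamespace("stats"))

# Oracle base model that knows the true marker effects (a "perfect" model
# up to the irreducible noise).
oracleSpec <- function(beta, label = "oracle") {
  baseModelSpec("rrblup", label = label, fitFun = function(G, y, seed) {
    structure(list(beta = beta,
                   mu = mean(y) - mean(matrix(as.numeric(genotypes(G)),
                                              nSamples(G)) %*% beta)),
              class = "oracleModel")
  })
}
predict.oracleModel <- function(object, newdata, ...) {
  Z <- matrix(as.numeric(genotypes(newdata)), nSamples(newdata))
  stats::setNames(drop(object$mu + Z %*% object$beta), sampleIds(newdata))
}
registerS3method("predict", "oracleModel", predict.oracleModel,
                 envir = asNamespace("stats"))

# Exhaustive signed-rank null: exact P(T >= t_obs) over all 2^n sign patterns
# of the observed absolute-value ranks (assumes no zeros / no ties).
enumSignedRankP <- function(x, alternative = "greater") {
  n <- length(x)
  r <- rank(abs(x))
  tObs <- sum(sign(x) * r)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tAll <- as.vector(signs %*% r)
  switch(alternative,
         greater = mean(tAll >= tObs),
         less = mean(tAll <= tObs),
         two.sided = min(1, 2 * min(mean(tAll >= tObs), mean(tAll <= tObs))))
}

writeTempVcf <- function(records, samples = c("A", "B", "C")) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
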