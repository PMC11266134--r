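#' Simulation configuration for synthetic genotype/phenotype data
#'
#' Genotype-class frequency profiles mirror the three regimes seen in real
#' marker panels: `TWO_HOMOZYGOUS` (two homozygote classes dominate, rice/
#' barley-like), `HOM_HET` (recessive homozygote plus heterozygote, maize-like)
#' and `THREE_CLASS` (all three classes substantial, mouse-like).
#'
#' @param nSamples,nMarkers dimensions of the simulated panel.
#' @param genotypeProfile one of `"TWO_HOMOZYGOUS"`, `"HOM_HET"`,
#'   `"THREE_CLASS"`, or a numeric vector of three class frequencies
#'   (aa, Aa, AA) summing to 1.
#' @param effectPrior marker-effect prior: `"GAUSSIAN"`, `"T"`, `"LAPLACE"` or
#'   `"POINT_MASS_MIXTURE"`.
#' @param priorParams list of prior parameters: `sd` (Gaussian and the mixture
#'   slab), `df` (t, must exceed 2), `rate` (Laplace), `pi` (mixture
#'   non-null probability).
#' @param h2 narrow-sense heritability, strictly inside (0, 1).
#' @param dominanceCoeff displacement of the heterozygote genetic value off
#'   the additive line, in units of the homozygote contrast; 0 gives a purely
#'   additive trait.
#' @param seed integer RNG seed.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(nSamples = 200L, nMarkers = 500L,
                      genotypeProfile = "THREE_CLASS",
                      effectPrior = c("GAUSSIAN", "T", "LAPLACE",
                                      "POINT_MASS_MIXTURE"),
                      priorParams = list(), h2 = 0.5, dominanceCoeff = 0,
                      seed = 1L) {
  effectPrior <- match.arg(effectPrior)
  if (is.character(genotypeProfile)) {
    genotypeProfile <- match.arg(genotypeProfile,
                                 c("TWO_HOMOZYGOUS", "HOM_HET", "THREE_CLASS"))
    freqs <- switch(genotypeProfile,
                    TWO_HOMOZYGOUS = c(0.80, 0.01, 0.19),
                    HOM_HET = c(0.78, 0.20, 0.02),
                    THREE_CLASS = c(0.45, 0.36, 0.19))
  } else {
    freqs <- as.numeric(genotypeProfile)
    if (length(freqs) != 3L || any(freqs < 0))
      stop("explicit genotype frequencies must be three nonnegative values")
    if (abs(sum(freqs) - 1) > 1e-8)
      stop("genotype-class frequencies must sum to 1")
  }
  if (!(h2 > 0 && h2 < 1)) stop("h2 must lie strictly inside (0, 1)")
  pp <- utils::modifyList(list(sd = 0.1, df = 5, rate = 10, pi = 0.5),
                          priorParams)
  if (effectPrior == "T" && pp$df <= 2)
    stop("t prior requires df > 2 for a finite variance")
  if (effectPrior == "POINT_MASS_MIXTURE" && (pp$pi < 0 || pp$pi > 1))
    stop("mixture pi must lie in [0, 1]")
  structure(list(nSamples = as.integer(nSamples),
                 nMarkers = as.integer(nMarkers),
                 classFreqs = freqs, effectPrior = effectPrior,
                 priorParams = pp, h2 = h2,
                 dominanceCoeff = dominanceCoeff, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a genotype matrix
#'
#' Each entry is an i.i.d. draw of a genotype class (-1, 0, 1) from the
#' configured class frequencies; markers carry no linkage disequilibrium,
#' which is what the marker-wise linear base models assume.
#'
#' @param cfg a [simConfig] object.
#' @return a [GenotypeMatrix-class], reproducible under `cfg$seed`.
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (any(cfg$classFreqs >= 1 - 1e-12))
    warning("a genotype class has frequency 1: all markers will be monomorphic")
  set.seed(cfg$seed)
  n <- cfg$nSamples; p <- cfg$nMarkers
  v <- matrix(sample(c(-1L, 0L, 1L), n * p, replace = TRUE,
                     prob = cfg$classFreqs), n, p)
  dimnames(v) <- list(sprintf("s%04d", seq_len(n)), sprintf("m%05d", seq_len(p)))
  genotypeMatrix(v)
}

#' Simulate marker effects from a prior
#'
#' Draws `nMarkers` i.i.d. effects from the configured prior family - the
#' same families the Bayesian alphabet models assume (Gaussian, scaled-t,
#' Laplace, point-mass mixture).
#'
#' @param cfg a [simConfig] object.
#' @return numeric vector of length `cfg$nMarkers`.
#' @export
simulateEffects <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 1L)
  p <- cfg$nMarkers; pp <- cfg$priorParams
  switch(cfg$effectPrior,
    GAUSSIAN = stats::rnorm(p, 0, pp$sd),
    T = stats::rt(p, df = pp$df) * pp$sd,
    LAPLACE = {
      # difference of exponentials ~ Laplace(rate)
      stats::rexp(p, pp$rate) - stats::rexp(p, pp$rate)
    },
    POINT_MASS_MIXTURE = {
      nonzero <- stats::runif(p) < pp$pi
      ifelse(nonzero, stats::rnorm(p, 0, pp$sd), 0)
    })
}

#' Simulate a phenotype from genotypes and marker effects
#'
#' The genetic value is `g_i = sum_j f(Z_ij) beta_j` where `f` is the identity
#' for an additive trait; with `dominanceCoeff != 0` the heterozygote code 0 is
#' mapped to `dominanceCoeff`, displacing the heterozygote class mean off the
#' additive line. Gaussian noise is added with variance
#' `Var(g) * (1 - h2) / h2`, computed from the realized genetic variance so the
#' target heritability holds per dataset.
#'
#' @param G a GenotypeMatrix.
#' @param beta marker-effect vector of length `nMarkers(G)`.
#' @param cfg a [simConfig] object (supplies `h2`, `dominanceCoeff`, `seed`).
#' @return a list with `trait` (a TraitVector), `geneticValues`, and
#'   `realizedH2` (Var(g) / Var(y)).
#' @export
simulatePhenotype <- function(G, beta, cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  Z <- genotypes(G)
  if (ncol(Z) != length(beta)) stop("beta length must equal the marker count")
  Zf <- matrix(as.numeric(Z), nrow(Z), ncol(Z), dimnames = dimnames(Z))
  if (cfg$dominanceCoeff != 0) Zf[Z == 0L] <- cfg$dominanceCoeff
  g <- drop(Zf %*% beta)
  vg <- stats::var(g)
  if (!is.finite(vg) || vg < 1e-12)
    stop("zero genetic variance: cannot scale noise to the target heritability")
  set.seed(cfg$seed + 2L)
  e <- stats::rnorm(nrow(Z), 0, sqrt(vg * (1 - cfg$h2) / cfg$h2))
  y <- g + e
  names(y) <- rownames(Z)
  list(trait = traitVector(y, traitName = "sim"),
       geneticValues = stats::setNames(g, rownames(Z)),
       realizedH2 = vg / stats::var(y))
}

#' Simulate a complete genotype/phenotype dataset
#'
#' Convenience wrapper chaining [simulateGenotypes], [simulateEffects] and
#' [simulatePhenotype].
#'
#' @param cfg a [simConfig] object.
#' @return list with `genotypes`, `trait`, `effects`, `geneticValues`,
#'   `realizedH2`.
#' @export
simulateDataset <- function(cfg) {
  G <- simulateGenotypes(cfg)
  beta <- simulateEffects(cfg)
  ph <- simulatePhenotype(G, beta, cfg)
  list(genotypes = G, trait = ph$trait, effects = beta,
       geneticValues = ph$geneticValues, realizedH2 = ph$realizedH2)
}
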