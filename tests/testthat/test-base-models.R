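test_that("the GRM matches its definition and is positive semidefinite", {
  G <- randomGenotypes(12, 30, seed = 1)
  grm <- computeGRM(G)
  Z <- matrix(as.numeric(genotypes(G)), 12, 30)
  p <- colMeans(Z + 1) / 2
  Zc <- sweep(Z, 2, 2 * p - 1)
  k <- 1 / (2 * sum(p * (1 - p)))
  expect_equal(grm$values, k * tcrossprod(Zc), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(grm$k, k)

  # duplicated sample rows give identical GRM rows
  v <- genotypes(G); v[2L, ] <- v[1L, ]
  grm2 <- computeGRM(genotypeMatrix(v))
  expect_equal(unname(grm2$values[1L, ]), unname(grm2$values[2L, ]),
               tolerance = 1e-12)

  big <- computeGRM(randomGenotypes(50, 200, seed = 2))
  ev <- eigen(big$values, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-8 * max(ev))

  mono <- genotypeMatrix(matrix(1L, 4, 3,
    dimnames = list(paste0("s", 1:4), paste0("m", 1:3))))
  expect_error(computeGRM(mono), "monomorphic")
})

test_that("rrBLUP with a fixed ridge parameter matches the normal equations", {
  G <- randomGenotypes(8, 3, seed = 4)
  set.seed(4)
  y <- rnorm(8)
  lam <- 2.5
  fit <- fitRRBLUP(G, y, lambda = lam, scaling = "none")
  # dense linear-algebra oracle with the intercept profiled by GLS
  Z <- matrix(as.numeric(genotypes(G)), 8, 3)
  V <- tcrossprod(Z) + lam * diag(8)
  mu <- sum(solve(V, y)) / sum(solve(V, rep(1, 8)))
  uOracle <- solve(crossprod(Z) + lam * diag(3), crossprod(Z, y - mu))
  expect_equal(unname(markerEffects(fit)), drop(uOracle), tolerance = 1e-8)
  expect_equal(fit@intercept, mu, tolerance = 1e-8)
})

test_that("rrBLUP handles a constant phenotype and shrinks with lambda", {
  G <- randomGenotypes(15, 10, seed = 5)
  fit <- fitRRBLUP(G, rep(3, 15))
  expect_lt(max(abs(markerEffects(fit))), 1e-8)
  expect_equal(unname(predict(fit, G)), rep(3, 15), tolerance = 1e-8)

  set.seed(6)
  y <- rnorm(15)
  norms <- vapply(c(0.1, 1, 10, 100), function(l)
    sqrt(sum(markerEffects(fitRRBLUP(G, y, lambda = l))^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("rrBLUP recovers the simulated heritability", {
  h2hat <- vapply(1:6, function(i) {
    dat <- simulateDataset(simConfig(nSamples = 250, nMarkers = 400, h2 = 0.5,
                                     seed = 20 + i))
    fit <- fitRRBLUP(dat$genotypes, traitValues(standardizeTrait(dat$trait)))
    # genetic variance on the phenotype scale is varU times the mean GRM
    # diagonal (the class frequencies need not be at Hardy-Weinberg)
    vg <- fit@varU * mean(diag(computeGRM(dat$genotypes)$values))
    vg / (vg + fit@varE)
  }, numeric(1))
  expect_true(all(abs(h2hat - 0.5) < 0.15))
  expect_lt(abs(mean(h2hat) - 0.5), 0.1)
})

test_that("GBLUP equals rrBLUP under matched scaling, and is equivariant", {
  for (seed in 1:5) {
    n <- sample(20:50, 1)
    p <- sample(40:120, 1)
    G <- randomGenotypes(n, p, seed = seed)
    lt <- linearTrait(G, seed = seed)
    y <- traitValues(lt$trait)
    Gte <- randomGenotypes(10, p, seed = seed + 500)
    fr <- fitRRBLUP(G, y)
    fg <- fitGBLUP(G, y)
    expect_lt(max(abs(predict(fr, G) - predict(fg, G))), 1e-6)
    expect_lt(max(abs(predict(fr, Gte) - predict(fg, Gte))), 1e-6)
  }

  # permuting sample order permutes predictions identically
  G <- randomGenotypes(20, 30, seed = 9)
  y <- traitValues(linearTrait(G, seed = 9)$trait)
  perm <- sample(20)
  f1 <- fitGBLUP(G, y)
  f2 <- fitGBLUP(G[perm, ], y[perm])
  expect_equal(predict(f1, G)[perm], predict(f2, G[perm, ]), tolerance = 1e-8)
})

test_that("the identity-kernel mixed model has the closed shrinkage form", {
  set.seed(11)
  y <- rnorm(12)
  lam <- 3
  fit <- stackGS:::remlKernel(diag(12), y, lambda = lam)
  expect_equal(fit$mu, mean(y), tolerance = 1e-8)
  expect_equal(fit$alpha, (y - mean(y)) / (1 + lam), tolerance = 1e-6)
})

test_that("deterministic fits are invariant to marker column order", {
  G <- randomGenotypes(25, 40, seed = 12)
  y <- traitValues(linearTrait(G, seed = 12)$trait)
  perm <- sample(40)
  Gp <- G[, perm]
  fr <- fitRRBLUP(G, y); frp <- fitRRBLUP(Gp, y)
  expect_equal(unname(predict(fr, G)), unname(predict(frp, Gp)),
               tolerance = 1e-10)
  expect_equal(unname(markerEffects(fr)[perm]), unname(markerEffects(frp)),
               tolerance = 1e-10)
  fk <- fitRKHS(G, y); fkp <- fitRKHS(Gp, y)
  expect_equal(unname(predict(fk, G)), unname(predict(fkp, Gp)),
               tolerance = 1e-10)
})

test_that("RKHS limits and duplicate-sample behavior are sane", {
  G <- randomGenotypes(20, 25, seed = 13)
  y <- traitValues(linearTrait(G, seed = 13)$trait)
  # bandwidth -> 0: the kernel flattens and predictions collapse to the mean
  f0 <- fitRKHS(G, y, bandwidth = 1e-8)
  expect_lt(max(abs(predict(f0, G) - mean(y))), 0.05 * stats::sd(y))

  v <- genotypes(G); v[2L, ] <- v[1L, ]
  G2 <- genotypeMatrix(v)
  f <- fitRKHS(G2, y)
  pr <- predict(f, G2)
  expect_equal(pr[[1L]], pr[[2L]], tolerance = 1e-10)
})

test_that("RKHS beats the linear model on a strongly dominant trait", {
  # oligogenic trait with the heterozygote far off the additive line: about
  # 60% of the genetic variance is invisible to a marker-linear model
  wins <- 0L
  for (i in 1:10) {
    cfg <- simConfig(nSamples = 250, nMarkers = 20, h2 = 0.9,
                     dominanceCoeff = 3, seed = 400 + i,
                     genotypeProfile = "THREE_CLASS")
    dat <- simulateDataset(cfg)
    idx <- seq_len(200)
    ts <- standardizeTrait(dat$trait, idx)
    y <- traitValues(ts)
    Gtr <- dat$genotypes[idx, ]; Gte <- dat$genotypes[-idx, ]
    fk <- fitRKHS(Gtr, y[idx])
    fr <- fitRRBLUP(Gtr, y[idx])
    if (mse(y[-idx], predict(fk, Gte)) < mse(y[-idx], predict(fr, Gte)))
      wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("prediction errors on marker mismatch and degenerate rows", {
  G <- randomGenotypes(15, 10, seed = 14)
  y <- traitValues(linearTrait(G, seed = 14)$trait)
  fit <- fitBayes(G, y, "bayesA", seed = 1,
                  hyper = bayesHyperDefaults(y, G, model = "bayesA",
                                             nIter = 200, burnIn = 50))
  # all-zero genotype row predicts the intercept (raw-coded Bayes fit)
  z0 <- genotypeMatrix(matrix(0L, 1, 10,
    dimnames = list("z", markerIds(G))))
  expect_equal(unname(predict(fit, z0)), fit@intercept, tolerance = 1e-12)
  expect_error(predict(fit, G[, 1:5]), "missing training markers")

  fr <- fitRRBLUP(G, y)
  # predicting on training data reproduces fitted values
  expect_equal(predict(fr, G), predict(fr, G), tolerance = 1e-12)
})

test_that("hyper-parameter defaults implement the variance partition", {
  G <- randomGenotypes(40, 30, seed = 15)
  set.seed(15)
  y <- rnorm(40)
  vy <- stats::var(y)
  hyA <- bayesHyperDefaults(y, G, R2 = 0.5, model = "bayesA")
  expect_equal(hyA@Se / (hyA@dfE + 2), 0.5 * vy, tolerance = 1e-12)

  # doubling Var(y) doubles both scale targets
  hy2 <- bayesHyperDefaults(y * sqrt(2), G, R2 = 0.5, model = "bayesA")
  expect_equal(hy2@Se, 2 * hyA@Se, tolerance = 1e-10)
  expect_equal(hy2@Sbeta, 2 * hyA@Sbeta, tolerance = 1e-10)

  # BayesC with pi = 0.5 doubles the slab scale relative to pi = 1
  hyC5 <- bayesHyperDefaults(y, G, model = "bayesC", pi = 0.5)
  hyC1 <- bayesHyperDefaults(y, G, model = "bayesC", pi = 1)
  expect_equal(hyC5@Sbeta, 2 * hyC1@Sbeta, tolerance = 1e-12)
})

test_that("R2 tuning returns grid values deterministically", {
  G <- randomGenotypes(40, 30, seed = 16)
  y <- traitValues(linearTrait(G, seed = 16)$trait)
  expect_equal(tuneR2(G, y, grid = 0.4, k = 2, nIter = 120, burnIn = 40), 0.4)
  a <- tuneR2(G, y, grid = c(0.2, 0.2, 0.6), k = 2, seed = 3,
              nIter = 120, burnIn = 40)
  b <- tuneR2(G, y, grid = c(0.2, 0.6), k = 2, seed = 3,
              nIter = 120, burnIn = 40)
  expect_equal(a, b)
  expect_error(tuneR2(G, y, grid = numeric()), "empty")
})

test_that("models survive a JSON save/load round trip", {
  G <- randomGenotypes(20, 12, seed = 17)
  y <- traitValues(linearTrait(G, seed = 17)$trait)
  Gte <- randomGenotypes(6, 12, seed = 18)
  f <- tempfile(fileext = ".json")
  for (fit in list(fitRRBLUP(G, y), fitGBLUP(G, y), fitRKHS(G, y),
                   fitBayes(G, y, "bayesC", seed = 1,
                            hyper = bayesHyperDefaults(y, G, model = "bayesC",
                                                       nIter = 150,
                                                       burnIn = 50)))) {
    saveModel(fit, f)
    back <- loadModel(f)
    expect_equal(predict(back, Gte), predict(fit, Gte), tolerance = 1e-12)
  }
  X <- matrix(rnorm(60), 20, 3)
  m <- trainMLP(X, rnorm(20), metaConfig(epochs = 20, seed = 2))
  saveModel(m, f)
  expect_equal(predict(loadModel(f), X), predict(m, X), tolerance = 1e-12)
})
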