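test_that("fold assignment partitions training samples near-equally", {
  f <- makeFolds(6, 3, seed = 1)
  expect_equal(as.vector(sort(table(f$foldOf))), c(2L, 2L, 2L))
  f2 <- makeFolds(7, 3, seed = 1)
  expect_equal(as.vector(sort(table(f2$foldOf), decreasing = TRUE)),
               c(3L, 2L, 2L))
  expect_identical(makeFolds(20, 5, seed = 9)$foldOf,
                   makeFolds(20, 5, seed = 9)$foldOf)
  expect_error(makeFolds(3, 5), "exceed")
  expect_error(makeFolds(10, 1), "at least 2")
})

test_that("out-of-fold features match a leave-one-out refit oracle", {
  n <- 10
  G <- randomGenotypes(n, 3, seed = 41)
  y <- traitValues(linearTrait(G, seed = 41, h2 = 0.9)$trait)
  spec <- baseModelSpec("rrblup", lambda = 1)
  folds <- makeFolds(n, n, seed = 2)          # leave-one-out
  oof <- buildMetaTraining(G, y, list(spec), folds, seed = 3)
  for (i in seq_len(n)) {
    f <- folds$foldOf[i]
    tr <- folds$foldOf != f
    fit <- fitRRBLUP(G[tr, ], y[tr], lambda = 1)
    expect_equal(unname(oof$features[i, 1L]),
                 unname(predict(fit, G[i, ])), tolerance = 1e-10)
  }
})

test_that("the k=3 toy produces one out-of-fold prediction per sample", {
  G <- randomGenotypes(6, 3, seed = 42)
  y <- traitValues(linearTrait(G, seed = 42)$trait)
  specs <- list(meanStubSpec("a"), meanStubSpec("b"),
                baseModelSpec("rrblup"), baseModelSpec("rrblup", label = "rr2"))
  folds <- makeFolds(6, 3, seed = 5)
  oof <- buildMetaTraining(G, y, specs, folds, seed = 6)
  expect_equal(dim(oof$features), c(6L, 4L))
  expect_false(anyNA(oof$features))
  expect_equal(nrow(oof$fitLog), 12L)          # k * s fits

  # duplicate deterministic specs give identical feature columns
  expect_equal(oof$features[, "a"], oof$features[, "b"])

  # the out-of-fold property: the fit used for sample i never saw fold(i)
  expect_true(all(oof$fitLog$trainN == 4L))
})

test_that("meta-test features come from full-training refits", {
  G <- randomGenotypes(12, 5, seed = 43)
  y <- traitValues(linearTrait(G, seed = 43)$trait)
  Gte <- randomGenotypes(3, 5, seed = 44)
  specs <- list(baseModelSpec("rrblup"), baseModelSpec("gblup"))
  mt <- buildMetaTest(G, y, Gte, specs, seed = 7)
  expect_equal(dim(mt$features), c(3L, 2L))
  # with G_test = G_train the features equal the refit fitted values
  mt2 <- buildMetaTest(G, y, G, specs, seed = 7)
  expect_equal(mt2$features[, 1L], predict(mt2$models$rrblup, G),
               tolerance = 1e-10)
  # removing a spec removes exactly one column
  mt3 <- buildMetaTest(G, y, Gte, specs[1L], seed = 7)
  expect_equal(ncol(mt3$features), 1L)
})

test_that("the CV stage performs exactly k x s base fits", {
  G <- randomGenotypes(20, 4, seed = 45)
  y <- traitValues(linearTrait(G, seed = 45)$trait)
  Gte <- randomGenotypes(5, 4, seed = 46)
  for (s in c(1L, 3L, 6L)) {
    for (k in c(2L, 5L)) {
      specs <- lapply(seq_len(s), function(i) meanStubSpec(paste0("stub", i)))
      res <- runStacking(G, y, Gte, specs, k = k,
                         metaCfg = metaConfig(epochs = 5), seed = 1)
      expect_identical(fitCount(res), k * s)
    }
  }
})

test_that("stacking is deterministic and leaks no test information", {
  G <- randomGenotypes(24, 30, seed = 47)
  y <- traitValues(linearTrait(G, seed = 47)$trait)
  Gte <- randomGenotypes(6, 30, seed = 48)
  specs <- list(baseModelSpec("rrblup"),
                baseModelSpec("bayesC", nIter = 150, burnIn = 50))
  r1 <- runStacking(G, y, Gte, specs, k = 4,
                    metaCfg = metaConfig(epochs = 50), seed = 3)
  r2 <- runStacking(G, y, Gte, specs, k = 4,
                    metaCfg = metaConfig(epochs = 50), seed = 3)
  expect_identical(finalPredictions(r1), finalPredictions(r2))

  # replacing the test genotypes must not change the meta training inputs
  GteOther <- randomGenotypes(6, 30, seed = 49)
  r3 <- runStacking(G, y, GteOther, specs, k = 4,
                    metaCfg = metaConfig(epochs = 50), seed = 3)
  expect_identical(metaTrainFeatures(r1), metaTrainFeatures(r3))
})

test_that("stacking does not ruin an already-perfect base model", {
  ok <- 0L
  for (i in 1:10) {
    G <- randomGenotypes(120, 60, seed = 600 + i)
    lt <- linearTrait(G, h2 = 0.5, seed = 600 + i)
    y <- traitValues(lt$trait)
    Gte <- randomGenotypes(40, 60, seed = 700 + i)
    set.seed(800 + i)
    Zte <- matrix(as.numeric(genotypes(Gte)), 40, 60)
    gte <- drop(Zte %*% lt$beta)
    yte <- gte + rnorm(40, 0, sqrt(max(var(lt$g), 1e-8)))
    specs <- list(oracleSpec(lt$beta), baseModelSpec("rrblup"))
    res <- runStacking(G, y, Gte, specs, k = 5, seed = i)
    mseStack <- mse(yte, finalPredictions(res))
    mseOracle <- mse(yte, res@metaTestFeatures[, "oracle"])
    if (mseStack <= 1.5 * mseOracle) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("bagging reduces to averaging identities", {
  G <- randomGenotypes(15, 8, seed = 50)
  y <- traitValues(linearTrait(G, seed = 50)$trait)
  Gte <- randomGenotypes(4, 8, seed = 51)
  # identical deterministic models without bootstrap: any single model
  specs <- list(meanStubSpec("a"), meanStubSpec("b"), meanStubSpec("c"))
  pr <- runBagging(G, y, Gte, specs, bootstrap = FALSE, seed = 1)
  expect_equal(unname(pr), rep(mean(y), 4))
  # +a and -a around the mean average to the mean
  specs2 <- list(offsetStubSpec(0.6), offsetStubSpec(-0.6))
  pr2 <- runBagging(G, y, Gte, specs2, bootstrap = FALSE, seed = 1)
  expect_equal(unname(pr2), rep(mean(y), 4))
  # bootstrap reproducibility
  specs3 <- list(baseModelSpec("rrblup"), baseModelSpec("gblup"))
  b1 <- runBagging(G, y, Gte, specs3, bootstrap = TRUE, seed = 5)
  b2 <- runBagging(G, y, Gte, specs3, bootstrap = TRUE, seed = 5)
  expect_identical(b1, b2)
})
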