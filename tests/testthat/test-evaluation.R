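test_that("PCA handles perfectly correlated and orthonormal reconstruction", {
  set.seed(51)
  base <- rnorm(30)
  x <- cbind(a = base, b = 2 * base + 5, c = rnorm(30))
  m <- fitPca(x)
  expect_equal(sum(m@varianceExplained), 1, tolerance = 1e-12)
  ## two perfectly correlated features + 1 independent: PC1 of the (a,b)
  ## sub-model explains everything
  m2 <- fitPca(x[, 1:2])
  expect_equal(m2@varianceExplained[1], 1, tolerance = 1e-12)

  z <- scale(x)
  scores <- pcaScores(m, x)
  back <- scores %*% t(m@loadings)
  expect_equal(unname(back), unname(z[, 1:3]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(crossprod(m@loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  ## deterministic sign: dominant loading entry positive
  expect_true(all(apply(m@loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("uncorrelated standardized features spread variance evenly", {
  set.seed(52)
  x <- matrix(rnorm(500 * 8), 500, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  m <- fitPca(x)
  expect_true(all(abs(m@varianceExplained - 1 / 8) < 0.04))
})

test_that("constant features are dropped with a message", {
  set.seed(53)
  x <- cbind(f1 = rnorm(20), f2 = rep(1, 20), f3 = rnorm(20))
  expect_message(m <- fitPca(x), "constant")
  expect_identical(m@dropped, "f2")
  expect_equal(ncol(m@loadings), 2)
  expect_error(fitPca(x[1, , drop = FALSE]), "at least 2")
})

test_that("separable features give perfect CV performance with zero-width CI", {
  set.seed(54)
  n <- 40L
  y <- rep(c("benign", "malignant"), each = 20)
  x <- cbind(sep = ifelse(y == "malignant", 10, 0) + rnorm(n),
             noise = rnorm(n))
  ft <- FeatureTable(x, y, "CUSTOM")
  r <- cvEvaluate(ft, rounds = 5, folds = 10, seed = 1)
  expect_equal(r@metrics["accuracy", "mean"], 100)
  expect_equal(r@metrics["accuracy", "ci_lower"], 100)
  expect_equal(r@metrics["sensitivity", "mean"], 100)
  ## per-round confusion counts respect the class sizes
  expect_equal(unname(r@confusion["TP"] + r@confusion["FN"]), 20)
  expect_equal(unname(r@confusion["TN"] + r@confusion["FP"]), 20)
})

test_that("label-permuted features give chance-level CV performance", {
  set.seed(55)
  ft <- nullFeatureTable(n = 60, p = 8, seed = 55)
  r <- cvEvaluate(ft, rounds = 12, folds = 10, seed = 2)
  ci <- r@metrics["accuracy", ]
  expect_lte(ci$ci_lower, 60)
  expect_gte(ci$ci_upper, 40)
})

test_that("CV reports are seed-deterministic and serialize to JSON", {
  ft <- nullFeatureTable(n = 40, p = 5, seed = 56)
  a <- cvEvaluate(ft, rounds = 4, folds = 5, seed = 11)
  b <- cvEvaluate(ft, rounds = 4, folds = 5, seed = 11)
  expect_identical(a@metrics, b@metrics)
  expect_identical(a@roundMetrics, b@roundMetrics)

  path <- tempfile(fileext = ".json")
  writePerformanceReport(a, path)
  back <- readPerformanceReport(path)
  expect_equal(back@metrics, a@metrics, tolerance = 1e-12)
  expect_equal(back@confusion, a@confusion, tolerance = 1e-12)
  expect_identical(back@nRounds, a@nRounds)
})

test_that("full-rank PC scores and raw features give identical predictions", {
  set.seed(57)
  dirc <- tempfile()
  generateCohort(cohortConfig(nLesions = 30L, nBenign = 15L,
                              nMalignant = 15L, seed = 57L), dirc)
  ft <- extractFeatures(loadCohort(file.path(dirc, "manifest.csv")),
                        sets = "STAT")$STAT
  ## a linear SVM is invariant to an orthonormal change of basis, so the
  ## sweep at k = rank reproduces the raw-feature fold metrics
  folds <- 5L; rounds <- 3L
  rank <- 22L
  sw <- pcSweep(ft, maxPcs = rank, rounds = rounds, folds = folds,
                seed = 5)
  raw <- cvEvaluate(ft, rounds = rounds, folds = folds, seed = 5)
  kmax <- length(sw)
  expect_equal(sw[[kmax]]@roundMetrics, raw@roundMetrics,
               tolerance = 1e-6)
})

test_that("PC sweep of a correlated set plateaus and nulls stay at chance", {
  set.seed(58)
  n <- 60L
  y <- rep(c("benign", "malignant"), each = 30)
  latent <- ifelse(y == "malignant", 1.6, 0) + rnorm(n)
  x <- sapply(1:12, function(j) latent + rnorm(n, sd = 0.7))
  colnames(x) <- paste0("f", 1:12)
  ft <- FeatureTable(x, y, "CUSTOM")
  sw <- pcSweep(ft, maxPcs = 12, rounds = 4, folds = 6, seed = 3)
  acc <- attr(sw, "accuracy")
  expect_gte(max(acc[1:min(10, length(acc))]), max(acc) - 2)

  ftn <- nullFeatureTable(n = 60, p = 12, seed = 58)
  swn <- pcSweep(ftn, maxPcs = 5, rounds = 6, folds = 6, seed = 3)
  for (k in seq_along(swn)) {
    ci <- swn[[k]]@metrics["accuracy", ]
    expect_lte(ci$ci_lower - 15, 50)
    expect_gte(ci$ci_upper + 15, 50)
  }
})

test_that("models never see test-fold labels", {
  set.seed(59)
  ft <- nullFeatureTable(n = 40, p = 6, seed = 59)
  x <- featureValues(ft)
  y <- lesionLabels(ft)
  fold <- CESMRadiomics:::.stratifiedFolds(y, 5L, seed = 4L)
  tr <- fold != 1
  pp <- CESMRadiomics:::.standardizePreprocess(x[tr, ], x[!tr, ])
  fit1 <- CESMRadiomics:::.svmFit(pp$train, y[tr])
  yCorrupt <- y
  yCorrupt[!tr] <- rev(yCorrupt[!tr])    # corrupt test-fold labels only
  fit2 <- CESMRadiomics:::.svmFit(pp$train, yCorrupt[tr])
  expect_identical(fit1$coefs, fit2$coefs)
  expect_identical(fit1$rho, fit2$rho)
  expect_identical(predict(fit1, pp$test), predict(fit2, pp$test))
})
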