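test_that("WMW filter keeps separating features, drops constants", {
  set.seed(41)
  n <- 40L
  y <- rep(c("benign", "malignant"), each = 20)
  x <- cbind(sep = ifelse(y == "malignant", 1, 0) + rnorm(n, sd = 1e-6),
             const = rep(3, n),
             noise = rnorm(n))
  ft <- FeatureTable(x, y, "CUSTOM")
  kept <- wmwFilter(ft)
  p <- attr(kept, "p")
  expect_true("sep" %in% kept)
  expect_lt(p[["sep"]], 1e-6)          # complete separation at n = 20/20
  expect_false("const" %in% kept)
  expect_equal(p[["const"]], 1)
})

test_that("WMW filter has nominal type-I error on null features", {
  set.seed(42)
  ft <- nullFeatureTable(n = 50L, p = 1000L, seed = 42)
  kept <- wmwFilter(ft)
  frac <- length(kept) / 1000
  ## 99.7% binomial band around alpha = 0.05 at 1000 features
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("internal Gaussian naive Bayes agrees with e1071", {
  set.seed(43)
  n <- 60L
  y <- factor(rep(c("benign", "malignant"), each = 30),
              levels = c("benign", "malignant"))
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  x[y == "malignant", 1] <- x[y == "malignant", 1] + 1.5
  tr <- c(1:20, 31:50); te <- setdiff(seq_len(n), tr)
  cache <- CESMRadiomics:::.nbLogDensities(x[tr, ], droplevels(y[tr]),
                                           x[te, ])
  pred <- CESMRadiomics:::.nbPredictFromCache(
    list(ll = cache$ll, logPrior = cache$logPrior), 1:5)
  ref <- predict(e1071::naiveBayes(x[tr, ], y[tr]), x[te, ])
  expect_equal(levels(y)[pred], as.character(ref))
})

test_that("backward selection keeps a dominant feature across seeds", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 40L
    y <- rep(c("benign", "malignant"), each = 20)
    x <- cbind(matrix(rnorm(n * 9), n, 9,
                      dimnames = list(NULL, paste0("noise", 1:9))),
               signal = ifelse(y == "malignant", 2, 0) + rnorm(n, sd = 0.5))
    ft <- FeatureTable(x, y, "CUSTOM")
    sel <- sbsNaiveBayes(ft, innerSeed = s)
    if ("signal" %in% sel) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("jointly informative XOR-like features are both retained", {
  set.seed(44)
  n <- 80L
  a <- rep(c(0, 0, 1, 1), n / 4) + rnorm(n, sd = 0.15)
  b <- rep(c(0, 1, 0, 1), n / 4) + rnorm(n, sd = 0.15)
  y <- ifelse(round(rep(c(0, 0, 1, 1), n / 4)) ==
              round(rep(c(0, 1, 0, 1), n / 4)), "benign", "malignant")
  ft <- FeatureTable(cbind(a = a, b = b), y, "CUSTOM")
  sel <- sbsNaiveBayes(ft, innerSeed = 1)
  expect_setequal(sel, c("a", "b"))

  single <- FeatureTable(cbind(only = rnorm(40)),
                         rep(c("benign", "malignant"), 20), "CUSTOM")
  expect_identical(as.character(sbsNaiveBayes(single)), "only")
})

test_that("SBS error trajectory is non-increasing and output is nested", {
  set.seed(45)
  dirc <- tempfile()
  generateCohort(cohortConfig(nLesions = 30L, nBenign = 15L,
                              nMalignant = 15L, seed = 45L), dirc)
  ft <- extractFeatures(loadCohort(file.path(dirc, "manifest.csv")),
                        sets = "STAT")$STAT
  kept <- wmwFilter(ft)
  sel <- wrapperSelect(ft)
  expect_true(all(sel %in% kept))
  expect_true(all(kept %in% featureNames(ft)))
  sbs <- sbsNaiveBayes(subsetFeatures(ft, kept))
  err <- attr(sbs, "errors")
  expect_true(all(diff(err) <= 0))
})

test_that("embedded selection recovers a strong feature and splits noise", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 60L
    y <- rep(c("benign", "malignant"), each = 30)
    x <- cbind(matrix(rnorm(n * 20), n, 20,
                      dimnames = list(NULL, paste0("noise", 1:20))),
               strong = ifelse(y == "malignant", 2, 0) + rnorm(n))
    ft <- FeatureTable(x, y, "CUSTOM")
    sel <- rfEmbeddedSelect(ft, nTrees = 300L, seed = s)
    if ("strong" %in% sel) hits <- hits + 1L
  }
  expect_gte(hits, 19)

  nullSel <- rfEmbeddedSelect(nullFeatureTable(n = 60, p = 40, seed = 9),
                              nTrees = 300L, seed = 1)
  expect_gt(length(nullSel), 5)        # above-mean rule keeps roughly half
  expect_lt(length(nullSel), 35)
})

test_that("Fisher enrichment p-values match the hypergeometric tail oracle", {
  set.seed(46)
  for (rep in 1:200) {
    n <- sample(20:100, 1)
    a <- sample(0:n, 1); b <- sample(0:n, 1)
    p <- CESMRadiomics:::.fisherEnrichment(a, b, n)
    expect_equal(p, oracleFisherGreater(a, n, b, n), tolerance = 1e-12,
                 info = sprintf("a=%d b=%d n=%d", a, b, n))
  }
  ## identical margins are never significant for enrichment
  expect_gte(CESMRadiomics:::.fisherEnrichment(30, 30, 100), 0.5)
  ## strong enrichment is
  expect_lt(CESMRadiomics:::.fisherEnrichment(90, 5, 100), 1e-10)
})

test_that("permutation significance flags planted signal, is deterministic", {
  set.seed(47)
  n <- 50L
  y <- rep(c("benign", "malignant"), each = 25)
  x <- cbind(matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, paste0("noise", 1:6))),
             planted = ifelse(y == "malignant", 2.5, 0) + rnorm(n))
  ft <- FeatureTable(x, y, "CUSTOM")
  res <- permutationSignificance(ft, "embedded", nRounds = 20L, seed = 3L,
                                 nTrees = 150L)
  tb <- selectionTable(res)
  expect_true(tb["planted", "significant"])
  expect_gte(tb["planted", "count_true"], 19)
  expect_true(validObject(res))

  res2 <- permutationSignificance(ft, "embedded", nRounds = 20L, seed = 3L,
                                  nTrees = 150L)
  expect_identical(as.data.frame(selectionTable(res2)),
                   as.data.frame(tb))
  expect_error(permutationSignificance(ft, "embedded", nRounds = 5L),
               "at least 20")
})
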