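test_that("a default cohort loads as 55 validated pairs", {
  dir <- tempfile()
  generateCohort(cohortConfig(seed = 8L), dir)
  pairs <- loadCohort(file.path(dir, "manifest.csv"))
  expect_length(pairs, 55)
  expect_true(all(vapply(pairs, function(p)
    identical(dim(leImage(p)), dim(rcImage(p))), logical(1))))
  expect_true(all(vapply(pairs, function(p) p@record$bits_le == 16L,
                         logical(1))))
})

test_that("missing images and shape mismatches are reported per lesion", {
  dir <- tempfile()
  mf <- generateCohort(cohortConfig(nLesions = 4L, nBenign = 2L,
                                    nMalignant = 2L, seed = 2L), dir)
  unlink(mf$rc_path[3])
  expect_error(loadCohort(file.path(dir, "manifest.csv")), "L003")

  dir2 <- tempfile()
  mf2 <- generateCohort(cohortConfig(nLesions = 2L, nBenign = 1L,
                                     nMalignant = 1L, seed = 2L), dir2)
  bad <- matrix(runif(20 * 24), 20)
  tiff::writeTIFF(bad, mf2$rc_path[1], bits.per.sample = 16L)
  err <- tryCatch(loadCohort(file.path(dir2, "manifest.csv")),
                  error = conditionMessage)
  expect_match(err, "L001")
  expect_match(err, "20x24")
})

test_that("8-bit PNG and 16-bit TIFF mix in one cohort with recorded depth", {
  dir <- tempfile(); dir.create(dir)
  set.seed(12)
  img8 <- matrix(sample(0:255, 32 * 32, replace = TRUE) / 255, 32)
  png::writePNG(img8, file.path(dir, "a_le.png"))
  png::writePNG(img8, file.path(dir, "a_rc.png"))
  img16 <- matrix(sample.int(65536L, 32 * 32, replace = TRUE) - 1L, 32)
  tiff::writeTIFF(img16 / 65535, file.path(dir, "b_le.tiff"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(img16 / 65535, file.path(dir, "b_rc.tiff"),
                  bits.per.sample = 16L)
  manifest <- data.frame(
    lesion_id = c("A", "B"), patient_id = c("P1", "P2"),
    view = "CC", label = c("benign", "malignant"), bpe_level = 1L,
    le_path = c("a_le.png", "b_le.tiff"),
    rc_path = c("a_rc.png", "b_rc.tiff"))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  pairs <- loadCohort(file.path(dir, "manifest.csv"))
  expect_equal(vapply(pairs, function(p) p@record$bits_le, integer(1)),
               c(8L, 16L))
  ## loading preserves native gray levels exactly
  expect_equal(unname(leImage(pairs[[1]])[1:4, 1]),
               round(img8[1:4, 1] * 255))
  expect_equal(unname(leImage(pairs[[2]])[1:4, 1]),
               as.numeric(img16[1:4, 1]))
})

test_that("feature tables round-trip through CSV at full precision", {
  set.seed(13)
  v <- matrix(rnorm(60) * 10^sample(-8:8, 60, replace = TRUE), 10, 6,
              dimnames = list(sprintf("L%02d", 1:10),
                              sprintf("GLCM_LE_HL_d0_s%d", 1:6)))
  ft <- FeatureTable(v, rep(c("benign", "malignant"), 5), "GLCM")
  path <- tempfile(fileext = ".csv")
  writeFeatureTable(ft, path)
  back <- readFeatureTable(path)
  expect_identical(featureNames(back), featureNames(ft))
  expect_identical(as.character(lesionLabels(back)),
                   as.character(lesionLabels(ft)))
  expect_equal(featureValues(back), featureValues(ft), tolerance = 1e-14)
  expect_identical(setId(back), "GLCM")
})

test_that("degenerate and malformed feature tables are handled", {
  expect_error(FeatureTable(matrix(1:4, 2, 2,
                                   dimnames = list(NULL, c("a", "a"))),
                            c("benign", "malignant"), "X"),
               "duplicate")
  empty <- FeatureTable(matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("a", "b"))),
                        character(0), "CUSTOM")
  path <- tempfile(fileext = ".csv")
  writeFeatureTable(empty, path)
  back <- readFeatureTable(path)
  expect_equal(ncol(featureValues(back)), 2)
  expect_equal(nrow(featureValues(back)), 0)

  lines <- readLines(path)
  writeLines(c(lines, "L01,benign,1.0"), path)   # too few fields
  expect_error(readFeatureTable(path), "line 3")
})

test_that("extraction assembles the four tables with fixed arities", {
  dir <- tempfile()
  generateCohort(cohortConfig(nLesions = 4L, nBenign = 2L,
                              nMalignant = 2L, seed = 7L), dir)
  pairs <- loadCohort(file.path(dir, "manifest.csv"))
  tabs <- extractFeatures(pairs)
  expect_named(tabs, c("STAT", "GRAD", "HAAR", "GLCM"))
  expect_equal(vapply(tabs, nrow, integer(1)),
               c(STAT = 22L, GRAD = 24L, HAAR = 96L, GLCM = 312L))
  expect_true(all(vapply(tabs, function(t)
    all(is.finite(featureValues(t))), logical(1))))
})
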