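test_that("first-order statistics match the hand-computed 2x2 case", {
  s <- statFeatures(matrix(c(0, 0, 0, 255), 2))
  expect_equal(s[["mean"]], 63.75)
  expect_equal(s[["variance"]], 12192.1875)
  expect_equal(s[["sd"]], sqrt(12192.1875))
  expect_equal(s[["min"]], 0)
  expect_equal(s[["max"]], 255)
  expect_equal(s[["range"]], 255)
})

test_that("moment statistics agree with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:10) {
    img <- matrix(runif(256, 0, 4096), 16)
    s <- statFeatures(img)
    o <- oracleMoments(img)
    expect_equal(s[["mean"]], o$mean, tolerance = 1e-10)
    expect_equal(s[["variance"]], o$variance, tolerance = 1e-10)
    expect_equal(s[["skewness"]], o$skewness, tolerance = 1e-10)
    expect_equal(s[["kurtosis"]], o$kurtosis, tolerance = 1e-10)
    expect_equal(s[["sd_over_mean"]], sqrt(o$variance) / o$mean,
                 tolerance = 1e-10)
  }
})

test_that("constant and zero-mean degenerate conventions hold", {
  s <- statFeatures(matrix(7, 5, 5))
  expect_equal(s[["mean"]], 7)
  expect_equal(unname(s[c("sd", "variance", "entropy",
                          "relative_smoothness", "skewness", "kurtosis",
                          "range", "sd_over_mean")]), rep(0, 8))
  z <- statFeatures(matrix(c(-1, 1, -1, 1), 2))
  expect_equal(z[["mean"]], 0)
  expect_equal(z[["sd_over_mean"]], 0)   # zero-mean convention
})

test_that("central statistics are shift-invariant, extremes shift", {
  set.seed(5)
  img <- matrix(rnorm(64), 8)
  a <- statFeatures(img); b <- statFeatures(img + 17)
  for (k in c("variance", "skewness", "kurtosis", "entropy",
              "relative_smoothness", "range", "sd"))
    expect_equal(a[[k]], b[[k]], tolerance = 1e-10, info = k)
  expect_equal(b[["mean"]], a[["mean"]] + 17)
  expect_equal(b[["min"]], a[["min"]] + 17)
})

test_that("histogram entropy is bounded by log2 of the level count", {
  set.seed(6)
  for (rep in 1:5) {
    img <- matrix(sample.int(32L, 100, replace = TRUE), 10)
    e <- statFeatures(img)[["entropy"]]
    expect_gte(e, 0)
    expect_lte(e, log2(length(unique(as.vector(img)))) + 1e-12)
  }
  cont <- matrix(runif(100), 10)
  expect_lte(statFeatures(cont)[["entropy"]], 8)   # 256 uniform bins
})

test_that("relative smoothness lies in [0,1) and grows with spread", {
  narrow <- statFeatures(matrix(c(rep(0, 50), rep(1, 14)), 8))
  wide <- statFeatures(matrix(rep(c(0, 1), 32), 8))
  expect_gte(narrow[["relative_smoothness"]], 0)
  expect_lt(wide[["relative_smoothness"]], 1)
  expect_gt(wide[["relative_smoothness"]],
            narrow[["relative_smoothness"]])
})

test_that("Sobel gradient of flat, ramp and transposed images behaves", {
  flat <- sobelGradient(matrix(3, 6, 6))
  expect_true(all(flat$gmag == 0))
  expect_true(all(flat$gdir == 0))

  ramp <- matrix(rep(1:8, each = 8), 8)  # intensity = column index
  g <- sobelGradient(ramp)
  interior <- g$gmag[2:7, 2:7]
  expect_true(all(abs(interior - 8) < 1e-12))   # Sobel response to slope 1
  expect_true(all(g$gdir %in% c(0, pi, -pi)))

  set.seed(7)
  img <- matrix(rnorm(64), 8)
  a <- sobelGradient(img); b <- sobelGradient(t(img))
  expect_equal(b$gmag, t(a$gmag), tolerance = 1e-12)
  expect_equal(b$fx, t(a$fy), tolerance = 1e-12)
  expect_equal(b$fy, t(a$fx), tolerance = 1e-12)

  expect_error(sobelGradient(matrix(1, 2, 2)), "3x3")
})

test_that("gradient statistics match brute-force stats of the field", {
  set.seed(8)
  img <- matrix(runif(144, 0, 255), 12)
  g <- sobelGradient(img)
  f <- gradFeatures(img)
  om <- oracleMoments(g$gmag); od <- oracleMoments(g$gdir)
  expect_equal(f[["mag_mean"]], om$mean, tolerance = 1e-10)
  expect_equal(f[["mag_variance"]], om$variance, tolerance = 1e-10)
  expect_equal(f[["dir_kurtosis"]], od$kurtosis, tolerance = 1e-10)
  expect_length(f, 12)

  ramp <- matrix(rep(1:10, each = 10), 10)
  fr <- gradFeatures(ramp)
  expect_equal(fr[["dir_variance"]], oracleMoments(sobelGradient(ramp)$gdir)$variance,
               tolerance = 1e-12)
})

test_that("STAT and GRAD pair vectors have fixed arity, order and symmetry", {
  pair <- makeTestPair()
  s <- statSet(pair); g <- gradSet(pair)
  expect_length(s, 22); expect_length(g, 24)
  expect_false(anyDuplicated(names(s)) > 0)
  expect_true(all(startsWith(names(s)[1:11], "STAT_LE_")))
  expect_true(all(startsWith(names(g)[13:24], "GRAD_RC_")))

  same <- RoiPair(leImage(pair), leImage(pair))
  ss <- statSet(same)
  expect_equal(unname(ss[1:11]), unname(ss[12:22]))

  doubled <- RoiPair(leImage(pair), 2 * leImage(pair))
  sd2 <- statSet(doubled)
  for (k in c("mean", "sd", "min", "max", "range"))
    expect_equal(sd2[[paste0("STAT_RC_", k)]],
                 2 * sd2[[paste0("STAT_LE_", k)]], tolerance = 1e-12)
  for (k in c("skewness", "kurtosis"))
    expect_equal(sd2[[paste0("STAT_RC_", k)]],
                 sd2[[paste0("STAT_LE_", k)]], tolerance = 1e-12)
})
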