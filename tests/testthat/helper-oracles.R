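# Independent brute-force oracles used to freeze expected values.  Every
# oracle is a direct transcription of the defining formula (explicit loops,
# no shared code with the implementation).

# population central moments by explicit loop
oracleMoments <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  m <- sum(x) / n
  ctr <- function(k) { s <- 0; for (v in x) s <- s + (v - m)^k; s / n }
  v <- ctr(2)
  list(mean = m, variance = v,
       skewness = if (v > 0) ctr(3) / v^1.5 else 0,
       kurtosis = if (v > 0) ctr(4) / v^2 else 0)
}

# single-level Haar by explicit 2x2 block transform (even-sized input)
oracleHaarStep <- function(m) {
  nr <- nrow(m) / 2; nc <- ncol(m) / 2
  LL <- HL <- LH <- HH <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    a <- m[2 * i - 1, 2 * j - 1]; b <- m[2 * i - 1, 2 * j]
    c_ <- m[2 * i, 2 * j - 1];    d <- m[2 * i, 2 * j]
    LL[i, j] <- (a + b + c_ + d) / 2
    HL[i, j] <- (a - b + c_ - d) / 2
    LH[i, j] <- (a + b - c_ - d) / 2
    HH[i, j] <- (a - b - c_ + d) / 2
  }
  list(LL = LL, HL = HL, LH = LH, HH = HH)
}

# GLCM by explicit pixel-pair enumeration
oracleGlcm <- function(image, direction, distance = 1L, nLevels = 16L) {
  rng <- range(image)
  q <- if (rng[1] == rng[2]) matrix(1L, nrow(image), ncol(image))
       else pmin(floor((image - rng[1]) / (rng[2] - rng[1]) * nLevels) + 1L,
                 nLevels)
  off <- switch(as.character(direction),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  counts <- matrix(0, nLevels, nLevels)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q)) {
      counts[q[i, j], q[i2, j2]] <- counts[q[i, j], q[i2, j2]] + 1
      counts[q[i2, j2], q[i, j]] <- counts[q[i2, j2], q[i, j]] + 1
    }
  }
  counts / sum(counts)
}

# the 13 GLCM statistics by explicit double loops over (i, j)
oracleGlcmStats <- function(p) {
  ng <- nrow(p)
  mux <- muy <- 0
  for (i in 1:ng) for (j in 1:ng) { mux <- mux + i * p[i, j]
                                    muy <- muy + j * p[i, j] }
  sx2 <- sy2 <- 0
  for (i in 1:ng) for (j in 1:ng) { sx2 <- sx2 + (i - mux)^2 * p[i, j]
                                    sy2 <- sy2 + (j - muy)^2 * p[i, j] }
  psum <- rep(0, 2 * ng); pdiff <- rep(0, ng)       # indices k and |k|+1
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  acc <- function(f) { s <- 0
    for (i in 1:ng) for (j in 1:ng) s <- s + f(i, j) * p[i, j]; s }
  ent <- function(q) { s <- 0
    for (v in q) if (v > 0) s <- s - v * log2(v); s }
  sumAvg <- sum((2:(2 * ng)) * psum[2:(2 * ng)])
  c(contrast = acc(function(i, j) (i - j)^2),
    correlation = if (sx2 > 0 && sy2 > 0)
      acc(function(i, j) (i - mux) * (j - muy)) / sqrt(sx2 * sy2) else 0,
    cluster_prominence = acc(function(i, j) (i + j - mux - muy)^4),
    cluster_shade = acc(function(i, j) (i + j - mux - muy)^3),
    dissimilarity = acc(function(i, j) abs(i - j)),
    energy = acc(function(i, j) p[i, j]),
    entropy = ent(as.vector(p)),
    homogeneity = acc(function(i, j) 1 / (1 + (i - j)^2)),
    sum_average = sumAvg,
    sum_variance = sum(((2:(2 * ng)) - sumAvg)^2 * psum[2:(2 * ng)]),
    sum_entropy = ent(psum),
    difference_entropy = ent(pdiff),
    nidm = acc(function(i, j) 1 / (1 + (i - j)^2 / ng^2)))
}

# one-sided (enrichment) Fisher exact p by exhaustive hypergeometric tail:
# P(X >= a) for X ~ Hypergeom(m = a+b successes, total n1+n2, draws n1)
oracleFisherGreater <- function(a, n1, b, n2) {
  k <- a + b
  support <- max(0, k - n2):min(k, n1)
  probs <- choose(n1, support) * choose(n2, k - support) /
    choose(n1 + n2, k)
  sum(probs[support >= a])
}

# small deterministic test pair
makeTestPair <- function(side = 32L, seed = 42L, rc = NULL) {
  set.seed(seed)
  le <- matrix(sample.int(4096L, side^2, replace = TRUE) - 1L, side)
  if (is.null(rc))
    rc <- matrix(sample.int(4096L, side^2, replace = TRUE) - 1L, side)
  RoiPair(le, rc)
}

# small synthetic cohort on disk; returns the manifest path
makeCohort <- function(n = 20L, nBenign = 10L, seed = 1L, dir = tempfile(),
                       ...) {
  cfg <- cohortConfig(nLesions = n, nBenign = nBenign,
                      nMalignant = n - nBenign, seed = seed, ...)
  generateCohort(cfg, dir)
  file.path(dir, "manifest.csv")
}

# pure-noise feature table with both classes
nullFeatureTable <- function(n = 40L, p = 10L, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
  FeatureTable(x, rep(c("benign", "malignant"), length.out = n), "CUSTOM")
}
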