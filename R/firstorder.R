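## First-order (STAT) and Sobel-gradient (GRAD) feature sets.
## Conventions fixed package-wide:
##  - population moments (denominator n);
##  - kurtosis non-excess (Gaussian -> 3);
##  - histogram entropy in bits: one bin per integer level for integer
##    images, 256 uniform bins over [min, max] otherwise;
##  - relative smoothness R = 1 - 1/(1 + var(x01)) with x01 the image
##    rescaled linearly to [0, 1];
##  - degenerate (constant / zero-mean) cases return 0 by convention.

.STAT_NAMES <- c("mean", "sd", "sd_over_mean", "variance", "skewness",
                 "entropy", "relative_smoothness", "kurtosis",
                 "min", "max", "range")
.SIX_STATS <- c("mean", "variance", "skewness", "entropy",
                "relative_smoothness", "kurtosis")

.histogramEntropy <- function(x) {
    if (length(x) < 2L) return(0)
    rng <- range(x)
    if (rng[1] == rng[2]) return(0)
    isInteger <- all(x == round(x))
    if (isInteger) {
        p <- tabulate(match(x, sort(unique(x))))
    } else {
        brk <- seq(rng[1], rng[2], length.out = 257L)
        p <- tabulate(findInterval(x, brk, rightmost.closed = TRUE),
                      nbins = 256L)
    }
    p <- p[p > 0] / length(x)
    -sum(p * log2(p))
}

.relativeSmoothness <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(0)
    x01 <- (x - rng[1]) / (rng[2] - rng[1])
    v <- mean((x01 - mean(x01))^2)
    1 - 1 / (1 + v)
}

## the six moment-type statistics shared by STAT/GRAD/HAAR sets
.sixStatistics <- function(x) {
    x <- as.numeric(x)
    m <- mean(x)
    v <- mean((x - m)^2)
    if (v > 0) {
        sk <- mean((x - m)^3) / v^1.5
        ku <- mean((x - m)^4) / v^2
    } else {
        sk <- 0; ku <- 0   # constant input: standardized moments undefined
    }
    c(mean = m, variance = v, skewness = sk,
      entropy = .histogramEntropy(x),
      relative_smoothness = .relativeSmoothness(x), kurtosis = ku)
}

#' First-order statistics of a gray-level image
#'
#' The 11 STAT descriptors of one channel: mean, standard deviation, their
#' ratio (coefficient of variation sd/mean), variance, skewness, histogram
#' entropy (bits), relative smoothness, kurtosis, minimum, maximum and
#' range.  Moments are population moments; kurtosis is non-excess.
#'
#' @param image numeric matrix (or vector) of finite gray levels, >= 2 px
#' @return named numeric(11)
#' @examples
#' statFeatures(matrix(c(0, 0, 0, 255), 2))[c("mean", "variance")]
#' @export
statFeatures <- function(image) {
    x <- as.numeric(image)
    if (length(x) < 2L) stop("image must have at least 2 pixels")
    if (!all(is.finite(x))) stop("image must be finite")
    six <- .sixStatistics(x)
    s <- sqrt(six[["variance"]])
    m <- six[["mean"]]
    c(mean = m, sd = s,
      sd_over_mean = if (m != 0) s / m else 0,
      variance = six[["variance"]], skewness = six[["skewness"]],
      entropy = six[["entropy"]],
      relative_smoothness = six[["relative_smoothness"]],
      kurtosis = six[["kurtosis"]],
      min = min(x), max = max(x), range = diff(range(x)))
}

.reflectPad1 <- function(m) {
    ## symmetric (edge-reflect) 1-px border for a 3x3 stencil
    m2 <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
    cbind(m2[, 1, drop = FALSE], m2, m2[, ncol(m2), drop = FALSE])
}

.convolve3 <- function(image, kernel) {
    p <- .reflectPad1(image)
    nr <- nrow(image); nc <- ncol(image)
    out <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
        w <- kernel[dr + 2, dc + 2]
        if (w != 0)
            out <- out + w * p[(2 + dr):(nr + 1 + dr),
                               (2 + dc):(nc + 1 + dc)]
    }
    out
}

.SOBEL_X <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3)  # d/dcol
.SOBEL_Y <- t(.SOBEL_X)                                  # d/drow

#' Sobel gradient field of an image
#'
#' Convolves with the standard 3x3 Sobel kernels (x = column direction,
#' y = row direction; symmetric edge reflection at the boundary) and returns
#' the derivative components together with the gradient magnitude
#' \eqn{\sqrt{f_x^2 + f_y^2}} and direction \eqn{\mathrm{atan2}(f_y, f_x)}.
#' Pixels where both derivatives vanish get direction 0.
#'
#' @param image numeric matrix, at least 3x3
#' @return list with matrices \code{fx}, \code{fy}, \code{gmag}, \code{gdir}
#' @export
sobelGradient <- function(image) {
    if (nrow(image) < 3L || ncol(image) < 3L)
        stop("image must be at least 3x3 for the Sobel kernel")
    fx <- .convolve3(image, .SOBEL_X)
    fy <- .convolve3(image, .SOBEL_Y)
    gmag <- sqrt(fx^2 + fy^2)
    gdir <- atan2(fy, fx)
    gdir[fx == 0 & fy == 0] <- 0
    list(fx = fx, fy = fy, gmag = gmag, gdir = gdir)
}

#' Gradient-based statistics of one channel
#'
#' The six moment-type statistics (mean, variance, skewness, entropy,
#' relative smoothness, kurtosis) of the Sobel gradient magnitude and of the
#' gradient direction, treated as plain real values on \eqn{[-\pi,\pi]}.
#'
#' @param image numeric matrix, at least 3x3
#' @return named numeric(12), names prefixed \code{mag_} / \code{dir_}
#' @export
gradFeatures <- function(image) {
    g <- sobelGradient(image)
    out <- c(.sixStatistics(g$gmag), .sixStatistics(g$gdir))
    names(out) <- c(paste0("mag_", .SIX_STATS), paste0("dir_", .SIX_STATS))
    out
}

.pairFeatures <- function(pair, fun, set) {
    le <- fun(leImage(pair))
    rc <- fun(rcImage(pair))
    out <- c(le, rc)
    names(out) <- c(sprintf("%s_LE_%s", set, names(le)),
                    sprintf("%s_RC_%s", set, names(rc)))
    out
}

#' STAT feature vector of a lesion (22 features)
#'
#' The 11 first-order statistics of the LE channel followed by those of the
#' RC channel, named \code{STAT_LE_mean} ... \code{STAT_RC_range}.
#'
#' @param pair a \linkS4class{RoiPair}
#' @return named numeric(22)
#' @export
statSet <- function(pair) .pairFeatures(pair, statFeatures, "STAT")

#' GRAD feature vector of a lesion (24 features)
#'
#' The 12 gradient statistics per channel, LE first,
#' named \code{GRAD_LE_mag_mean} ... \code{GRAD_RC_dir_kurtosis}.
#'
#' @param pair a \linkS4class{RoiPair}
#' @return named numeric(24)
#' @export
gradSet <- function(pair) .pairFeatures(pair, gradFeatures, "GRAD")
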