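## Gray-level co-occurrence matrices and Haralick-type statistics.
## Defaults: Ng = 16 equal-width quantization bins over the sub-image's own
## [min, max] (signed Haar detail values included), distance d = 1,
## symmetric accumulation, levels indexed 1..Ng for the statistics.

.GLCM_DIRECTIONS <- c(d0 = 0, d45 = 45, d90 = 90, d135 = 135)
.GLCM_STAT_NAMES <- c("contrast", "correlation", "cluster_prominence",
                      "cluster_shade", "dissimilarity", "energy", "entropy",
                      "homogeneity", "sum_average", "sum_variance",
                      "sum_entropy", "difference_entropy", "nidm")

## offsets in (row, col) image coordinates, origin top-left
.glcmOffset <- function(direction, distance) {
    switch(as.character(direction),
           "0"   = c(0L, distance),
           "45"  = c(-distance, distance),
           "90"  = c(-distance, 0L),
           "135" = c(-distance, -distance),
           stop("direction must be one of 0, 45, 90, 135 degrees"))
}

.quantizeLevels <- function(image, nLevels) {
    rng <- range(image)
    if (rng[1] == rng[2])
        return(matrix(1L, nrow(image), ncol(image)))
    q <- floor((image - rng[1]) / (rng[2] - rng[1]) * nLevels) + 1L
    q[q > nLevels] <- nLevels   # pixels at the exact maximum
    matrix(as.integer(q), nrow(image))
}

#' Gray-level co-occurrence matrix of an image
#'
#' Quantizes intensities into \code{nLevels} equal-width bins over the
#' image's own range (a constant image falls entirely into bin 1), counts
#' co-occurring level pairs at the given offset together with its opposite
#' (symmetric accumulation), and normalizes to sum 1.  Offsets in (row, col)
#' image coordinates with origin top-left: 0 deg = (0, +d),
#' 45 deg = (-d, +d), 90 deg = (-d, 0), 135 deg = (-d, -d).
#'
#' @param image numeric matrix
#' @param direction one of 0, 45, 90, 135 (degrees)
#' @param distance offset length in pixels (default 1)
#' @param nLevels number of quantization levels (default 16)
#' @return object of informal class \code{"Glcm"}: list with \code{p}
#'   (nLevels x nLevels symmetric matrix summing to 1), \code{nLevels},
#'   \code{direction}, \code{distance}
#' @examples
#' g <- computeGlcm(matrix(c(0, 0, 1, 1), 2), direction = 0, nLevels = 2)
#' g$p
#' @export
computeGlcm <- function(image, direction, distance = 1L, nLevels = 16L) {
    nLevels <- as.integer(nLevels)
    if (nLevels < 2L) stop("nLevels must be at least 2")
    off <- .glcmOffset(direction, as.integer(distance))
    q <- .quantizeLevels(image, nLevels)
    nr <- nrow(q); nc <- ncol(q)
    rows <- seq_len(nr); cols <- seq_len(nc)
    r1 <- rows[rows >= 1 - off[1] & rows <= nr - off[1]]
    c1 <- cols[cols >= 1 - off[2] & cols <= nc - off[2]]
    if (!length(r1) || !length(c1))
        stop(sprintf("no valid pixel pairs for offset (%d, %d) in a %dx%d image",
                     off[1], off[2], nr, nc))
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
    counts <- matrix(tabulate((a - 1L) * nLevels + b, nbins = nLevels^2),
                     nLevels, nLevels, byrow = TRUE)
    counts <- counts + t(counts)              # symmetric accumulation
    structure(list(p = counts / sum(counts), nLevels = nLevels,
                   direction = as.numeric(direction),
                   distance = as.integer(distance)),
              class = "Glcm")
}

#' Haralick-type statistics of a co-occurrence matrix
#'
#' The 13 descriptors of a normalized symmetric GLCM \eqn{p(i,j)} with
#' 1-based levels and margins \eqn{\mu_x,\mu_y,\sigma_x,\sigma_y},
#' \eqn{p_{x+y}}, \eqn{p_{x-y}}: contrast, correlation (0 when a margin is
#' degenerate), cluster prominence, cluster shade, dissimilarity, energy
#' (angular second moment), entropy (bits), homogeneity, sum average, sum
#' variance (centered on the sum average), sum entropy, difference entropy,
#' and the normalized inverse difference moment
#' \eqn{\sum p/(1+(i-j)^2/N_g^2)}.
#'
#' @param glcm a \code{"Glcm"} from \code{\link{computeGlcm}}, or a plain
#'   normalized symmetric matrix
#' @return named numeric(13)
#' @export
glcmStatistics <- function(glcm) {
    p <- if (inherits(glcm, "Glcm")) glcm$p else as.matrix(glcm)
    ng <- nrow(p)
    i <- matrix(seq_len(ng), ng, ng)          # row level index
    j <- t(i)
    px <- rowSums(p); py <- colSums(p)
    mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
    sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
    sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
    ## margins of i+j (2..2Ng) and |i-j| (0..Ng-1)
    psum  <- tapply(as.vector(p), as.vector(i + j), sum)
    pdiff <- tapply(as.vector(p), as.vector(abs(i - j)), sum)
    ksum  <- as.numeric(names(psum))
    ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
    sumAvg <- sum(ksum * psum)
    corr <- if (sx > 0 && sy > 0)
        sum((i - mux) * (j - muy) * p) / (sx * sy) else 0
    c(contrast            = sum((i - j)^2 * p),
      correlation         = corr,
      cluster_prominence  = sum((i + j - mux - muy)^4 * p),
      cluster_shade       = sum((i + j - mux - muy)^3 * p),
      dissimilarity       = sum(abs(i - j) * p),
      energy              = sum(p^2),
      entropy             = ent(p),
      homogeneity         = sum(p / (1 + (i - j)^2)),
      sum_average         = sumAvg,
      sum_variance        = sum((ksum - sumAvg)^2 * psum),
      sum_entropy         = ent(psum),
      difference_entropy  = ent(pdiff),
      nidm                = sum(p / (1 + (i - j)^2 / ng^2)))
}

#' GLCM feature vector of a lesion (312 features)
#'
#' For each channel, the level-1 Haar detail sub-images HL, LH and HH are
#' quantized and their co-occurrence matrices computed in the four
#' directions; the 13 Haralick-type statistics of each give
#' 3 x 4 x 13 = 156 features per channel (LE first), named
#' \code{GLCM_<CH>_<HL|LH|HH>_<d0|d45|d90|d135>_<statistic>}.
#'
#' @param pair a \linkS4class{RoiPair}
#' @param distance,nLevels co-occurrence parameters (defaults d = 1,
#'   Ng = 16)
#' @return named numeric(312)
#' @export
glcmSet <- function(pair, distance = 1L, nLevels = 16L) {
    bands <- c("HL1", "LH1", "HH1")
    channelFeatures <- function(img) {
        h <- haarDecompose(img, levels = 1)
        out <- numeric(0)
        for (b in bands) for (d in names(.GLCM_DIRECTIONS)) {
            g <- computeGlcm(h[[b]], .GLCM_DIRECTIONS[[d]],
                             distance = distance, nLevels = nLevels)
            s <- glcmStatistics(g)
            names(s) <- sprintf("%s_%s_%s", sub("1$", "", b), d, names(s))
            out <- c(out, s)
        }
        out
    }
    .pairFeatures(pair, channelFeatures, "GLCM")
}
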