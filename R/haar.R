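## Two-level separable orthonormal Haar analysis.
## Low/high analysis pair (1,1)/sqrt(2) and (1,-1)/sqrt(2); odd dimensions
## are made even by replicating the last row/column (recorded in `padding`),
## which avoids spurious high-frequency energy at the edge.

.haarPairs <- function(m, along = c("col", "row")) {
    along <- match.arg(along)
    if (along == "row") {
        res <- .haarPairs(t(m), "col")
        return(list(L = t(res$L), H = t(res$H)))
    }
    n <- ncol(m)
    odd <- seq(1, n, by = 2); even <- seq(2, n, by = 2)
    list(L = (m[, odd, drop = FALSE] + m[, even, drop = FALSE]) / sqrt(2),
         H = (m[, odd, drop = FALSE] - m[, even, drop = FALSE]) / sqrt(2))
}

.padEven <- function(m) {
    pad <- c(rows = nrow(m) %% 2L, cols = ncol(m) %% 2L)
    if (pad["rows"]) m <- rbind(m, m[nrow(m), , drop = FALSE])
    if (pad["cols"]) m <- cbind(m, m[, ncol(m), drop = FALSE])
    list(m = m, pad = pad)
}

.haarStep <- function(m) {
    p <- .padEven(m)
    cols <- .haarPairs(p$m, "col")
    rowsL <- .haarPairs(cols$L, "row")
    rowsH <- .haarPairs(cols$H, "row")
    ## LL: low/low, HL: column-direction (horizontal) detail,
    ## LH: row-direction (vertical) detail, HH: diagonal detail
    list(LL = rowsL$L, HL = rowsH$L, LH = rowsL$H, HH = rowsH$H,
         pad = p$pad)
}

.haarStepInverse <- function(LL, HL, LH, HH) {
    unpairRows <- function(L, H) {
        n <- 2L * nrow(L)
        out <- matrix(0, n, ncol(L))
        out[seq(1, n, 2), ] <- (L + H) / sqrt(2)
        out[seq(2, n, 2), ] <- (L - H) / sqrt(2)
        out
    }
    unpairCols <- function(L, H) t(unpairRows(t(L), t(H)))
    colL <- unpairRows(LL, LH)
    colH <- unpairRows(HL, HH)
    unpairCols(colL, colH)
}

.HAAR_BANDS <- c("LL1", "HL1", "LH1", "HH1", "LL2", "HL2", "LH2", "HH2")

#' Two-level 2-D Haar wavelet decomposition
#'
#' Separable orthonormal Haar analysis: level 1 splits the image into the
#' downscaled approximation LL1 and the horizontal/vertical/diagonal detail
#' bands HL1/LH1/HH1; level 2 repeats the split on LL1.  Odd dimensions are
#' edge-replicated to even size at each level (recorded in the result).
#' A constant image c yields zero detail bands, LL1 = 2c and LL2 = 4c (each
#' level scales a constant by sqrt(2) per direction).
#'
#' @param image numeric matrix, at least 8x8 so level-2 sub-images are >= 2x2
#' @param levels 1 or 2
#' @return list of sub-image matrices (\code{LL1}, \code{HL1}, \code{LH1},
#'   \code{HH1} and, for two levels, \code{LL2}, \code{HL2}, \code{LH2},
#'   \code{HH2}) plus \code{padding}, a list of per-level (rows, cols)
#'   replication counts
#' @examples
#' h <- haarDecompose(matrix(5, 8, 8))
#' h$LL2[1, 1]   # 4 * 5 = 20, details all zero
#' @export
haarDecompose <- function(image, levels = 2) {
    if (!levels %in% 1:2) stop("levels must be 1 or 2")
    minSide <- if (levels == 2) 8L else 2L
    if (nrow(image) < minSide || ncol(image) < minSide)
        stop(sprintf(
            "image must be at least %dx%d for a %d-level Haar decomposition",
            minSide, minSide, levels))
    s1 <- .haarStep(image)
    out <- list(LL1 = s1$LL, HL1 = s1$HL, LH1 = s1$LH, HH1 = s1$HH)
    padding <- list(level1 = s1$pad)
    if (levels == 2) {
        s2 <- .haarStep(s1$LL)
        out <- c(out, list(LL2 = s2$LL, HL2 = s2$HL, LH2 = s2$LH,
                           HH2 = s2$HH))
        padding$level2 <- s2$pad
    }
    out$padding <- padding
    out
}

#' Inverse of a one-level Haar split
#'
#' Reconstructs the (padded) parent image from its four sub-bands; used for
#' the perfect-reconstruction and energy-conservation checks.
#'
#' @param LL,HL,LH,HH sub-band matrices of identical dimensions
#' @return the reconstructed matrix (twice the sub-band size)
#' @export
haarReconstruct <- function(LL, HL, LH, HH) .haarStepInverse(LL, HL, LH, HH)

#' HAAR feature vector of a lesion (96 features)
#'
#' Six moment-type statistics (mean, variance, skewness, entropy, relative
#' smoothness, kurtosis) of each of the eight sub-images of a two-level Haar
#' decomposition, LE channel first:
#' \code{HAAR_<CH>_<band>_<statistic>} with bands
#' LL1, HL1, LH1, HH1, LL2, HL2, LH2, HH2.
#'
#' @param pair a \linkS4class{RoiPair} with both channels >= 8x8
#' @return named numeric(96)
#' @export
haarSet <- function(pair) {
    channelFeatures <- function(img) {
        h <- haarDecompose(img, levels = 2)
        out <- unlist(lapply(.HAAR_BANDS,
                             function(b) .sixStatistics(h[[b]])))
        names(out) <- as.vector(t(outer(.HAAR_BANDS, .SIX_STATS,
                                        paste, sep = "_")))
        out
    }
    .pairFeatures(pair, channelFeatures, "HAAR")
}
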