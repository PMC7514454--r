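## Seeded synthetic CESM-like cohort generator.
## Each lesion is built from its own RNG stream keyed by (seed, lesion
## index), so a cohort can be extended without reshuffling earlier lesions:
##  (1) stationary background: Gaussian-filtered white noise (sigma =
##      correlation length), unit-variance normalized, scaled by
##      backgroundSd times a per-lesion BPE multiplier drawn from
##      bpeLevels with class-balanced assignment;
##  (2) lesion mask: centered ellipse whose radius is modulated by a
##      truncated Fourier radial perturbation (harmonics 3..8, random
##      phases), amplitude = boundary irregularity; lightly smoothed so the
##      margin is not a hard step;
##  (3) RC = baseline + background + amplitude*mask + in-lesion
##      high-frequency texture (white noise scaled by textureEnergy *
##      amplitude); LE = the same with both lesion terms scaled by
##      leFactor;
##  (4) additive white noise (noiseSd), rounding, clipping to 16 bits.

.lesionSeed <- function(seed, index)
    (abs(seed) + 7919L * index) %% 2147483647L

.gaussKernel1d <- function(sigma) {
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
    k / sum(k)
}

.blurSeparable <- function(m, sigma) {
    if (sigma <= 0) return(m)
    k <- .gaussKernel1d(sigma)
    r <- (length(k) - 1L) / 2L
    blur1 <- function(x) {           # along columns of a matrix, reflect pad
        n <- ncol(x)
        idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
        xp <- x[, idx, drop = FALSE]
        out <- matrix(0, nrow(x), n)
        for (s in seq_along(k))
            out <- out + k[s] * xp[, s:(s + n - 1), drop = FALSE]
        out
    }
    t(blur1(t(blur1(m))))
}

.defaultParams <- list(
    benign    = c(corrLength = 4, amplitude = 5000,
                  irregularity = 0.08, textureEnergy = 0.08),
    malignant = c(corrLength = 4, amplitude = 6500,
                  irregularity = 0.28, textureEnergy = 0.25))

#' Default synthetic-cohort configuration
#'
#' Emulates the structure of a CESM screening cohort: 55 lesions, 29 benign
#' and 26 malignant, four background-parenchymal-enhancement (BPE) levels
#' with class-balanced assignment, ROI sides drawn uniformly from 32-96 px,
#' 16-bit gray levels.  Malignant lesions differ from benign ones in
#' enhancement amplitude, margin spiculation and in-lesion high-frequency
#' texture energy; the background correlation structure is
#' class-independent.
#'
#' @param nLesions,nBenign,nMalignant cohort composition
#' @param roiSizeRange integer(2) min/max ROI side (pixels, min >= 16)
#' @param bpeLevels number of BPE classes (default 4)
#' @param benignParams,malignantParams named numeric(4) texture parameters
#'   (\code{corrLength}, \code{amplitude}, \code{irregularity},
#'   \code{textureEnergy})
#' @param backgroundSd background-field standard deviation (gray levels)
#' @param baseline additive offset (gray levels)
#' @param leFactor LE/RC lesion amplitude ratio
#' @param noiseSd white-noise standard deviation (gray levels)
#' @param seed master seed
#' @return a \linkS4class{CohortConfig}
#' @examples
#' cohortConfig(seed = 7)
#' @export
cohortConfig <- function(nLesions = 55L, nBenign = 29L, nMalignant = 26L,
                         roiSizeRange = c(32L, 96L), bpeLevels = 4L,
                         benignParams = .defaultParams$benign,
                         malignantParams = .defaultParams$malignant,
                         backgroundSd = 1500, baseline = 15000,
                         leFactor = 0.35, noiseSd = 300, seed = 1L) {
    new("CohortConfig",
        nLesions = as.integer(nLesions), nBenign = as.integer(nBenign),
        nMalignant = as.integer(nMalignant),
        roiSizeRange = as.integer(roiSizeRange),
        bpeLevels = as.integer(bpeLevels),
        benignParams = benignParams, malignantParams = malignantParams,
        backgroundSd = backgroundSd, baseline = baseline,
        leFactor = leFactor, noiseSd = noiseSd, seed = as.integer(seed))
}

.synthesizeLesion <- function(config, index, label, bpeLevel) {
    set.seed(.lesionSeed(config@seed, index))
    pars <- if (label == "benign") config@benignParams
            else config@malignantParams
    side <- sample(config@roiSizeRange[1]:config@roiSizeRange[2], 1L)
    mult <- seq(0.5, 1.5, length.out = config@bpeLevels)[bpeLevel]

    bg <- .blurSeparable(matrix(rnorm(side^2), side), pars[["corrLength"]])
    bg <- bg / stats::sd(as.numeric(bg)) * config@backgroundSd * mult

    ## lesion mask with Fourier-perturbed radius
    ctr <- (side + 1) / 2
    r0 <- side * stats::runif(1, 0.26, 0.34)
    harmonics <- 3:8
    coef <- stats::rnorm(length(harmonics))
    coef <- coef / sqrt(sum(coef^2) / 2)       # unit-sd perturbation
    phase <- stats::runif(length(harmonics), 0, 2 * pi)
    yy <- matrix(seq_len(side) - ctr, side, side)
    xx <- t(yy)
    theta <- atan2(yy, xx)
    pert <- Reduce(`+`, lapply(seq_along(harmonics), function(h)
        coef[h] * cos(harmonics[h] * theta + phase[h])))
    rad <- pmax(r0 * (1 + pars[["irregularity"]] * pert), 0.15 * r0)
    mask <- (sqrt(xx^2 + yy^2) <= rad) * 1
    mask <- .blurSeparable(mask, 1)

    texture <- matrix(stats::rnorm(side^2), side) *
        pars[["textureEnergy"]] * pars[["amplitude"]] * mask
    lesionRc <- pars[["amplitude"]] * mask + texture
    rc <- config@baseline + bg + lesionRc +
        stats::rnorm(side^2, sd = config@noiseSd)
    le <- config@baseline + bg + config@leFactor * lesionRc +
        stats::rnorm(side^2, sd = config@noiseSd)
    clip <- function(m) {
        m <- round(m); m[m < 0] <- 0; m[m > 65535] <- 65535
        matrix(as.integer(m), side)
    }
    list(le = clip(le), rc = clip(rc), side = side)
}

#' Generate a synthetic CESM-like cohort
#'
#' Writes one LE and one RC 16-bit grayscale TIFF per lesion plus a CSV
#' manifest with header
#' \code{lesion_id,patient_id,view,label,bpe_level,le_path,rc_path}.
#' BPE levels are assigned round-robin within each class, so benign and
#' malignant counts per level differ by at most 1.  Output is bit-exact
#' reproducible for a fixed configuration (each lesion has its own RNG
#' stream keyed by the master seed and the lesion index).
#'
#' @param config a \linkS4class{CohortConfig}
#' @param outDir output directory (created if needed)
#' @return invisibly, the manifest data.frame (also written to
#'   \code{manifest.csv} in \code{outDir})
#' @examples
#' dir <- tempfile()
#' mf <- generateCohort(cohortConfig(nLesions = 4L, nBenign = 2L,
#'                                   nMalignant = 2L, seed = 1L), dir)
#' table(mf$label)
#' @export
generateCohort <- function(config, outDir) {
    validObject(config)
    if (config@nLesions < 1L) stop("cohort must contain at least 1 lesion")
    imgDir <- file.path(outDir, "images")
    dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)

    labels <- c(rep("benign", config@nBenign),
                rep("malignant", config@nMalignant))
    ## interleave classes proportionally so lesion order carries no signal
    pos <- c((seq_len(config@nBenign) - 0.5) / max(1L, config@nBenign),
             (seq_len(config@nMalignant) - 0.25) / max(1L, config@nMalignant))
    labels <- labels[order(pos)]
    classIdx <- stats::ave(seq_along(labels), labels, FUN = seq_along)
    bpe <- (classIdx - 1L) %% config@bpeLevels + 1L
    nPatients <- max(1L, config@nLesions - 4L)
    views <- c("CC", "MLO")

    rows <- vector("list", config@nLesions)
    for (i in seq_len(config@nLesions)) {
        lesion <- .synthesizeLesion(config, i, labels[i], bpe[i])
        id <- sprintf("L%03d", i)
        lePath <- file.path(imgDir, paste0(id, "_le.tiff"))
        rcPath <- file.path(imgDir, paste0(id, "_rc.tiff"))
        tiff::writeTIFF(lesion$le / 65535, lePath, bits.per.sample = 16L,
                        compression = "none")
        tiff::writeTIFF(lesion$rc / 65535, rcPath, bits.per.sample = 16L,
                        compression = "none")
        rows[[i]] <- data.frame(
            lesion_id = id,
            patient_id = sprintf("P%03d", (i - 1L) %% nPatients + 1L),
            view = views[(i %% 2L) + 1L],
            label = labels[i], bpe_level = bpe[i],
            le_path = lePath, rc_path = rcPath,
            stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(manifest)
}

#' Class-separability summary of a generated cohort
#'
#' For each feature set, the standardized mean differences (Cohen's d with
#' pooled population SD) of the five most class-separating features.  Used
#' to calibrate and sanity-check the generator: with default parameters at
#' least one RC-derived feature should separate strongly (|d| > 0.8), while
#' a degenerate configuration with identical class parameters should show
#' only noise-level effect sizes.
#'
#' @param manifestPath path to a cohort manifest CSV
#' @param sets feature sets to summarize (default STAT and GRAD; HAAR/GLCM
#'   are accepted but slower)
#' @return data.frame with columns set, feature, effect_size, ordered by
#'   decreasing |effect_size| within set
#' @export
classSeparabilityReport <- function(manifestPath,
                                    sets = c("STAT", "GRAD")) {
    pairs <- loadCohort(manifestPath)
    labels <- vapply(pairs, function(p) p@record$label, character(1))
    if (length(unique(labels)) < 2L)
        stop("both classes must be present to measure separability")
    tables <- extractFeatures(pairs, sets = sets)
    out <- lapply(tables, function(ft) {
        v <- featureValues(ft)
        y <- lesionLabels(ft)
        d <- vapply(seq_len(ncol(v)), function(j) {
            a <- v[y == "benign", j]; b <- v[y == "malignant", j]
            sp <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
                       (length(a) + length(b)))
            if (sp == 0) 0 else (mean(b) - mean(a)) / sp
        }, numeric(1))
        ord <- order(-abs(d))[seq_len(min(5L, ncol(v)))]
        data.frame(set = setId(ft), feature = featureNames(ft)[ord],
                   effect_size = d[ord], stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}
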