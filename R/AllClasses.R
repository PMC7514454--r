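#' @import methods
#' @importFrom stats setNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.FEATURE_SETS <- c("STAT", "GRAD", "HAAR", "GLCM")
.SET_ARITY   <- c(STAT = 22L, GRAD = 24L, HAAR = 96L, GLCM = 312L)
.CLASS_LEVELS <- c("benign", "malignant")

#' Configuration of a synthetic CESM-like cohort
#'
#' Parameters of the seeded generator that emulates a cohort of paired
#' low-energy (LE) / recombined (RC) lesion regions of interest.  Lesion
#' texture is controlled per class by four knobs: the correlation length of
#' the stationary background field (pixels), the contrast-enhancement
#' amplitude added inside the lesion mask on the RC channel (gray levels),
#' the radial boundary-irregularity amplitude (unitless; spiculation), and
#' the high-frequency in-lesion texture energy (unitless fraction of the
#' enhancement amplitude).
#'
#' @slot nLesions,nBenign,nMalignant cohort composition (lesions)
#' @slot roiSizeRange integer(2), min/max ROI side in pixels
#' @slot bpeLevels number of background-parenchymal-enhancement classes used
#'   for class-balanced assignment
#' @slot benignParams,malignantParams named numeric(4):
#'   \code{corrLength}, \code{amplitude}, \code{irregularity},
#'   \code{textureEnergy}
#' @slot backgroundSd baseline standard deviation of the background field in
#'   gray levels, before the per-lesion BPE multiplier
#' @slot baseline additive gray-level offset of both channels
#' @slot leFactor amplitude ratio of the LE lesion density to the RC
#'   enhancement
#' @slot noiseSd white-noise standard deviation in gray levels
#' @slot seed integer master seed; each lesion derives its own stream from
#'   (seed, lesion index)
#' @export
setClass("CohortConfig", representation(
    nLesions       = "integer",
    nBenign        = "integer",
    nMalignant     = "integer",
    roiSizeRange   = "integer",
    bpeLevels      = "integer",
    benignParams   = "numeric",
    malignantParams = "numeric",
    backgroundSd   = "numeric",
    baseline       = "numeric",
    leFactor       = "numeric",
    noiseSd        = "numeric",
    seed           = "integer"
))

.PARAM_NAMES <- c("corrLength", "amplitude", "irregularity", "textureEnergy")

setValidity("CohortConfig", function(object) {
    msg <- character()
    if (object@nBenign + object@nMalignant != object@nLesions)
        msg <- c(msg, "nBenign + nMalignant must equal nLesions")
    if (length(object@roiSizeRange) != 2L ||
        object@roiSizeRange[1] > object@roiSizeRange[2])
        msg <- c(msg, "roiSizeRange must be increasing (min, max)")
    if (object@roiSizeRange[1] < 16L)
        msg <- c(msg, paste(
            "minimum ROI side is 16 px: two dyadic Haar reductions must",
            "leave level-2 sub-images of at least 4x4"))
    for (p in c("benignParams", "malignantParams")) {
        v <- slot(object, p)
        if (!identical(names(v), .PARAM_NAMES))
            msg <- c(msg, sprintf("%s must be named %s", p,
                                  paste(.PARAM_NAMES, collapse = ", ")))
        else if (any(v < 0))
            msg <- c(msg, sprintf("%s must be non-negative", p))
    }
    if (object@noiseSd < 0 || object@backgroundSd < 0)
        msg <- c(msg, "noise and background standard deviations must be >= 0")
    if (object@bpeLevels < 1L)
        msg <- c(msg, "bpeLevels must be >= 1")
    if (length(msg)) msg else TRUE
})

#' One lesion's paired LE/RC region of interest
#'
#' @slot le,rc numeric matrices in gray-level units, identical dimensions
#' @slot record one-row data.frame with lesion metadata (lesion_id,
#'   patient_id, view, label, bpe_level, bit depth)
#' @export
setClass("RoiPair", representation(
    le = "matrix", rc = "matrix", record = "data.frame"))

setValidity("RoiPair", function(object) {
    msg <- character()
    if (!identical(dim(object@le), dim(object@rc)))
        msg <- c(msg, sprintf(
            "LE and RC dimensions differ: %s vs %s",
            paste(dim(object@le), collapse = "x"),
            paste(dim(object@rc), collapse = "x")))
    if (any(dim(object@le) < 16L))
        msg <- c(msg, "ROI must be at least 16x16")
    if (!all(is.finite(object@le)) || !all(is.finite(object@rc)))
        msg <- c(msg, "pixel values must be finite")
    if (min(object@le) < 0 || min(object@rc) < 0)
        msg <- c(msg, "pixel values must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Feature table: lesions by named texture features
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"values"}
#' (features in rows, lesions in columns), per-lesion class labels in
#' \code{colData()$label}, and the feature-set identifier in
#' \code{metadata()$setId}.  Feature names follow the stable scheme
#' \code{<set>_<channel>_<subimage?>_<direction?>_<statistic>} so that
#' selection-frequency reports are unambiguous.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
    msg <- character()
    nm <- rownames(object)
    if (is.null(nm) || anyDuplicated(nm))
        msg <- c(msg, "feature names must be present and unique")
    if (!"values" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'values' is required")
    if (!"label" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'label' column")
    else if (!all(as.character(object$label) %in% .CLASS_LEVELS))
        msg <- c(msg, "labels must be 'benign' or 'malignant'")
    if (length(msg)) msg else TRUE
})

#' Per-feature selection frequencies under true and permuted labels
#'
#' @slot method "wrapper" or "embedded"
#' @slot table DataFrame with per-feature \code{count_true},
#'   \code{count_perm}, \code{fisher_p}, \code{significant}
#' @slot nRounds number of successful resampling rounds per arm
#' @slot alpha significance level
#' @export
setClass("SelectionResult", representation(
    method = "character", table = "DataFrame",
    nRounds = "integer", alpha = "numeric"))

setValidity("SelectionResult", function(object) {
    msg <- character()
    tb <- object@table
    need <- c("count_true", "count_perm", "fisher_p", "significant")
    if (!all(need %in% colnames(tb)))
        msg <- c(msg, paste("table must contain",
                            paste(need, collapse = ", ")))
    else {
        if (any(tb$count_true < 0 | tb$count_true > object@nRounds) ||
            any(tb$count_perm < 0 | tb$count_perm > object@nRounds))
            msg <- c(msg, "counts must lie in [0, nRounds]")
        if (any(tb$fisher_p <= 0 | tb$fisher_p > 1))
            msg <- c(msg, "fisher_p must lie in (0, 1]")
        if (!identical(tb$significant, tb$fisher_p < object@alpha))
            msg <- c(msg, "significant must equal fisher_p < alpha")
    }
    if (length(msg)) msg else TRUE
})

#' Cross-validated classification performance
#'
#' Mean and 95\% confidence interval (normal approximation over CV rounds)
#' of accuracy, sensitivity and specificity in percent, with the aggregated
#' confusion counts.  Malignant is the positive class.
#'
#' @slot metrics data.frame with rows accuracy/sensitivity/specificity and
#'   columns mean, ci_lower, ci_upper (percent)
#' @slot confusion named numeric: mean per-round TP, TN, FP, FN
#' @slot nRounds,nFolds CV geometry
#' @slot classifier,features descriptors
#' @export
setClass("PerformanceReport", representation(
    metrics = "data.frame", confusion = "numeric",
    nRounds = "integer", nFolds = "integer",
    classifier = "character", features = "character",
    roundMetrics = "matrix"))

setValidity("PerformanceReport", function(object) {
    m <- object@metrics
    msg <- character()
    if (!all(c("mean", "ci_lower", "ci_upper") %in% colnames(m)))
        msg <- c(msg, "metrics needs mean, ci_lower, ci_upper columns")
    else {
        if (any(m$mean < 0 | m$mean > 100))
            msg <- c(msg, "metrics are percentages in [0, 100]")
        if (any(m$ci_lower > m$mean | m$ci_upper < m$mean))
            msg <- c(msg, "confidence interval must contain the mean")
    }
    if (length(msg)) msg else TRUE
})

#' Principal component model of a standardized feature table
#'
#' @slot center,scale per-feature standardization constants
#' @slot loadings orthonormal loading vectors (features x components)
#' @slot varianceExplained fractions, non-increasing, summing to 1
#' @slot dropped names of constant features removed before standardization
#' @export
setClass("PcaModel", representation(
    center = "numeric", scale = "numeric", loadings = "matrix",
    varianceExplained = "numeric", dropped = "character"))

setValidity("PcaModel", function(object) {
    msg <- character()
    L <- object@loadings
    if (ncol(L) >= 1) {
        g <- crossprod(L)
        if (max(abs(g - diag(ncol(L)))) > 1e-8)
            msg <- c(msg, "loadings must be orthonormal")
    }
    v <- object@varianceExplained
    if (is.unsorted(rev(v), strictly = FALSE))
        msg <- c(msg, "variance fractions must be non-increasing")
    if (length(msg)) msg else TRUE
})
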