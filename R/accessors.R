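#' Construct a FeatureTable
#'
#' @param values numeric matrix, lesions in rows and features in columns
#'   (stored transposed, Bioconductor-style: features x lesions)
#' @param labels character/factor of per-lesion classes,
#'   \code{"benign"}/\code{"malignant"}
#' @param setId feature-set identifier: one of STAT, GRAD, HAAR, GLCM, or a
#'   free-form id for derived tables
#' @param lesionIds optional lesion identifiers (defaults to rownames)
#' @param params optional list of extraction parameters stored in metadata
#' @return a \linkS4class{FeatureTable}
#' @examples
#' ft <- FeatureTable(matrix(rnorm(20), 10, 2,
#'                           dimnames = list(NULL, c("f1", "f2"))),
#'                    labels = rep(c("benign", "malignant"), 5),
#'                    setId = "CUSTOM")
#' dim(featureValues(ft))
#' @export
FeatureTable <- function(values, labels, setId,
                         lesionIds = NULL, params = list()) {
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        stop("feature columns must be named")
    if (anyDuplicated(colnames(values)))
        stop("duplicate feature names: ",
             paste(unique(colnames(values)[duplicated(colnames(values))]),
                   collapse = ", "))
    if (nrow(values) != length(labels))
        stop("one label per lesion required")
    if (is.null(lesionIds))
        lesionIds <- rownames(values)
    if (is.null(lesionIds))
        lesionIds <- sprintf("lesion%03d", seq_len(nrow(values)))
    lesionIds <- make.unique(as.character(lesionIds))  # bootstrap resamples
    labels <- factor(as.character(labels), levels = .CLASS_LEVELS)
    if (anyNA(labels))
        stop("labels must be 'benign' or 'malignant'")
    assay <- t(values)
    colnames(assay) <- lesionIds
    se <- SummarizedExperiment(
        assays = list(values = assay),
        colData = DataFrame(label = labels, row.names = lesionIds))
    metadata(se)$setId <- setId
    metadata(se)$params <- params
    new("FeatureTable", se)
}

#' @describeIn FeatureTable-class lesions x features numeric matrix
#' @export
setMethod("featureValues", "FeatureTable",
          function(object) t(assay(object, "values")))

#' @describeIn FeatureTable-class per-lesion class factor
#' @export
setMethod("lesionLabels", "FeatureTable", function(object) object$label)

#' @describeIn FeatureTable-class feature-set identifier
#' @export
setMethod("setId", "FeatureTable",
          function(object) metadata(object)$setId)

#' @describeIn FeatureTable-class feature names
#' @param x,i,... see base generics
#' @export
featureNames <- function(x) rownames(x)

setMethod("show", "FeatureTable", function(object) {
    lab <- table(lesionLabels(object))
    cat(sprintf("FeatureTable '%s': %d features x %d lesions (%s)\n",
                setId(object), nrow(object), ncol(object),
                paste(sprintf("%d %s", lab, names(lab)), collapse = ", ")))
})

#' Restrict a FeatureTable to a feature subset
#'
#' @param table a \linkS4class{FeatureTable}
#' @param features character vector of feature names to keep
#' @return the restricted \linkS4class{FeatureTable}
#' @export
subsetFeatures <- function(table, features) {
    missing <- setdiff(features, featureNames(table))
    if (length(missing))
        stop("unknown features: ", paste(missing, collapse = ", "))
    table[features, ]
}

#' @describeIn RoiPair-class low-energy channel matrix
#' @export
setMethod("leImage", "RoiPair", function(object) object@le)

#' @describeIn RoiPair-class recombined channel matrix
#' @export
setMethod("rcImage", "RoiPair", function(object) object@rc)

#' Construct a RoiPair
#' @param le,rc numeric gray-level matrices of identical dimensions
#' @param record one-row data.frame of lesion metadata; a minimal record is
#'   built when omitted
#' @export
RoiPair <- function(le, rc, record = NULL) {
    if (is.null(record))
        record <- data.frame(lesion_id = "lesion", patient_id = "patient",
                             view = "CC", label = "benign", bpe_level = 1L,
                             stringsAsFactors = FALSE)
    new("RoiPair", le = le, rc = rc, record = record)
}

setMethod("show", "RoiPair", function(object) {
    cat(sprintf("RoiPair %s [%s]: %dx%d px, LE+RC\n",
                object@record$lesion_id, object@record$label,
                nrow(object@le), ncol(object@le)))
})

#' @describeIn SelectionResult-class features whose selection frequency is
#'   significantly enriched under true labels (Fisher p < alpha), or all
#'   features ever selected when \code{significantOnly = FALSE}
#' @param significantOnly logical
#' @export
setMethod("selectedFeatures", "SelectionResult",
          function(object, significantOnly = TRUE) {
    tb <- object@table
    if (significantOnly) rownames(tb)[tb$significant]
    else rownames(tb)[tb$count_true > 0]
})

#' @describeIn SelectionResult-class full per-feature DataFrame
#' @export
setMethod("selectionTable", "SelectionResult", function(object) object@table)

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf(
        "SelectionResult (%s): %d features, %d significant at alpha=%g (%d rounds/arm)\n",
        object@method, nrow(object@table), sum(object@table$significant),
        object@alpha, object@nRounds))
})

setMethod("show", "PerformanceReport", function(object) {
    cat(sprintf("PerformanceReport: %s on %s (%d x %d-fold CV)\n",
                object@classifier, object@features,
                object@nRounds, object@nFolds))
    m <- object@metrics
    for (i in seq_len(nrow(m)))
        cat(sprintf("  %-12s %6.2f%% [%.2f, %.2f]\n", rownames(m)[i],
                    m$mean[i], m$ci_lower[i], m$ci_upper[i]))
})

setMethod("show", "PcaModel", function(object) {
    cat(sprintf("PcaModel: %d features -> %d components (top: %.1f%% var)\n",
                nrow(object@loadings), ncol(object@loadings),
                100 * object@varianceExplained[1]))
})

setMethod("show", "CohortConfig", function(object) {
    cat(sprintf(
        "CohortConfig: %d lesions (%d benign / %d malignant), %d BPE levels, side %d-%d px, seed %d\n",
        object@nLesions, object@nBenign, object@nMalignant,
        object@bpeLevels, object@roiSizeRange[1], object@roiSizeRange[2],
        object@seed))
})
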