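#' @rdname FeatureTable-class
#' @param object a package object
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname FeatureTable-class
#' @export
setGeneric("lesionLabels", function(object) standardGeneric("lesionLabels"))

#' @rdname FeatureTable-class
#' @export
setGeneric("setId", function(object) standardGeneric("setId"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectedFeatures",
           function(object, ...) standardGeneric("selectedFeatures"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectionTable",
           function(object) standardGeneric("selectionTable"))

#' @rdname RoiPair-class
#' @export
setGeneric("leImage", function(object) standardGeneric("leImage"))

#' @rdname RoiPair-class
#' @export
setGeneric("rcImage", function(object) standardGeneric("rcImage"))
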