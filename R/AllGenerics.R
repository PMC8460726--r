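#' @rdname PairLibrary-accessors
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname PairLibrary-accessors
#' @export
setGeneric("designs", function(x) standardGeneric("designs"))

#' @rdname PairLibrary-accessors
#' @export
setGeneric("barcodeKeys", function(x) standardGeneric("barcodeKeys"))

#' @rdname OutcomeCounts-accessors
#' @export
setGeneric("outcomeCounts", function(x) standardGeneric("outcomeCounts"))

#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-accessors
#' @export
setGeneric("layoutInfo", function(x) standardGeneric("layoutInfo"))
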