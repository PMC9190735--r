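#' @rdname timePoints
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname samplingRate
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname trialInfo
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' @rdname epochData
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname objectIds
#' @export
setGeneric("objectIds", function(x) standardGeneric("objectIds"))

#' @rdname categoryLabels
#' @export
setGeneric("categoryLabels", function(x) standardGeneric("categoryLabels"))

#' @rdname dimensionNames
#' @export
setGeneric("dimensionNames", function(x) standardGeneric("dimensionNames"))

#' @rdname conditionNames
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' @rdname supertrialData
#' @export
setGeneric("supertrialData", function(x) standardGeneric("supertrialData"))

#' @rdname provenance
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname whiteningMatrix
#' @export
setGeneric("whiteningMatrix", function(x) standardGeneric("whiteningMatrix"))

#' @rdname shrinkageIntensity
#' @export
setGeneric("shrinkageIntensity",
           function(x) standardGeneric("shrinkageIntensity"))

#' @rdname accuracyValues
#' @export
setGeneric("accuracyValues", function(x) standardGeneric("accuracyValues"))

#' @rdname decodingScheme
#' @export
setGeneric("decodingScheme", function(x) standardGeneric("decodingScheme"))

#' @rdname significantMask
#' @export
setGeneric("significantMask", function(x) standardGeneric("significantMask"))

#' @rdname clusterTable
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname pointwiseP
#' @export
setGeneric("pointwiseP", function(x) standardGeneric("pointwiseP"))

#' @rdname peakLatencies
#' @export
setGeneric("peakLatencies", function(x) standardGeneric("peakLatencies"))

#' @rdname bootDifferences
#' @export
setGeneric("bootDifferences", function(x) standardGeneric("bootDifferences"))

#' @rdname applyNormalizer
#' @export
setGeneric("applyNormalizer",
           function(x, normalizer) standardGeneric("applyNormalizer"))
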