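#' @rdname PfaResult-class
#' @param object,x a result object
#' @export
setGeneric("principalFeatures",
           function(object) standardGeneric("principalFeatures"))

#' @rdname PfaResult-class
#' @export
setGeneric("removedFeatures",
           function(object) standardGeneric("removedFeatures"))

#' @rdname ClusterLabels-class
#' @export
setGeneric("clusterIds", function(object) standardGeneric("clusterIds"))

#' @rdname BinnedMatrix-class
#' @export
setGeneric("binAssignments",
           function(object) standardGeneric("binAssignments"))

#' @rdname BinnedMatrix-class
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' @rdname RankedFeatures-class
#' @export
setGeneric("ranking", function(object) standardGeneric("ranking"))

#' @rdname Embedding-class
#' @export
setGeneric("embeddingCoords",
           function(object) standardGeneric("embeddingCoords"))
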