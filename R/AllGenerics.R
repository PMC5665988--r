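#' @name accessors
#' @title Accessors for planktonNCP classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param x an object of the documented class.
#' @return The accessed component.
NULL

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname accessors
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname accessors
#' @export
setGeneric("inclusionProbs", function(x) standardGeneric("inclusionProbs"))

#' @rdname accessors
#' @export
setGeneric("predictorRanking", function(x)
    standardGeneric("predictorRanking"))

#' @rdname accessors
#' @export
setGeneric("selectedPredictors", function(x)
    standardGeneric("selectedPredictors"))

#' @rdname accessors
#' @export
setGeneric("betaDraws", function(x) standardGeneric("betaDraws"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname accessors
#' @export
setGeneric("trueEffects", function(x) standardGeneric("trueEffects"))

#' @rdname accessors
#' @export
setGeneric("trueNcp", function(x) standardGeneric("trueNcp"))

#' Graph topology metrics of a co-occurrence network
#'
#' @param network a [CooccurrenceNetwork-class].
#' @param ... passed to methods; see [topologyMetrics,CooccurrenceNetwork-method].
#' @export
setGeneric("topologyMetrics", function(network, ...)
    standardGeneric("topologyMetrics"))
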