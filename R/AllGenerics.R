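#' @rdname RegionalCBF
#' @param x,object an object of the documented class.
#' @export
setGeneric("cbfMatrix", function(x) standardGeneric("cbfMatrix"))

#' @rdname RegionalCBF
#' @export
setGeneric("subjectInfo", function(x) standardGeneric("subjectInfo"))

#' @rdname RegionalCBF
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname RegionalCBF
#' @export
setGeneric("isResidualized", function(x) standardGeneric("isResidualized"))

#' @rdname SyntheticCohort
#' @export
setGeneric("cohortGroup", function(x, group) standardGeneric("cohortGroup"))

#' @rdname SyntheticCohort
#' @export
setGeneric("truthMatrices", function(x) standardGeneric("truthMatrices"))

#' @rdname CovarianceNetwork
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))

#' @rdname ThresholdedGraph
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname ThresholdedGraph
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname ThresholdedGraph
#' @export
setGeneric("sparsityLevel", function(x) standardGeneric("sparsityLevel"))

#' @rdname ThresholdedGraph
#' @export
setGeneric("graphMode", function(x) standardGeneric("graphMode"))

#' @rdname ThresholdedGraph
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname ThresholdedGraph
#' @export
setGeneric("asIgraph", function(x, distance = FALSE)
    standardGeneric("asIgraph"))

#' @rdname MetricCurve
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' @rdname MetricCurve
#' @export
setGeneric("aucValues", function(x) standardGeneric("aucValues"))

#' @rdname PermutationResult
#' @export
setGeneric("observedDifference", function(x)
    standardGeneric("observedDifference"))

#' @rdname PermutationResult
#' @export
setGeneric("nullDistribution", function(x)
    standardGeneric("nullDistribution"))

#' @rdname PermutationResult
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
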