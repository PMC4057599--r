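#' Accessors for gatewaynet classes
#'
#' \code{stateLabel} returns the biological state name carried by an
#' object; \code{networkGraph} the underlying \pkg{igraph} graph;
#' \code{clusterMembers} the probe identifiers of a cluster.
#'
#' @param x a gatewaynet object.
#' @return \code{stateLabel}: character; \code{networkGraph}: an igraph
#'   graph; \code{clusterMembers}: character vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stateLabel", function(x) standardGeneric("stateLabel"))

#' @rdname accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname accessors
#' @export
setMethod("stateLabel", "StateExpression", function(x) x@stateLabel)

#' @rdname accessors
#' @export
setMethod("stateLabel", "StateNetwork", function(x) x@stateLabel)

#' @rdname accessors
#' @export
setMethod("stateLabel", "DenseCluster", function(x) x@stateLabel)

#' @rdname accessors
#' @export
setMethod("networkGraph", "StateNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("networkGraph", "IntegratedNetwork", function(x) x@graph)

#' @rdname accessors
#' @export
setMethod("clusterMembers", "DenseCluster", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("clusterDensityValue",
    function(x) standardGeneric("clusterDensityValue"))

#' @rdname accessors
#' @export
setMethod("clusterDensityValue", "DenseCluster", function(x) x@density)

#' @rdname accessors
#' @export
setGeneric("clusterId", function(x) standardGeneric("clusterId"))

#' @rdname accessors
#' @export
setMethod("clusterId", "DenseCluster", function(x) x@clusterId)

#' @rdname accessors
#' @export
setGeneric("sourceClusters", function(x) standardGeneric("sourceClusters"))

#' @rdname accessors
#' @export
setMethod("sourceClusters", "IntegratedNetwork", function(x) x@clusters)

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname accessors
#' @export
setMethod("stateLabels", "IntegratedNetwork", function(x) x@stateLabels)

#' Expression values of a StateExpression
#'
#' @param x a \linkS4class{StateExpression}.
#' @return numeric matrix, probes in rows.
#' @export
exprsValues <- function(x) {
    stopifnot(is(x, "StateExpression"))
    SummarizedExperiment::assay(x)
}
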