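#' @name accessors
#' @title Accessors for netCentral classes
#' @description Small accessor generics: prefer these over direct slot
#'   access.
#' @param x a netCentral object.
#' @return \code{nodeIds}: character vector; \code{edgeTable}: data.frame;
#'   \code{numNodes}/\code{numEdges}: integer; \code{isDirected}/
#'   \code{isWeighted}: logical; \code{networkName}: character;
#'   \code{centralityValues}: named numeric; \code{resultScope},
#'   \code{resultMode}: scope string / mode list; \code{attributeNames}:
#'   character; \code{distances}: numeric matrix; \code{classificationCalls},
#'   \code{classificationThresholds}: the report's call matrix / thresholds.
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))
#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))
#' @rdname accessors
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))
#' @rdname accessors
#' @export
setGeneric("isWeighted", function(x) standardGeneric("isWeighted"))
#' @rdname accessors
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))
#' @rdname accessors
#' @export
setGeneric("centralityValues", function(x) standardGeneric("centralityValues"))
#' @rdname accessors
#' @export
setGeneric("resultScope", function(x) standardGeneric("resultScope"))
#' @rdname accessors
#' @export
setGeneric("resultMode", function(x) standardGeneric("resultMode"))
#' @rdname accessors
#' @export
setGeneric("attributeNames", function(x) standardGeneric("attributeNames"))
#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))
#' @rdname accessors
#' @export
setGeneric("classificationCalls", function(x) standardGeneric("classificationCalls"))
#' @rdname accessors
#' @export
setGeneric("classificationThresholds", function(x) standardGeneric("classificationThresholds"))
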