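#' @rdname accessors
#' @aliases nodeIds,Network-method
setMethod("nodeIds", "Network", function(x) x@nodes)

#' @rdname accessors
#' @aliases edgeTable,Network-method
setMethod("edgeTable", "Network", function(x) x@edges)

#' @rdname accessors
#' @aliases numNodes,Network-method
setMethod("numNodes", "Network", function(x) length(x@nodes))

#' @rdname accessors
#' @aliases numEdges,Network-method
setMethod("numEdges", "Network", function(x) nrow(x@edges))

#' @rdname accessors
#' @aliases isDirected,Network-method
setMethod("isDirected", "Network", function(x) x@directed)

#' @rdname accessors
#' @aliases isWeighted,Network-method
setMethod("isWeighted", "Network", function(x) {
    nrow(x@edges) > 0L && !anyNA(x@edges$weight)
})

#' @rdname accessors
#' @aliases networkName,Network-method
setMethod("networkName", "Network", function(x) x@name)

setMethod("show", "Network", function(object) {
    cat(sprintf("Network '%s': %d nodes, %d edges, %s, %s\n",
                object@name, numNodes(object), numEdges(object),
                if (object@directed) "directed" else "undirected",
                if (isWeighted(object)) "weighted" else "unweighted"))
    ids <- object@nodes
    cat("  nodes: ", paste(utils::head(ids, 8L), collapse = ", "),
        if (length(ids) > 8L) ", ..." else "", "\n", sep = "")
})

#' @rdname accessors
#' @aliases centralityValues,CentralityResult-method
setMethod("centralityValues", "CentralityResult", function(x) x@values)

#' @rdname accessors
#' @aliases resultScope,CentralityResult-method
setMethod("resultScope", "CentralityResult", function(x) x@scope)

#' @rdname accessors
#' @aliases resultMode,CentralityResult-method
setMethod("resultMode", "CentralityResult", function(x) x@mode)

setMethod("show", "CentralityResult", function(object) {
    m <- object@mode
    cat(sprintf("CentralityResult '%s' (%s scope; %s, %s)\n",
                object@index, object@scope,
                if (isTRUE(m$directed)) "directed" else "undirected",
                if (isTRUE(m$weighted)) "weighted" else "unweighted"))
    v <- object@values
    if (object@scope == "network") {
        print(v)
    } else {
        cat(sprintf("  %d values; range [%s, %s]\n", length(v),
                    format(min(v)), format(max(v))))
    }
})

#' @rdname accessors
#' @aliases nodeIds,AttributeTable-method
setMethod("nodeIds", "AttributeTable", function(x) rownames(x@data))

#' @rdname accessors
#' @aliases attributeNames,AttributeTable-method
setMethod("attributeNames", "AttributeTable", function(x) colnames(x@data))

#' Extract one attribute as a named vector
#'
#' @param x an [AttributeTable-class].
#' @param name attribute (column) name.
#' @return named numeric vector over the table's node ids (\code{NA} where
#'   missing).
#' @export
attributeValues <- function(x, name) {
    stopifnot(is(x, "AttributeTable"))
    if (!name %in% colnames(x@data))
        stop(sprintf("unknown attribute '%s'; available: %s", name,
                     paste(colnames(x@data), collapse = ", ")))
    stats::setNames(x@data[[name]], rownames(x@data))
}

setMethod("show", "AttributeTable", function(object) {
    cat(sprintf("AttributeTable: %d nodes x %d attributes (%s)\n",
                nrow(object@data), ncol(object@data),
                paste(colnames(object@data), collapse = ", ")))
})

#' @rdname accessors
#' @aliases distances,DistanceMatrix-method
setMethod("distances", "DistanceMatrix", function(x) x@mat)

setMethod("show", "DistanceMatrix", function(object) {
    m <- object@mode
    cat(sprintf("DistanceMatrix: %d x %d (%s, %s)\n",
                nrow(object@mat), ncol(object@mat),
                if (isTRUE(m$directed)) "directed" else "undirected",
                if (isTRUE(m$weighted)) "weighted" else "unweighted"))
})

#' @rdname accessors
#' @aliases classificationCalls,ClassificationReport-method
setMethod("classificationCalls", "ClassificationReport", function(x) x@calls)

#' @rdname accessors
#' @aliases classificationThresholds,ClassificationReport-method
setMethod("classificationThresholds", "ClassificationReport",
          function(x) x@thresholds)

setMethod("show", "ClassificationReport", function(object) {
    cat(sprintf("ClassificationReport: %d nodes x %d variables (rule: %s)\n",
                nrow(object@calls), ncol(object@calls), object@rule))
    for (v in colnames(object@calls)) {
        cc <- object@calls[, v]
        cat(sprintf("  %s: threshold %s, %d high / %d low / %d unclassified\n",
                    v, format(object@thresholds[[v]]),
                    sum(cc %in% TRUE), sum(cc %in% FALSE), sum(is.na(cc))))
    }
})

setMethod("show", "ModeComparison", function(object) {
    cat(sprintf("ModeComparison '%s': %d nodes, Spearman rho = %s\n",
                object@index, nrow(object@table),
                format(object@spearman, digits = 4)))
    print(table(object@table$quadrant))
})
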