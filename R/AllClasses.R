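#' @import methods
NULL

.emptyEdges <- function() {
    data.frame(from = character(), to = character(),
               weight = numeric(), stringsAsFactors = FALSE)
}

#' Network: the graph container
#'
#' An S4 container for a (possibly directed, possibly weighted) network.
#' Nodes are identified by case-sensitive character ids; edges are stored as
#' an ordered (from, to) table with an optional strictly positive weight
#' interpreted as a distance between the endpoints.  Either every edge is
#' weighted or none is: mixing weighted and unweighted edges silently
#' corrupts shortest paths and is rejected by the validity method.
#' Self-loops are recorded but never lie on a shortest path between distinct
#' nodes, so every path-based index ignores them (degree excludes them by
#' default, with a flag to include them).
#'
#' @slot nodes character vector of unique node identifiers (n >= 1).
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}
#'   (\code{NA} throughout for an unweighted network).
#' @slot directed single logical; when \code{TRUE} the edge (u,v) is distinct
#'   from (v,u).
#' @slot name display name of the network.
#'
#' @seealso [Network()] for the user-facing constructor, [readSIF()],
#'   [readEdgeList()], [readGraphML()] for file readers.
#' @exportClass Network
setClass("Network",
         slots = c(nodes = "character",
                   edges = "data.frame",
                   directed = "logical",
                   name = "character"))

setValidity("Network", function(object) {
    msg <- character()
    if (length(object@nodes) < 1L)
        msg <- c(msg, "a network must contain at least one node")
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "node ids must be unique")
    if (any(!nzchar(object@nodes)))
        msg <- c(msg, "node ids must be non-empty strings")
    if (length(object@directed) != 1L || is.na(object@directed))
        msg <- c(msg, "'directed' must be a single TRUE/FALSE")
    e <- object@edges
    if (!all(c("from", "to", "weight") %in% names(e))) {
        msg <- c(msg, "edge table must have columns from, to, weight")
    } else if (nrow(e)) {
        bad <- !(e$from %in% object@nodes) | !(e$to %in% object@nodes)
        if (any(bad))
            msg <- c(msg, sprintf("%d edge(s) reference nodes absent from the network",
                                  sum(bad)))
        w <- e$weight
        if (any(is.na(w)) && !all(is.na(w)))
            msg <- c(msg, "edges mix weighted and unweighted; weight every edge or none")
        ww <- w[!is.na(w)]
        if (length(ww) && (any(!is.finite(ww)) || any(ww <= 0)))
            msg <- c(msg, "edge weights must be finite and strictly positive")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a Network
#'
#' @param nodes character vector of node ids.  Ids are taken verbatim
#'   (case-sensitive); leading/trailing whitespace is stripped.
#' @param edges \code{NULL} for an edgeless graph, or a data.frame with
#'   columns \code{from} and \code{to} (and optionally \code{weight}).
#' @param directed logical; interpret edges as ordered pairs?
#' @param name display name.
#' @return A [Network-class] object.
#' @examples
#' g <- Network(c("A", "B", "C"),
#'              data.frame(from = c("A", "B"), to = c("B", "C")))
#' numEdges(g)
#' @export
Network <- function(nodes, edges = NULL, directed = FALSE, name = "network") {
    nodes <- trimws(as.character(nodes))
    if (is.null(edges) || nrow(edges) == 0L) {
        edges <- .emptyEdges()
    } else {
        edges <- as.data.frame(edges, stringsAsFactors = FALSE)
        if (!all(c("from", "to") %in% names(edges)))
            stop("'edges' needs columns 'from' and 'to'")
        if (!"weight" %in% names(edges))
            edges$weight <- NA_real_
        edges <- data.frame(from = trimws(as.character(edges$from)),
                            to = trimws(as.character(edges$to)),
                            weight = as.numeric(edges$weight),
                            stringsAsFactors = FALSE)
    }
    rownames(edges) <- NULL
    new("Network", nodes = nodes, edges = edges,
        directed = isTRUE(directed), name = as.character(name)[1L])
}

#' ShortestPathSummary: single-source shortest-path machinery
#'
#' Distances, shortest-path counts (sigma) and predecessor sets from one
#' source node, the substrate behind stress and betweenness.  Unreachable
#' nodes carry distance \code{Inf} and sigma 0.
#'
#' @slot source the source node id.
#' @slot dist named numeric vector of shortest-path distances.
#' @slot sigma named numeric vector counting distinct shortest paths from
#'   the source to each node (1 at the source itself).
#' @slot preds named list; for each reachable node, the character vector of
#'   predecessor node ids on shortest paths.
#' @exportClass ShortestPathSummary
setClass("ShortestPathSummary",
         slots = c(source = "character",
                   dist = "numeric",
                   sigma = "numeric",
                   preds = "list"))

#' DistanceMatrix: all-pairs shortest-path distances
#'
#' @slot mat numeric matrix, node ids on both dimensions, \code{Inf} for
#'   unreachable pairs, zero diagonal; symmetric iff the mode is undirected.
#' @slot mode list tagging the computation
#'   (\code{directed}, \code{weighted}, \code{orientation}).
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
         slots = c(mat = "matrix", mode = "list"))

#' CentralityResult: one computed index
#'
#' @slot index name of the index (e.g. \code{"betweenness"}).
#' @slot scope one of \code{"node"}, \code{"edge"}, \code{"network"}.
#' @slot values named numeric vector keyed by node id, by \code{"u|v"} edge
#'   label, or a single named scalar for network scope.
#' @slot mode list tagging the computation mode (\code{directed},
#'   \code{weighted}, \code{semantics}, \code{orientation}).
#' @exportClass CentralityResult
setClass("CentralityResult",
         slots = c(index = "character",
                   scope = "character",
                   values = "numeric",
                   mode = "list"))

setValidity("CentralityResult", function(object) {
    msg <- character()
    if (!object@scope %in% c("node", "edge", "network"))
        msg <- c(msg, "scope must be node, edge or network")
    if (is.null(names(object@values)) && length(object@values))
        msg <- c(msg, "values must be named")
    if (any(!is.finite(object@values)))
        msg <- c(msg, "centrality values must be finite")
    if (!length(object@mode))
        msg <- c(msg, "mode tag must be populated")
    if (length(msg)) msg else TRUE
})

#' AttributeTable: experimental node attributes
#'
#' Maps node ids to named numeric experimental values (expression level,
#' phosphorylation level, ...).  Missing values are \code{NA}, explicitly
#' distinct from zero.
#'
#' @slot data data.frame of numeric columns with node ids as row names.
#' @exportClass AttributeTable
setClass("AttributeTable", slots = c(data = "data.frame"))

setValidity("AttributeTable", function(object) {
    d <- object@data
    msg <- character()
    if (anyDuplicated(rownames(d)))
        msg <- c(msg, "duplicate node ids in attribute table")
    if (ncol(d) && !all(vapply(d, is.numeric, logical(1))))
        msg <- c(msg, "attribute columns must be numeric")
    if (anyDuplicated(colnames(d)))
        msg <- c(msg, "attribute names must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct an AttributeTable
#'
#' @param data data.frame of numeric columns; node ids are taken from
#'   \code{rownames(data)} unless \code{ids} is given.
#' @param ids optional character vector of node ids (length \code{nrow(data)}).
#' @return An [AttributeTable-class].
#' @examples
#' at <- AttributeTable(data.frame(expression = c(1.5, 2.0)), ids = c("A", "B"))
#' attributeNames(at)
#' @export
AttributeTable <- function(data, ids = NULL) {
    data <- as.data.frame(data, stringsAsFactors = FALSE)
    if (!is.null(ids)) rownames(data) <- trimws(as.character(ids))
    new("AttributeTable", data = data)
}

#' ClassificationReport: boolean high/low panel
#'
#' Per-node boolean calls (high = value at or above the per-variable
#' threshold) for selected centralities and experimental attributes.
#' \code{NA} marks nodes unclassified for a variable because their value is
#' missing; such nodes never match a query literal on that variable.
#'
#' @slot calls logical matrix, nodes x variables, \code{NA} = unclassified.
#' @slot thresholds named numeric vector, the resolved threshold per variable.
#' @slot rule the threshold rule used (\code{"mean"}, \code{"median"} or
#'   \code{"value:x"}).
#' @exportClass ClassificationReport
setClass("ClassificationReport",
         slots = c(calls = "matrix",
                   thresholds = "numeric",
                   rule = "character"))

#' ModeComparison: directed vs undirected contrast for one index
#'
#' @slot index the compared index name.
#' @slot table data.frame with per-node directed/undirected values, ranks,
#'   rank shift and quadrant label.
#' @slot spearman Spearman rank correlation between the two value vectors
#'   (\code{NA} when one vector is constant).
#' @exportClass ModeComparison
setClass("ModeComparison",
         slots = c(index = "character",
                   table = "data.frame",
                   spearman = "numeric"))
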