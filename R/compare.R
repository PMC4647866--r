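#' Drop edge directions
#'
#' Returns the undirected view of a network: directions are discarded and
#' antiparallel or duplicate edges collapse to a single edge carrying the
#' minimum weight (the minimum keeps shortest-path semantics intact).
#'
#' @param graph a [Network-class].
#' @return an undirected [Network-class].
#' @export
asUndirected <- function(graph) {
    stopifnot(is(graph, "Network"))
    if (!graph@directed) return(graph)
    e <- graph@edges
    if (nrow(e)) {
        a <- pmin(e$from, e$to)
        b <- pmax(e$from, e$to)
        key <- paste(a, b, sep = "\r")
        o <- order(key, e$weight)
        keep <- o[!duplicated(key[o])]
        e <- data.frame(from = a[keep], b = b[keep], weight = e$weight[keep],
                        stringsAsFactors = FALSE)
        names(e) <- c("from", "to", "weight")
        rownames(e) <- NULL
    }
    new("Network", nodes = graph@nodes, edges = e, directed = FALSE,
        name = graph@name)
}

.compareIndexFun <- function(index) {
    switch(index,
        degree = function(g, o) degreeCentrality(g, "total"),
        eccentricity = function(g, o) eccentricityCentrality(g, orientation = o),
        closeness = function(g, o) closenessCentrality(g, o),
        radiality = function(g, o) radialityCentrality(g, o),
        centroid = function(g, o) centroidValue(g, o),
        stress = function(g, o) stressCentrality(g, o),
        betweenness = function(g, o) betweennessCentrality(g, orientation = o),
        eigenvector = function(g, o) eigenvectorCentrality(g),
        bridging = function(g, o) bridgingCentrality(g, o),
        .usageStop("unknown index name '%s'; valid names are: %s", index,
                   paste(.NODE_INDICES, collapse = ", ")))
}

#' Contrast directed and undirected computation of one index
#'
#' Computes a node index under the directed interpretation of the graph and
#' again with directions dropped, then reports per-node value pairs, ranks,
#' rank shifts, the Spearman rank correlation, and a qualitative quadrant
#' per node: high/high, high/low, low/high or low/low relative to each
#' mode's mean (high means at or above the mean).  The discordant quadrants
#' (high in one mode, low in the other) are the nodes whose interpretation
#' changes entirely with the direction model -- on signalling networks these
#' are the regulators an undirected analysis mis-ranks.
#'
#' @param graph a [Network-class]; a warning is issued for undirected input,
#'   where both computations coincide.
#' @param index a node-scope index name (see [computeCentralities()]).
#' @param orientation distance orientation for the directed computation.
#' @return a [ModeComparison-class].
#' @examples
#' g <- Network(c("A", "B", "C"),
#'              data.frame(from = c("A", "B"), to = c("B", "C")),
#'              directed = TRUE)
#' compareModes(g, "stress")
#' @export
compareModes <- function(graph, index, orientation = c("out", "in")) {
    stopifnot(is(graph, "Network"))
    orientation <- match.arg(orientation)
    fun <- .compareIndexFun(index)
    if (!graph@directed)
        warning("input network is undirected: directed and undirected modes coincide")
    dirVals <- centralityValues(fun(graph, orientation))
    undVals <- centralityValues(fun(asUndirected(graph), orientation))
    rho <- if (stats::sd(dirVals) == 0 || stats::sd(undVals) == 0) {
        if (identical(rank(dirVals), rank(undVals))) 1 else NA_real_
    } else {
        stats::cor(dirVals, undVals, method = "spearman")
    }
    # high = at or above the mode's mean; an all-zero vector classifies
    # everything low (a node with zero centrality cannot be called central,
    # and for stress-like indices a direction flip can zero the whole graph)
    quadHigh <- function(v) if (all(v == 0)) rep(FALSE, length(v)) else v >= mean(v)
    hiD <- quadHigh(dirVals)
    hiU <- quadHigh(undVals)
    quadrant <- paste(ifelse(hiD, "high", "low"),
                      ifelse(hiU, "high", "low"), sep = "/")
    rd <- .centralityRank(dirVals)
    ru <- .centralityRank(undVals)
    tab <- data.frame(node = graph@nodes,
                      directed = as.numeric(dirVals),
                      undirected = as.numeric(undVals),
                      rankDirected = rd, rankUndirected = ru,
                      rankShift = ru - rd,
                      quadrant = quadrant,
                      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    new("ModeComparison", index = index, table = tab, spearman = rho)
}

#' @rdname compareModes
#' @param comparison a [ModeComparison-class].
#' @return \code{comparisonTable}: the per-node data.frame;
#'   \code{discordantNodes}: ids in the high/low or low/high quadrants.
#' @export
comparisonTable <- function(comparison) {
    stopifnot(is(comparison, "ModeComparison"))
    comparison@table
}

#' @rdname compareModes
#' @export
discordantNodes <- function(comparison) {
    stopifnot(is(comparison, "ModeComparison"))
    tab <- comparison@table
    tab$node[tab$quadrant %in% c("high/low", "low/high")]
}
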