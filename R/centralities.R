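# The centrality index suite.  Conventions (pinned as this package's
# contract):
#   * eccentricity and closeness are reciprocals (larger = more central);
#   * radiality offsets distances by the finite diameter plus one;
#   * centroid value is the minimum over opponents of gamma_v(w) - gamma_w(v);
#   * stress and betweenness are unnormalized and exclude endpoints;
#   * unreachable pairs are dropped from every sum / maximum, so all values
#     stay finite; a node reaching nothing scores 0.

.modeTag <- function(graph, orientation = "out", semantics = "distance") {
    list(directed = graph@directed, weighted = isWeighted(graph),
         semantics = semantics, orientation = orientation)
}

.nodeResult <- function(graph, index, values, orientation = "out",
                        semantics = "distance") {
    new("CentralityResult", index = index, scope = "node",
        values = stats::setNames(values, graph@nodes),
        mode = .modeTag(graph, orientation, semantics))
}

# edge labels follow the stored edge table order: "from|to"
.edgeLabels <- function(graph) {
    e <- graph@edges
    paste(e$from, e$to, sep = "|")
}

## ---- degree ---------------------------------------------------------------

#' Degree centrality
#'
#' Incident-edge count.  For directed networks ask for \code{mode}
#' \code{"in"}, \code{"out"} or \code{"total"} (in + out).  Self-loops are
#' excluded by default; when included, a loop adds 2 to an undirected degree
#' and 1 each to in- and out-degree.
#'
#' @param graph a [Network-class].
#' @param mode which degree for directed graphs; ignored (total) when
#'   undirected.
#' @param includeSelfLoops count self-loops?
#' @return a [CentralityResult-class] with node scope.
#' @examples
#' centralityValues(degreeCentrality(canonicalGraph("star", 5)))
#' @export
degreeCentrality <- function(graph, mode = c("total", "in", "out"),
                             includeSelfLoops = FALSE) {
    stopifnot(is(graph, "Network"))
    mode <- match.arg(mode)
    ids <- graph@nodes
    e <- graph@edges
    loops <- e$from == e$to
    if (!includeSelfLoops) e <- e[!loops, , drop = FALSE]
    indeg <- as.numeric(table(factor(e$to, levels = ids)))
    outdeg <- as.numeric(table(factor(e$from, levels = ids)))
    vals <- if (!graph@directed || mode == "total") indeg + outdeg
            else if (mode == "in") indeg
            else outdeg
    index <- if (graph@directed && mode != "total")
        paste0(mode, "Degree") else "degree"
    .nodeResult(graph, index, vals)
}

## ---- distance-derived indices --------------------------------------------

#' Eccentricity centrality
#'
#' Reciprocal of the longest shortest path leaving a node, so larger = more
#' central.  A node reaching no other node scores 0.  \code{raw = TRUE}
#' returns the non-reciprocal eccentricity (the longest shortest path
#' itself).
#'
#' @inheritParams singleSource
#' @param raw return the raw (non-reciprocal) eccentricity?
#' @return a [CentralityResult-class].
#' @export
eccentricityCentrality <- function(graph, raw = FALSE,
                                   orientation = c("out", "in")) {
    orientation <- match.arg(orientation)
    D <- distances(allPairs(graph, orientation))
    vals <- vapply(seq_len(nrow(D)), function(i) {
        d <- D[i, -i]
        d <- d[is.finite(d)]
        if (!length(d)) return(0)
        if (raw) max(d) else 1 / max(d)
    }, numeric(1))
    .nodeResult(graph, if (raw) "eccentricityRaw" else "eccentricity",
                vals, orientation)
}

#' Closeness centrality
#'
#' Reciprocal of the total distance from a node to every node it can reach;
#' an isolated node scores 0.
#'
#' @inheritParams eccentricityCentrality
#' @return a [CentralityResult-class].
#' @examples
#' centralityValues(closenessCentrality(weightedTriangle()))[["A"]]  # 1/7
#' @export
closenessCentrality <- function(graph, orientation = c("out", "in")) {
    orientation <- match.arg(orientation)
    D <- distances(allPairs(graph, orientation))
    vals <- vapply(seq_len(nrow(D)), function(i) {
        d <- D[i, -i]
        d <- d[is.finite(d)]
        if (!length(d)) return(0)
        1 / sum(d)
    }, numeric(1))
    .nodeResult(graph, "closeness", vals, orientation)
}

#' Radiality centrality
#'
#' Average of (diameter + 1 - distance) over the node's reachable set,
#' divided by n - 1: rewards nodes near everything relative to the
#' network's span.  The diameter is the largest finite pairwise distance in
#' the same computation mode.
#'
#' @inheritParams eccentricityCentrality
#' @return a [CentralityResult-class].
#' @export
radialityCentrality <- function(graph, orientation = c("out", "in")) {
    orientation <- match.arg(orientation)
    D <- distances(allPairs(graph, orientation))
    n <- nrow(D)
    finite <- D[is.finite(D) & row(D) != col(D)]
    delta <- if (length(finite)) max(finite) else 0
    vals <- vapply(seq_len(n), function(i) {
        d <- D[i, -i]
        d <- d[is.finite(d)]
        if (!length(d) || n == 1L) return(0)
        sum(delta + 1 - d) / (n - 1)
    }, numeric(1))
    .nodeResult(graph, "radiality", vals, orientation)
}

#' Centroid value
#'
#' For each pair (v, w), gamma_v(w) counts the other nodes strictly closer
#' to v than to w (equidistant nodes count for neither); the centroid value
#' of v is the minimum over opponents w of gamma_v(w) - gamma_w(v).
#' Positive values mark the network's centroid region.
#'
#' @inheritParams eccentricityCentrality
#' @return a [CentralityResult-class].
#' @export
centroidValue <- function(graph, orientation = c("out", "in")) {
    orientation <- match.arg(orientation)
    D <- distances(allPairs(graph, orientation))
    n <- nrow(D)
    if (n == 1L)
        return(.nodeResult(graph, "centroid", 0, orientation))
    f <- matrix(0, n, n)
    for (v in seq_len(n - 1L)) {
        for (w in seq((v + 1L), n)) {
            u <- setdiff(seq_len(n), c(v, w))
            gvw <- sum(D[v, u] < D[w, u])
            gwv <- sum(D[w, u] < D[v, u])
            f[v, w] <- gvw - gwv
            f[w, v] <- gwv - gvw
        }
    }
    diag(f) <- NA
    vals <- apply(f, 1L, min, na.rm = TRUE)
    vals[!is.finite(vals)] <- 0   # n == 1 guard; min over empty set
    .nodeResult(graph, "centroid", vals, orientation)
}

## ---- Brandes accumulation: stress, betweenness, edge betweenness ---------

# One pass over all sources accumulating node betweenness, stress and
# per-edge betweenness.  Vertices are processed in decreasing distance
# (ties by index) so accumulation order is identical whether the summaries
# came from BFS or Dijkstra.
.brandesAccumulate <- function(graph, orientation = "out") {
    sp <- .spAll(graph, orientation)
    n <- sp$adjd$n
    btw <- numeric(n)
    strs <- numeric(n)
    eb <- numeric(nrow(graph@edges))
    for (core in sp$cores) {
        delta <- numeric(n)     # betweenness dependency
        deltaS <- numeric(n)    # stress dependency (path counts)
        for (w in .accumulationOrder(core)) {
            pr <- core$preds[[w]]
            if (length(pr$p)) {
                cb <- core$sigma[pr$p] / core$sigma[w] * (1 + delta[w])
                delta[pr$p] <- delta[pr$p] + cb
                eb[pr$e] <- eb[pr$e] + cb
                cs <- core$sigma[pr$p] * (1 + deltaS[w] / core$sigma[w])
                deltaS[pr$p] <- deltaS[pr$p] + cs
            }
            if (w != core$s) {
                btw[w] <- btw[w] + delta[w]
                strs[w] <- strs[w] + deltaS[w]
            }
        }
    }
    if (!graph@directed) {   # each unordered pair was counted from both ends
        btw <- btw / 2; strs <- strs / 2; eb <- eb / 2
    }
    list(betweenness = btw, stress = strs, edge = eb)
}

#' Stress centrality
#'
#' Number of shortest paths between pairs of other nodes that pass through
#' a node (the node is never an endpoint of the counted paths).  Pairs are
#' unordered for undirected networks and ordered for directed ones, which
#' is why reversing a single edge can silently zero a node's stress.
#'
#' @inheritParams eccentricityCentrality
#' @return a [CentralityResult-class].
#' @examples
#' p3 <- canonicalGraph("path", 3)
#' centralityValues(stressCentrality(p3))   # midpoint transits one path
#' @export
stressCentrality <- function(graph, orientation = c("out", "in")) {
    orientation <- match.arg(orientation)
    acc <- .brandesAccumulate(graph, orientation)
    .nodeResult(graph, "stress", acc$stress, orientation)
}

#' Betweenness centrality
#'
#' Sum over pairs (s, t) of the fraction of their shortest paths passing
#' through a node, accumulated by the dependency recursion over the
#' shortest-path predecessor DAG.  Unnormalized by default;
#' \code{normalized = TRUE} divides by the number of ordered (directed) or
#' unordered (undirected) pairs of other nodes.
#'
#' @inheritParams eccentricityCentrality
#' @param normalized divide by the number of node pairs?
#' @return a [CentralityResult-class].
#' @export
betweennessCentrality <- function(graph, normalized = FALSE,
                                  orientation = c("out", "in")) {
    orientation <- match.arg(orientation)
    acc <- .brandesAccumulate(graph, orientation)
    vals <- acc$betweenness
    n <- numNodes(graph)
    if (normalized && n > 2) {
        pairs <- if (graph@directed) (n - 1) * (n - 2)
                 else (n - 1) * (n - 2) / 2
        vals <- vals / pairs
    }
    .nodeResult(graph, if (normalized) "betweennessNormalized" else "betweenness",
                vals, orientation)
}

#' Edge betweenness
#'
#' Per-edge analogue of betweenness: the summed fraction of shortest paths
#' running along each edge (endpoint pairs included).  Self-loops score 0.
#' Values are keyed \code{"from|to"} in the network's edge-table order.
#'
#' @inheritParams eccentricityCentrality
#' @return a [CentralityResult-class] with edge scope.
#' @export
edgeBetweenness <- function(graph, orientation = c("out", "in")) {
    orientation <- match.arg(orientation)
    acc <- .brandesAccumulate(graph, orientation)
    new("CentralityResult", index = "edgeBetweenness", scope = "edge",
        values = stats::setNames(acc$edge, .edgeLabels(graph)),
        mode = .modeTag(graph, orientation))
}

## ---- eigenvector and bridging --------------------------------------------

# dense (weighted) adjacency, self-loops excluded, parallels collapsed to
# the minimum weight
.adjacencyMatrix <- function(graph, topologyOnly = FALSE) {
    adjd <- .adjacency(graph, "out")
    A <- matrix(0, adjd$n, adjd$n, dimnames = list(adjd$ids, adjd$ids))
    for (i in seq_len(adjd$n)) {
        nb <- adjd$adj[[i]]
        if (!is.null(nb))
            A[i, nb$to] <- if (topologyOnly || !adjd$weighted) 1 else nb$w
    }
    A
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the (weighted) adjacency matrix by power
#' iteration: nonnegative entries, Euclidean norm 1.  Directed networks use
#' incoming-link contributions (the right eigenvector of the transposed
#' adjacency), so on a directed graph with no recurrent structure the
#' iteration may converge to a vector supported on sinks; this is reported
#' as-is, not masked.  The iteration runs on the unit-diagonal-shifted
#' matrix (same eigenvectors, strictly dominant leading eigenvalue), so
#' bipartite graphs converge instead of oscillating.  Iteration stops when
#' successive iterates differ by less than \code{tol} in max-norm.
#'
#' @inheritParams eccentricityCentrality
#' @param topologyOnly ignore edge weights and use the 0/1 adjacency?
#' @param tol max-norm convergence tolerance.
#' @param maxIter iteration cap; non-convergence is an error (the graph may
#'   lack the aperiodicity power iteration needs).
#' @return a [CentralityResult-class].
#' @export
eigenvectorCentrality <- function(graph, topologyOnly = FALSE,
                                  tol = 1e-10, maxIter = 10000L) {
    stopifnot(is(graph, "Network"))
    if (numEdges(graph) == 0L)
        stop("eigenvector centrality needs at least one edge")
    A <- .adjacencyMatrix(graph, topologyOnly)
    M <- if (graph@directed) t(A) else A
    n <- nrow(M)
    # unit diagonal shift: identical eigenvectors, but the dominant
    # eigenvalue of M + I is unique in modulus, so the iteration cannot
    # oscillate on bipartite (period-2) structures
    M <- M + diag(n)
    x <- rep(1 / sqrt(n), n)
    for (iter in seq_len(maxIter)) {
        xn <- as.numeric(M %*% x)
        nrm <- sqrt(sum(xn^2))
        if (nrm == 0)
            stop("power iteration collapsed to the zero vector; ",
             "the graph has no structure the principal eigenvector can attach to")
        xn <- xn / nrm
        if (max(abs(xn - x)) < tol) {
            return(.nodeResult(graph, "eigenvector", xn,
                               semantics = if (topologyOnly) "topology" else "distance"))
        }
        x <- xn
    }
    stop("power iteration did not converge after ", maxIter,
         " iterations; the graph may be aperiodicity-deficient ",
         "(e.g. bipartite), so the principal eigenvector is not attracting")
}

#' Bridging centrality
#'
#' Betweenness multiplied by the bridging coefficient
#' psi(v) = (1/d(v)) / sum over neighbors i of 1/d(i), with d the total
#' degree (self-loops excluded).  Nodes of degree 0, or with any degree-0
#' neighbor, get psi = 0.  High values mark nodes that sit on many shortest
#' paths *between* densely connected regions rather than inside them.
#'
#' @inheritParams eccentricityCentrality
#' @return a [CentralityResult-class].
#' @export
bridgingCentrality <- function(graph, orientation = c("out", "in")) {
    orientation <- match.arg(orientation)
    btw <- centralityValues(betweennessCentrality(graph, orientation = orientation))
    deg <- centralityValues(degreeCentrality(graph, mode = "total"))
    ids <- graph@nodes
    e <- graph@edges
    e <- e[e$from != e$to, , drop = FALSE]
    psi <- vapply(seq_along(ids), function(i) {
        v <- ids[i]
        if (deg[[v]] == 0) return(0)
        nbrs <- unique(c(e$to[e$from == v], e$from[e$to == v]))
        dn <- deg[nbrs]
        if (any(dn == 0)) return(0)
        (1 / deg[[v]]) / sum(1 / dn)
    }, numeric(1))
    .nodeResult(graph, "bridging", as.numeric(btw) * psi, orientation)
}

## ---- network-level indices -----------------------------------------------

#' Network diameter and average distance
#'
#' Diameter: the largest finite pairwise shortest-path distance.  Average
#' distance: the mean over finite off-diagonal pairs.  Both respect the
#' directed/weighted mode; unreachable pairs are excluded.
#'
#' @inheritParams eccentricityCentrality
#' @return a [CentralityResult-class] with network scope holding both
#'   scalars (\code{diameter}, \code{averageDistance}).
#' @export
networkIndices <- function(graph, orientation = c("out", "in")) {
    orientation <- match.arg(orientation)
    D <- distances(allPairs(graph, orientation))
    off <- D[row(D) != col(D)]
    off <- off[is.finite(off)]
    vals <- c(diameter = if (length(off)) max(off) else 0,
              averageDistance = if (length(off)) mean(off) else 0)
    new("CentralityResult", index = "network", scope = "network",
        values = vals, mode = .modeTag(graph, orientation))
}

## ---- dispatcher -----------------------------------------------------------

.NODE_INDICES <- c("degree", "eccentricity", "closeness", "radiality",
                   "centroid", "stress", "betweenness", "eigenvector",
                   "bridging")
.ALL_INDICES <- c(.NODE_INDICES, "edgeBetweenness", "network")

#' Compute a set of centrality indices
#'
#' One-call driver over the whole suite.  \code{indices = "all"} computes
#' every node index, edge betweenness and the network-level scalars; for
#' directed graphs the degree entry expands to in/out/total.  Strength-type
#' weights are reciprocal-transformed before any shortest path is computed.
#'
#' @inheritParams eccentricityCentrality
#' @param indices \code{"all"} or a character vector drawn from
#'   \code{degree, eccentricity, closeness, radiality, centroid, stress,
#'   betweenness, eigenvector, bridging, edgeBetweenness, network}.
#' @param weightSemantics \code{"distance"} or \code{"strength"}; see
#'   [transformWeights()].
#' @param includeSelfLoops passed to [degreeCentrality()].
#' @param rawEccentricity passed to [eccentricityCentrality()].
#' @param normalizedBetweenness passed to [betweennessCentrality()].
#' @param topologyOnlyEigenvector passed to [eigenvectorCentrality()].
#' @return named list of [CentralityResult-class] objects.
#' @examples
#' res <- computeCentralities(weightedTriangle(), c("closeness", "network"))
#' centralityValues(res$network)[["diameter"]]   # 5
#' @export
computeCentralities <- function(graph, indices = "all",
                                orientation = c("out", "in"),
                                weightSemantics = c("distance", "strength"),
                                includeSelfLoops = FALSE,
                                rawEccentricity = FALSE,
                                normalizedBetweenness = FALSE,
                                topologyOnlyEigenvector = FALSE) {
    stopifnot(is(graph, "Network"))
    orientation <- match.arg(orientation)
    weightSemantics <- match.arg(weightSemantics)
    if (identical(indices, "all")) indices <- .ALL_INDICES
    bad <- setdiff(indices, .ALL_INDICES)
    if (length(bad))
        .usageStop("unknown index name(s): %s; valid names are: %s",
                   paste(bad, collapse = ", "),
                   paste(.ALL_INDICES, collapse = ", "))
    g <- if (isWeighted(graph) && weightSemantics == "strength")
        transformWeights(graph, "strength") else graph
    out <- list()
    for (idx in indices) {
        res <- switch(idx,
            degree = {
                if (g@directed) {
                    out$inDegree <- degreeCentrality(g, "in", includeSelfLoops)
                    out$outDegree <- degreeCentrality(g, "out", includeSelfLoops)
                }
                degreeCentrality(g, "total", includeSelfLoops)
            },
            eccentricity = eccentricityCentrality(g, rawEccentricity, orientation),
            closeness = closenessCentrality(g, orientation),
            radiality = radialityCentrality(g, orientation),
            centroid = centroidValue(g, orientation),
            stress = stressCentrality(g, orientation),
            betweenness = betweennessCentrality(g, normalizedBetweenness, orientation),
            eigenvector = if (numEdges(g) > 0L)
                eigenvectorCentrality(g, topologyOnlyEigenvector) else NULL,
            bridging = bridgingCentrality(g, orientation),
            edgeBetweenness = edgeBetweenness(g, orientation),
            network = networkIndices(g, orientation))
        if (!is.null(res)) out[[idx]] <- res
        for (nm in names(out))   # record the requested semantics in the tag
            out[[nm]]@mode$semantics <- weightSemantics
    }
    out
}
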