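# Shortest-path engine: BFS / Dijkstra with shortest-path counting (sigma)
# and predecessor DAGs -- the substrate for every distance-based index.

# Two path costs are considered equal iff |a-b| <= 1e-9 * max(1, |a|, |b|):
# sigma counting on real weights needs an explicit tie rule.
.PATH_TOL <- 1e-9

.costEqual <- function(a, b) {
    is.finite(a) && is.finite(b) &&
        abs(a - b) <= .PATH_TOL * max(1, abs(a), abs(b))
}

#' Reinterpret edge weights as distances or strengths
#'
#' Edge attributes that already measure a distance are used verbatim; for
#' strength-type attributes (e.g. the speed of a reaction) the reciprocal is
#' taken, because a higher speed means the nodes are effectively closer.
#'
#' @param graph a weighted [Network-class] (every edge must carry a weight).
#' @param semantics \code{"distance"} (identity) or \code{"strength"}
#'   (replace every weight w by 1/w).
#' @return the transformed [Network-class].
#' @examples
#' g <- weightedTriangle()
#' edgeTable(transformWeights(g, "strength"))$weight   # 1/2, 1/3, 1/7
#' @export
transformWeights <- function(graph, semantics = c("distance", "strength")) {
    stopifnot(is(graph, "Network"))
    semantics <- match.arg(semantics)
    w <- graph@edges$weight
    if (anyNA(w))
        stop("transformWeights() requires a fully weighted network")
    if (any(w <= 0))
        stop("all edge weights must be strictly positive")
    if (semantics == "strength")
        graph@edges$weight <- 1 / w
    graph
}

# Compact adjacency used by all path computations: self-loops dropped,
# parallel edges collapsed to the minimum weight, undirected edges expanded
# both ways.  orientation = "in" transposes a directed graph so that
# distances are measured along incoming edges.
.adjacency <- function(graph, orientation = "out") {
    ids <- graph@nodes
    n <- length(ids)
    e <- graph@edges
    keep <- e$from != e$to
    eidx <- which(keep)
    fi <- match(e$from[keep], ids)
    ti <- match(e$to[keep], ids)
    weighted <- isWeighted(graph)
    w <- if (weighted) e$weight[keep] else rep(1, length(fi))
    if (!graph@directed) {
        fi2 <- c(fi, ti); ti2 <- c(ti, fi)
        w <- c(w, w); eidx <- c(eidx, eidx)
        fi <- fi2; ti <- ti2
    } else if (orientation == "in") {
        tmp <- fi; fi <- ti; ti <- tmp
    }
    # collapse parallels: keep the lightest representative per (from, to)
    if (length(fi)) {
        key <- (fi - 1) * n + ti
        o <- order(key, w)
        first <- !duplicated(key[o])
        sel <- o[first]
        fi <- fi[sel]; ti <- ti[sel]; w <- w[sel]; eidx <- eidx[sel]
    }
    adj <- vector("list", n)
    if (length(fi)) {
        sp <- split(seq_along(fi), factor(fi, levels = seq_len(n)))
        for (i in seq_len(n)) {
            j <- sp[[i]]
            adj[[i]] <- list(to = ti[j], w = w[j], eidx = eidx[j])
        }
    }
    list(adj = adj, n = n, ids = ids, weighted = weighted,
         directed = graph@directed, orientation = orientation)
}

# Core single-source computation on an .adjacency() structure.
# Returns integer-indexed dist / sigma / preds (list of list(p=, e=)) plus
# the finalization order.  BFS for unweighted graphs, O(n^2) Dijkstra
# otherwise (exact for strictly positive weights).
.spCore <- function(adjd, s) {
    n <- adjd$n
    dist <- rep(Inf, n); dist[s] <- 0
    sigma <- rep(0, n); sigma[s] <- 1
    preds <- rep(list(list(p = integer(), e = integer())), n)
    ord <- integer(0)
    if (!adjd$weighted) {
        queue <- s
        while (length(queue)) {
            u <- queue[1L]; queue <- queue[-1L]
            ord <- c(ord, u)
            nb <- adjd$adj[[u]]
            if (is.null(nb)) next
            for (k in seq_along(nb$to)) {
                v <- nb$to[k]
                if (is.infinite(dist[v])) {
                    dist[v] <- dist[u] + 1
                    queue <- c(queue, v)
                }
                if (dist[v] == dist[u] + 1) {
                    sigma[v] <- sigma[v] + sigma[u]
                    preds[[v]]$p <- c(preds[[v]]$p, u)
                    preds[[v]]$e <- c(preds[[v]]$e, nb$eidx[k])
                }
            }
        }
    } else {
        done <- rep(FALSE, n)
        repeat {
            cand <- which(!done & is.finite(dist))
            if (!length(cand)) break
            u <- cand[which.min(dist[cand])]
            done[u] <- TRUE
            ord <- c(ord, u)
            nb <- adjd$adj[[u]]
            if (is.null(nb)) next
            for (k in seq_along(nb$to)) {
                v <- nb$to[k]
                nd <- dist[u] + nb$w[k]
                if (.costEqual(nd, dist[v])) {
                    sigma[v] <- sigma[v] + sigma[u]
                    preds[[v]]$p <- c(preds[[v]]$p, u)
                    preds[[v]]$e <- c(preds[[v]]$e, nb$eidx[k])
                } else if (nd < dist[v]) {
                    dist[v] <- nd
                    sigma[v] <- sigma[u]
                    preds[[v]] <- list(p = u, e = nb$eidx[k])
                }
            }
        }
    }
    list(s = s, dist = dist, sigma = sigma, preds = preds, ord = ord)
}

# Deterministic accumulation order shared by stress / betweenness / edge
# betweenness: reachable vertices by decreasing distance, ties by node
# index.  Using the same rule for BFS- and Dijkstra-derived summaries makes
# the all-weights-one computation bitwise identical to the unweighted one.
.accumulationOrder <- function(core) {
    reach <- which(is.finite(core$dist))
    reach[order(-core$dist[reach], reach)]
}

#' Single-source shortest paths with path counting
#'
#' Exact distances, counts of distinct shortest paths (sigma) and
#' predecessor sets from one source.  Unweighted networks use breadth-first
#' search; weighted networks use Dijkstra's algorithm (weights must be
#' strictly positive).  Two weighted path costs are merged as ties when they
#' agree within a relative tolerance of 1e-9.
#'
#' @param graph a [Network-class].
#' @param source source node id.
#' @param orientation for directed graphs, measure distances along outgoing
#'   (\code{"out"}, default) or incoming (\code{"in"}) edges.
#' @return a [ShortestPathSummary-class].
#' @examples
#' s <- singleSource(weightedTriangle(), "A")
#' s@dist[["C"]]   # 5: the path through B beats the direct distance-7 edge
#' @export
singleSource <- function(graph, source, orientation = c("out", "in")) {
    stopifnot(is(graph, "Network"))
    orientation <- match.arg(orientation)
    ids <- graph@nodes
    si <- match(source, ids)
    if (is.na(si))
        stop(sprintf("source node '%s' is not in the network", source))
    core <- .spCore(.adjacency(graph, orientation), si)
    preds <- lapply(core$preds, function(pr) ids[pr$p])
    names(preds) <- ids
    new("ShortestPathSummary", source = source,
        dist = stats::setNames(core$dist, ids),
        sigma = stats::setNames(core$sigma, ids),
        preds = preds)
}

setMethod("show", "ShortestPathSummary", function(object) {
    cat(sprintf("ShortestPathSummary from '%s': %d/%d nodes reachable\n",
                object@source, sum(is.finite(object@dist)) - 1L,
                length(object@dist) - 1L))
})

# All single-source cores for one graph/orientation.
.spAll <- function(graph, orientation = "out") {
    adjd <- .adjacency(graph, orientation)
    list(adjd = adjd,
         cores = lapply(seq_len(adjd$n), function(s) .spCore(adjd, s)))
}

#' All-pairs shortest-path distances
#'
#' @param graph a [Network-class].
#' @param orientation see [singleSource()].
#' @return a [DistanceMatrix-class]; entries are \code{Inf} for unreachable
#'   pairs and the matrix is asymmetric for directed graphs.
#' @examples
#' distances(allPairs(weightedTriangle()))["A", "C"]   # 5
#' @export
allPairs <- function(graph, orientation = c("out", "in")) {
    stopifnot(is(graph, "Network"))
    orientation <- match.arg(orientation)
    sp <- .spAll(graph, orientation)
    ids <- sp$adjd$ids
    mat <- do.call(rbind, lapply(sp$cores, `[[`, "dist"))
    dimnames(mat) <- list(ids, ids)
    new("DistanceMatrix", mat = mat,
        mode = list(directed = graph@directed,
                    weighted = sp$adjd$weighted,
                    orientation = orientation))
}

#' Export a distance matrix as TSV
#'
#' Writes the pairwise distances with node ids as the first column;
#' unreachable pairs are written as \code{Inf}.
#'
#' @param dm a [DistanceMatrix-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDistanceMatrix <- function(dm, path) {
    stopifnot(is(dm, "DistanceMatrix"))
    m <- dm@mat
    lines <- c(paste(c("node", colnames(m)), collapse = "\t"),
               vapply(seq_len(nrow(m)), function(i) {
                   paste(c(rownames(m)[i], .fmtNum(m[i, ])), collapse = "\t")
               }, character(1)))
    writeLines(lines, path)
    invisible(path)
}
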