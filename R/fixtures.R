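# Deterministic network generators: canonical benchmark graphs, the
# three-node weighted worked example, and seeded random annotated networks
# emulating oncogene-style inputs (edge table + direction table + measured
# node attributes).

#' The three-node weighted triangle
#'
#' Undirected triangle on nodes A, B, C with distance attributes
#' dist(A,B) = 2, dist(B,C) = 3 and dist(A,C) = 7.  It is the minimal
#' network where weighting flips a shortest path: ignoring weights the
#' distance from A to C is 1 (the direct edge), while under the distance
#' attributes the path through B costs 2 + 3 = 5, beating the direct 7.
#'
#' @return an undirected weighted [Network-class].
#' @examples
#' distances(allPairs(weightedTriangle()))["A", "C"]   # 5
#' @export
weightedTriangle <- function() {
    Network(c("A", "B", "C"),
            data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                       weight = c(2, 3, 7)),
            directed = FALSE, name = "weighted-triangle")
}

#' Canonical benchmark graphs
#'
#' Labelled path, cycle, star (node 1 is the center) or complete graph on
#' \code{n} nodes, unweighted and undirected.
#'
#' @param name one of \code{"path"}, \code{"cycle"}, \code{"star"},
#'   \code{"complete"}.
#' @param n number of nodes (>= 1; cycles need n >= 3).
#' @return a [Network-class] with nodes \code{N1..Nn}.
#' @examples
#' centralityValues(degreeCentrality(canonicalGraph("cycle", 4)))
#' @export
canonicalGraph <- function(name = c("path", "cycle", "star", "complete"), n) {
    name <- match.arg(name)
    n <- as.integer(n)
    if (n < 1L) stop("n must be >= 1")
    ids <- paste0("N", seq_len(n))
    e <- switch(name,
        path = if (n > 1L)
            data.frame(from = ids[-n], to = ids[-1L]) else NULL,
        cycle = {
            if (n < 3L) stop("a cycle needs n >= 3")
            data.frame(from = ids, to = ids[c(seq_len(n)[-1L], 1L)])
        },
        star = if (n > 1L)
            data.frame(from = rep(ids[1L], n - 1L), to = ids[-1L]) else NULL,
        complete = if (n > 1L) {
            pr <- utils::combn(ids, 2L)
            data.frame(from = pr[1L, ], to = pr[2L, ])
        } else NULL)
    Network(ids, e, directed = FALSE, name = sprintf("%s-%d", name, n))
}

#' Seeded random annotated network
#'
#' Generates a random graph -- Erdos-Renyi with edge probability \code{p},
#' or preferential attachment adding \code{m} edges per incoming node --
#' together with a node attribute table of normally distributed
#' \code{expression} and \code{phosphorylation} columns, emulating a
#' signalling-network analysis input.  Optionally each edge receives a
#' random direction and/or a log-normal positive distance weight.  All
#' draws come from R's generator seeded with \code{seed}, so a given spec
#' always reproduces the same network and, via \code{dir}, byte-identical
#' files.
#'
#' Defaults emulate a mid-size interaction subnetwork: log2-scale
#' expression around 8 +/- 2, phosphorylation log-ratios around 0 +/- 1,
#' and log-normal edge distances (meanlog 0, sdlog 0.5) concentrated near 1
#' with a heavy right tail.
#'
#' @param n number of nodes (>= 2).
#' @param p Erdos-Renyi edge probability in [0, 1].
#' @param model \code{"er"} or \code{"pa"} (preferential attachment).
#' @param m edges added per node for \code{model = "pa"}.
#' @param directed assign a random direction to every edge?
#' @param weighted attach log-normal distance weights?
#' @param seed integer seed; required, every draw depends on it.
#' @param exprMean,exprSD,phosMean,phosSD attribute distribution parameters.
#' @param weightMeanlog,weightSDlog log-normal weight parameters.
#' @param dir if non-NULL, a directory to write \code{<prefix>_edges.tsv},
#'   \code{<prefix>_attributes.tsv} and (when directed)
#'   \code{<prefix>_edge_directions.tsv} into.
#' @param prefix file-name prefix used with \code{dir}.
#' @return list with elements \code{graph} ([Network-class]),
#'   \code{attributes} ([AttributeTable-class]) and \code{files} (paths
#'   written, or \code{NULL}).
#' @examples
#' net <- randomAnnotated(n = 20, p = 0.15, seed = 7)
#' numEdges(net$graph)
#' @export
randomAnnotated <- function(n, p = 0.1, model = c("er", "pa"), m = 2L,
                            directed = FALSE, weighted = FALSE, seed,
                            exprMean = 8, exprSD = 2,
                            phosMean = 0, phosSD = 1,
                            weightMeanlog = 0, weightSDlog = 0.5,
                            dir = NULL, prefix = "network") {
    model <- match.arg(model)
    n <- as.integer(n)
    if (n < 2L) stop("n must be >= 2")
    if (model == "er" && (p < 0 || p > 1)) stop("p must lie in [0, 1]")
    if (missing(seed)) stop("'seed' is required: fixtures must be reproducible")
    set.seed(as.integer(seed))
    ids <- paste0("N", seq_len(n))
    if (model == "er") {
        pr <- utils::combn(n, 2L)
        take <- stats::runif(ncol(pr)) < p
        from <- ids[pr[1L, take]]
        to <- ids[pr[2L, take]]
    } else {
        m <- max(1L, as.integer(m))
        from <- character(0); to <- character(0)
        degw <- rep(1, n)   # +1 smoothing so early nodes stay reachable
        for (v in 2:n) {
            k <- min(m, v - 1L)
            tgt <- sample.int(v - 1L, k, prob = degw[seq_len(v - 1L)])
            from <- c(from, rep(ids[v], k))
            to <- c(to, ids[tgt])
            degw[tgt] <- degw[tgt] + 1
            degw[v] <- degw[v] + k
        }
    }
    if (directed && length(from)) {
        flip <- stats::runif(length(from)) < 0.5
        tmp <- from[flip]; from[flip] <- to[flip]; to[flip] <- tmp
    }
    w <- if (weighted && length(from))
        stats::rlnorm(length(from), weightMeanlog, weightSDlog) else NA_real_
    edges <- if (length(from))
        data.frame(from = from, to = to, weight = w,
                   stringsAsFactors = FALSE) else NULL
    graph <- Network(ids, edges, directed = directed,
                     name = sprintf("%s-%d-seed%d", model, n, as.integer(seed)))
    attrs <- AttributeTable(
        data.frame(expression = stats::rnorm(n, exprMean, exprSD),
                   phosphorylation = stats::rnorm(n, phosMean, phosSD)),
        ids = ids)
    files <- NULL
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        ef <- file.path(dir, paste0(prefix, "_edges.tsv"))
        af <- file.path(dir, paste0(prefix, "_attributes.tsv"))
        writeEdgeList(graph, ef)
        writeAttributes(attrs, af)
        files <- c(edges = ef, attributes = af)
        if (directed) {
            df <- file.path(dir, paste0(prefix, "_edge_directions.tsv"))
            e <- edgeTable(graph)
            writeLines(c("source\ttarget",
                         paste(e$from, e$to, sep = "\t")), df)
            files <- c(files, directions = df)
        }
    }
    list(graph = graph, attributes = attrs, files = files)
}
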