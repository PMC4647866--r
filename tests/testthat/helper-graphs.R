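# seeded random graphs for property-style tests, built directly from the
# constructor (not via the fixture generators, to keep the two independent)

randomTestGraph <- function(n, p = 0.4, directed = FALSE, weighted = FALSE,
                            seed, integerWeights = FALSE) {
    set.seed(seed)
    ids <- paste0("v", seq_len(n))
    pr <- t(utils::combn(n, 2L))
    take <- stats::runif(nrow(pr)) < p
    from <- ids[pr[take, 1L]]
    to <- ids[pr[take, 2L]]
    if (directed && length(from)) {
        flip <- stats::runif(length(from)) < 0.5
        tmp <- from[flip]; from[flip] <- to[flip]; to[flip] <- tmp
        # add some antiparallel arcs so directed structure is real
        anti <- stats::runif(length(from)) < 0.3
        newFrom <- c(from, to[anti]); newTo <- c(to, from[anti])
        from <- newFrom; to <- newTo
    }
    w <- NA_real_
    if (weighted && length(from)) {
        w <- if (integerWeights) sample(1:9, length(from), replace = TRUE)
             else stats::runif(length(from), 0.5, 3)
    }
    edges <- if (length(from))
        data.frame(from = from, to = to, weight = w,
                   stringsAsFactors = FALSE) else NULL
    Network(ids, edges, directed = directed)
}

# relabel the nodes of a graph by a permutation map (named character vector)
relabelGraph <- function(g, map) {
    e <- edgeTable(g)
    if (nrow(e)) {
        e$from <- unname(map[e$from])
        e$to <- unname(map[e$to])
    }
    Network(unname(map[nodeIds(g)]), if (nrow(e)) e else NULL,
            directed = isDirected(g), name = networkName(g))
}

# scale all weights by a positive constant
scaleWeights <- function(g, c) {
    e <- edgeTable(g)
    e$weight <- e$weight * c
    Network(nodeIds(g), e, directed = isDirected(g), name = networkName(g))
}

# weighted copy with every weight set to 1 (degenerate-mode checks)
unitWeights <- function(g) {
    e <- edgeTable(g)
    if (nrow(e)) e$weight <- 1
    Network(nodeIds(g), if (nrow(e)) e else NULL, directed = isDirected(g),
            name = networkName(g))
}

# assert that two graphs (typically unweighted vs unit-weighted copies)
# produce identical results for the entire index suite; the eigenvector is
# compared separately because on directed graphs without recurrent
# structure it legitimately reports non-convergence -- in which case both
# modes must report it identically
expectSameSuite <- function(gA, gB, label = "") {
    idx <- c("degree", "eccentricity", "closeness", "radiality", "centroid",
             "stress", "betweenness", "bridging", "edgeBetweenness",
             "network")
    resA <- computeCentralities(gA, idx)
    resB <- computeCentralities(gB, idx)
    testthat::expect_setequal(names(resA), names(resB))
    for (nm in names(resA))
        testthat::expect_identical(centralityValues(resA[[nm]]),
                                   centralityValues(resB[[nm]]),
                                   label = paste(nm, label))
    evA <- tryCatch(eigenvectorCentrality(gA), error = identity)
    evB <- tryCatch(eigenvectorCentrality(gB), error = identity)
    if (inherits(evA, "error") || inherits(evB, "error")) {
        testthat::expect_identical(conditionMessage(evA), conditionMessage(evB),
                                   label = paste("eigenvector error", label))
    } else {
        testthat::expect_identical(centralityValues(evA),
                                   centralityValues(evB),
                                   label = paste("eigenvector", label))
    }
}
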