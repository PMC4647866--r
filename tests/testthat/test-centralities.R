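test_that("degree handles stars, direction and isolated nodes", {
    s5 <- canonicalGraph("star", 5)
    d <- centralityValues(degreeCentrality(s5))
    expect_equal(d[["N1"]], 4)
    expect_equal(unname(d[-1]), rep(1, 4))

    dg <- Network(c("A", "B", "C"),
                  data.frame(from = "A", to = "B"), directed = TRUE)
    expect_equal(centralityValues(degreeCentrality(dg, "out"))[["A"]], 1)
    expect_equal(centralityValues(degreeCentrality(dg, "in"))[["A"]], 0)
    expect_equal(centralityValues(degreeCentrality(dg, "total"))[["C"]], 0)

    loop <- Network("A", data.frame(from = "A", to = "A"))
    expect_equal(centralityValues(degreeCentrality(loop))[["A"]], 0)
    expect_equal(centralityValues(
        degreeCentrality(loop, includeSelfLoops = TRUE))[["A"]], 2)
})

test_that("hand-derived values: eccentricity, closeness, radiality, centroid", {
    p3 <- canonicalGraph("path", 3)
    ecc <- centralityValues(eccentricityCentrality(p3))
    expect_equal(unname(ecc), c(1/2, 1, 1/2))
    expect_equal(unname(centralityValues(
        eccentricityCentrality(p3, raw = TRUE))), c(2, 1, 2))

    c4 <- canonicalGraph("cycle", 4)
    expect_equal(unname(centralityValues(eccentricityCentrality(c4))),
                 rep(1/2, 4))
    k3 <- canonicalGraph("complete", 3)
    expect_equal(unname(centralityValues(eccentricityCentrality(k3))),
                 rep(1, 3))
    expect_equal(unname(centralityValues(closenessCentrality(k3))),
                 rep(1/2, 3))
    expect_equal(unname(centralityValues(radialityCentrality(k3))),
                 rep(1, 3))

    s5 <- canonicalGraph("star", 5)
    expect_equal(centralityValues(closenessCentrality(s5))[["N1"]], 1/4)
    expect_equal(centralityValues(radialityCentrality(s5))[["N1"]], 2)
    cen <- centralityValues(centroidValue(s5))
    expect_equal(cen[["N1"]], 3)
    expect_equal(unname(cen[-1]), rep(-3, 4))

    # K2: no third node, centroid 0 for both
    expect_equal(unname(centralityValues(centroidValue(canonicalGraph("path", 2)))),
                 c(0, 0))

    # weighted triangle: closeness(A) = 1/(2+5)
    expect_equal(centralityValues(closenessCentrality(weightedTriangle()))[["A"]],
                 1/7)
})

test_that("stress and betweenness on the minimal fixtures", {
    p3 <- canonicalGraph("path", 3)
    expect_equal(unname(centralityValues(stressCentrality(p3))), c(0, 1, 0))
    expect_equal(unname(centralityValues(betweennessCentrality(p3))),
                 c(0, 1, 0))

    s5 <- canonicalGraph("star", 5)
    expect_equal(centralityValues(betweennessCentrality(s5))[["N1"]], 6)
    expect_equal(centralityValues(stressCentrality(s5))[["N1"]], 6)

    # 4-cycle: each node transits one of the two equal shortest paths
    # for exactly one opposite pair
    c4 <- canonicalGraph("cycle", 4)
    expect_equal(unname(centralityValues(betweennessCentrality(c4))),
                 rep(1/2, 4))
    expect_equal(unname(centralityValues(stressCentrality(c4))), rep(1, 4))

    # direction sensitivity: A->B->C transits B, reversing the first arc kills it
    dg <- Network(c("A", "B", "C"),
                  data.frame(from = c("A", "B"), to = c("B", "C")),
                  directed = TRUE)
    expect_equal(centralityValues(stressCentrality(dg))[["B"]], 1)
    dg2 <- Network(c("A", "B", "C"),
                   data.frame(from = c("B", "B"), to = c("A", "C")),
                   directed = TRUE)
    expect_equal(centralityValues(stressCentrality(dg2))[["B"]], 0)
})

test_that("normalized betweenness divides by the pair count", {
    s5 <- canonicalGraph("star", 5)
    expect_equal(centralityValues(
        betweennessCentrality(s5, normalized = TRUE))[["N1"]], 1)
})

test_that("edge betweenness matches hand counts and the path-length identity", {
    p3 <- canonicalGraph("path", 3)
    eb <- centralityValues(edgeBetweenness(p3))
    expect_equal(unname(eb), c(2, 2))

    s5 <- canonicalGraph("star", 5)
    expect_equal(unname(centralityValues(edgeBetweenness(s5))), rep(4, 4))

    # sum over edges = sum over connected pairs of dist(s,t)
    # (unweighted graphs: a shortest path of length L spans L edge-units)
    for (seed in 1:6) {
        g <- randomTestGraph(9, 0.35, directed = seed %% 2 == 0, seed = seed)
        eb <- sum(centralityValues(edgeBetweenness(g)))
        D <- distances(allPairs(g))
        off <- D[row(D) != col(D)]
        pairSum <- sum(off[is.finite(off)])
        if (!isDirected(g)) pairSum <- pairSum / 2
        expect_equal(eb, pairSum, tolerance = 1e-9)
    }
})

test_that("eigenvector centrality matches dense eigendecomposition", {
    # K2: symmetric pair
    expect_equal(unname(centralityValues(
        eigenvectorCentrality(canonicalGraph("path", 2)))),
        rep(sqrt(2) / 2, 2))
    # connected regular graphs: uniform unit vector
    for (g in list(canonicalGraph("cycle", 5), canonicalGraph("complete", 6))) {
        n <- numNodes(g)
        expect_equal(unname(centralityValues(eigenvectorCentrality(g))),
                     rep(1 / sqrt(n), n), tolerance = 1e-8)
    }
    # random symmetric graphs vs full-spectrum solver
    for (seed in 1:6) {
        g <- randomTestGraph(10, 0.5, weighted = seed %% 2 == 0, seed = seed)
        if (numEdges(g) == 0L) next
        A <- matrix(0, 10, 10, dimnames = list(nodeIds(g), nodeIds(g)))
        e <- edgeTable(g)
        w <- if (isWeighted(g)) e$weight else rep(1, nrow(e))
        for (i in seq_len(nrow(e))) {
            A[e$from[i], e$to[i]] <- w[i]
            A[e$to[i], e$from[i]] <- w[i]
        }
        ref <- eigen(A, symmetric = TRUE)$vectors[, 1]
        ref <- abs(ref)   # principal vector is sign-ambiguous, entries nonneg
        got <- centralityValues(eigenvectorCentrality(g))
        expect_equal(unname(got), unname(ref), tolerance = 1e-6)
    }
    expect_error(eigenvectorCentrality(Network(c("A", "B"))), "at least one edge")
})

test_that("topology-only eigenvector ignores the weights", {
    g <- weightedTriangle()
    topo <- centralityValues(eigenvectorCentrality(g, topologyOnly = TRUE))
    expect_equal(unname(topo), rep(1 / sqrt(3), 3), tolerance = 1e-8)
    wtd <- centralityValues(eigenvectorCentrality(g))
    expect_gt(max(abs(wtd - topo)), 1e-3)
})

test_that("bridging centrality multiplies betweenness by the bridging coefficient", {
    p3 <- canonicalGraph("path", 3)
    b <- centralityValues(bridgingCentrality(p3))
    expect_equal(b[["N2"]], 0.25)   # btw 1 x (1/2)/(1+1)
    s5 <- canonicalGraph("star", 5)
    expect_equal(centralityValues(bridgingCentrality(s5))[["N1"]], 3/8)
    iso <- Network(c("A", "B", "C"), data.frame(from = "A", to = "B"))
    expect_equal(centralityValues(bridgingCentrality(iso))[["C"]], 0)
})

test_that("network indices: diameter and average distance", {
    k3 <- canonicalGraph("complete", 3)
    v <- centralityValues(networkIndices(k3))
    expect_equal(unname(v), c(1, 1))
    p3 <- canonicalGraph("path", 3)
    v <- centralityValues(networkIndices(p3))
    expect_equal(v[["diameter"]], 2)
    expect_equal(v[["averageDistance"]], 4/3)
    expect_equal(centralityValues(networkIndices(weightedTriangle()))[["diameter"]],
                 5)
})

test_that("every path-based index equals exhaustive enumeration on small graphs", {
    nGraphs <- 24   # the full-size sweep lives in the acceptance suite
    for (seed in seq_len(nGraphs)) {
        directed <- seed %% 2 == 0
        weighted <- seed %% 4 %in% c(0, 1)
        g <- randomTestGraph(sample(4:7, 1), 0.45, directed, weighted,
                             seed = 1000 + seed)
        oraclePaths <- oraclePathCentralities(g)
        oracleDist <- oracleFromDistances(oraclePaths$dist)
        expect_equal(centralityValues(stressCentrality(g)),
                     oraclePaths$stress, tolerance = 1e-9)
        expect_equal(centralityValues(betweennessCentrality(g)),
                     oraclePaths$betweenness, tolerance = 1e-9)
        expect_equal(centralityValues(edgeBetweenness(g)),
                     oraclePaths$edgeBetweenness, tolerance = 1e-9)
        expect_equal(centralityValues(closenessCentrality(g)),
                     oracleDist$closeness, tolerance = 1e-9)
        expect_equal(centralityValues(eccentricityCentrality(g)),
                     oracleDist$eccentricity, tolerance = 1e-9)
        expect_equal(centralityValues(radialityCentrality(g)),
                     oracleDist$radiality, tolerance = 1e-9)
        expect_equal(centralityValues(centroidValue(g)),
                     oracleDist$centroid, tolerance = 1e-9)
    }
})

test_that("cross-check against igraph on a mid-size random graph", {
    library(igraph)
    g <- randomTestGraph(20, 0.2, weighted = TRUE, seed = 202)
    e <- edgeTable(g)
    ig <- igraph::graph_from_data_frame(e, directed = FALSE,
                                        vertices = nodeIds(g))
    expect_equal(unname(centralityValues(betweennessCentrality(g))),
                 unname(igraph::betweenness(ig, weights = e$weight)),
                 tolerance = 1e-8)
    clo <- igraph::closeness(ig, weights = e$weight, mode = "all")
    ours <- centralityValues(closenessCentrality(g))
    # igraph closeness is 1/sum(dist) over reachable nodes too
    comparable <- !is.na(clo)
    expect_equal(unname(ours[comparable]), unname(clo[comparable]),
                 tolerance = 1e-8)
})

test_that("node indices are constant on vertex-transitive graphs", {
    idx <- list(degreeCentrality, eccentricityCentrality, closenessCentrality,
                radialityCentrality, centroidValue, stressCentrality,
                betweennessCentrality, bridgingCentrality)
    for (g in list(canonicalGraph("cycle", 6), canonicalGraph("complete", 5))) {
        for (f in idx) {
            v <- centralityValues(f(g))
            expect_lt(diff(range(v)), 1e-12)
        }
        ev <- centralityValues(eigenvectorCentrality(g))
        expect_lt(diff(range(ev)), 1e-8)
    }
})

test_that("relabelling nodes permutes every result identically", {
    g <- randomTestGraph(9, 0.4, weighted = TRUE, seed = 77)
    map <- stats::setNames(paste0("x", rev(seq_len(9))), nodeIds(g))
    g2 <- relabelGraph(g, map)
    for (f in list(degreeCentrality, closenessCentrality, stressCentrality,
                   betweennessCentrality, centroidValue, bridgingCentrality)) {
        v1 <- centralityValues(f(g))
        v2 <- centralityValues(f(g2))
        expect_equal(unname(v2[map[names(v1)]]), unname(v1), tolerance = 1e-12)
    }
})

test_that("stress dominates betweenness everywhere", {
    for (seed in 1:8) {
        g <- randomTestGraph(10, 0.35, directed = seed %% 2 == 0,
                             weighted = seed %% 3 == 0, seed = seed + 50)
        s <- centralityValues(stressCentrality(g))
        b <- centralityValues(betweennessCentrality(g))
        expect_true(all(s - b >= -1e-9))
    }
})

test_that("computeCentralities drives the suite and validates index names", {
    g <- weightedTriangle()
    res <- computeCentralities(g)
    expect_true(all(c("degree", "closeness", "betweenness", "edgeBetweenness",
                      "network") %in% names(res)))
    expect_equal(centralityValues(res$network)[["diameter"]], 5)
    expect_identical(resultMode(res$closeness)$weighted, TRUE)

    err <- tryCatch(computeCentralities(g, "nonsense"), condition = identity)
    expect_s3_class(err, "usageError")
    expect_match(conditionMessage(err), "closeness")   # lists valid names

    # strength semantics reciprocal-transforms before computing: under
    # reciprocal weights the longest shortest path is A-C-B (1/7 + 1/3),
    # since A-B now routes through the strong A-C edge
    res2 <- computeCentralities(g, "network", weightSemantics = "strength")
    expect_equal(centralityValues(res2$network)[["diameter"]], 1/7 + 1/3)

    dres <- computeCentralities(
        Network(c("A", "B"), data.frame(from = "A", to = "B"), directed = TRUE),
        "degree")
    expect_true(all(c("degree", "inDegree", "outDegree") %in% names(dres)))
})

test_that("weighted computation with unit weights reproduces the unweighted result", {
    for (seed in 1:10) {
        g <- randomTestGraph(9, 0.4, directed = seed %% 2 == 0, seed = seed + 400)
        if (numEdges(g) == 0L) next
        expectSameSuite(g, unitWeights(g), label = sprintf("seed %d", seed))
    }
})

test_that("directed orientation flag transposes the distance view", {
    dg <- Network(c("A", "B", "C"),
                  data.frame(from = c("A", "B"), to = c("B", "C")),
                  directed = TRUE)
    out <- centralityValues(closenessCentrality(dg, orientation = "out"))
    inn <- centralityValues(closenessCentrality(dg, orientation = "in"))
    expect_equal(out[["A"]], 1/3)   # reaches B at 1, C at 2
    expect_equal(out[["C"]], 0)
    expect_equal(inn[["C"]], 1/3)
    expect_equal(inn[["A"]], 0)
})
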