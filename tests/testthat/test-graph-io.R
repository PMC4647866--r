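test_that("SIF parsing handles single edges, multi-target lines and singletons", {
    f <- withr::local_tempfile(fileext = ".sif")

    writeLines("A\tpp\tB", f)
    g <- readSIF(f)
    expect_setequal(nodeIds(g), c("A", "B"))
    expect_equal(numEdges(g), 1L)
    expect_false(isDirected(g))
    expect_false(isWeighted(g))

    writeLines("A\tpp\tB\tC", f)
    g <- readSIF(f)
    e <- edgeTable(g)
    expect_equal(nrow(e), 2L)
    expect_setequal(paste(e$from, e$to), c("A B", "A C"))

    writeLines("X", f)
    g <- readSIF(f)
    expect_equal(nodeIds(g), "X")
    expect_equal(numEdges(g), 0L)

    # duplicate edges collapse; blank lines are skipped
    writeLines(c("A\tpp\tB", "", "B\tpp\tA", "A\tpp\tB"), f)
    expect_equal(numEdges(readSIF(f)), 1L)
})

test_that("malformed SIF lines fail with the offending line number", {
    f <- withr::local_tempfile(fileext = ".sif")
    writeLines(c("A\tpp\tB", "A\tpp"), f)
    expect_error(readSIF(f), "line 2")
})

test_that("edge-list reader reproduces the weighted triangle and validates weights", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("source\ttarget\tdist", "A\tB\t2", "B\tC\t3", "A\tC\t7"), f)
    g <- readEdgeList(f, weightColumn = "dist")
    expect_setequal(nodeIds(g), c("A", "B", "C"))
    expect_true(isWeighted(g))
    expect_equal(sort(edgeTable(g)$weight), c(2, 3, 7))

    # same rows without naming the weight column: unweighted triangle
    g0 <- readEdgeList(f)
    expect_false(isWeighted(g0))
    expect_equal(numEdges(g0), 3L)

    writeLines(c("source\ttarget\tdist", "A\tB\t2", "B\tC\t-1", "C\tD\tx"), f)
    expect_error(readEdgeList(f, weightColumn = "dist"), "row\\(s\\) 2, 3")

    writeLines(c("source\ttarget", "A\tB"), f)
    expect_error(readEdgeList(f, weightColumn = "dist"), "not found")
})

test_that("directed edge lists keep antiparallel edges distinct", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("source\ttarget", "A\tB", "B\tA"), f)
    g <- readEdgeList(f, directed = TRUE)
    expect_true(isDirected(g))
    expect_equal(numEdges(g), 2L)
    # undirected reading collapses the same pair
    expect_equal(numEdges(readEdgeList(f, directed = FALSE)), 1L)
})

test_that("duplicate edges with conflicting weights are rejected, not last-wins", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("source\ttarget\tdist", "A\tB\t2", "B\tA\t5"), f)
    expect_error(readEdgeList(f, weightColumn = "dist"), "conflicting")
    # identical duplicates are fine and collapse
    writeLines(c("source\ttarget\tdist", "A\tB\t2", "B\tA\t2"), f)
    expect_equal(numEdges(readEdgeList(f, weightColumn = "dist")), 1L)
})

test_that("GraphML round trip preserves graph and attached centralities", {
    f <- withr::local_tempfile(fileext = ".graphml")
    g <- weightedTriangle()
    res <- computeCentralities(g, c("betweenness", "closeness"))
    writeGraphML(g, f, results = res)
    back <- readGraphML(f)
    expect_equal(nodeIds(back$graph), nodeIds(g))
    expect_equal(edgeTable(back$graph), edgeTable(g))
    expect_equal(isDirected(back$graph), isDirected(g))
    expect_setequal(attributeNames(back$nodeAttributes),
                    c("betweenness", "closeness"))
    expect_equal(attributeValues(back$nodeAttributes, "closeness"),
                 centralityValues(res$closeness))

    # directedness survives
    dg <- Network(c("A", "B"), data.frame(from = "A", to = "B"),
                  directed = TRUE)
    writeGraphML(dg, f)
    expect_true(isDirected(readGraphML(f)$graph))
})

test_that("GraphML referential integrity and schema are checked", {
    f <- withr::local_tempfile(fileext = ".graphml")
    writeLines(c('<?xml version="1.0"?>',
                 '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
                 '<graph id="g" edgedefault="undirected">',
                 '<node id="A"/>',
                 '<edge source="A" target="GHOST"/>',
                 '</graph></graphml>'), f)
    expect_error(readGraphML(f), "GHOST")

    writeLines('<notgraphml/>', f)
    expect_error(readGraphML(f), "not a GraphML")
})

test_that("attribute tables round-trip with missing values kept distinct from zero", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("id\texpr", "A\t1.5"), f)
    at <- readAttributes(f)
    expect_equal(attributeValues(at, "expr"), c(A = 1.5))

    writeLines(c("id\texpr\tphos", "A\t1.5\t", "B\t\t0"), f)
    at <- readAttributes(f)
    expect_true(is.na(attributeValues(at, "phos")[["A"]]))
    expect_identical(attributeValues(at, "phos")[["B"]], 0)
    expect_true(is.na(attributeValues(at, "expr")[["B"]]))

    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeAttributes(at, f2)
    back <- readAttributes(f2)
    expect_equal(back@data, at@data)

    writeLines(c("id\texpr", "A\t1", "A\t2"), f)
    expect_error(readAttributes(f), "duplicate")
})

test_that("attribute rows for unknown nodes warn but are retained", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("id\texpr", "A\t1", "Z\t2"), f)
    g <- Network(c("A", "B"), data.frame(from = "A", to = "B"))
    expect_warning(at <- readAttributes(f, graph = g), "Z")
    expect_true("Z" %in% nodeIds(at))
})

test_that("node ids are whitespace-stripped but case-sensitive", {
    f <- withr::local_tempfile(fileext = ".sif")
    writeLines(c("A \tpp\t B", "a\tpp\tB"), f)
    g <- readSIF(f)
    expect_setequal(nodeIds(g), c("A", "B", "a"))
    expect_equal(numEdges(g), 2L)
})

test_that("Network validity enforces endpoints, positive weights and no mixing", {
    expect_error(Network(c("A", "B"),
                         data.frame(from = "A", to = "Z")),
                 "absent")
    expect_error(Network(c("A", "B"),
                         data.frame(from = "A", to = "B", weight = -1)),
                 "positive")
    expect_error(Network(c("A", "B", "C"),
                         data.frame(from = c("A", "B"), to = c("B", "C"),
                                    weight = c(1, NA))),
                 "mix")
    expect_error(Network(character(0)), "at least one node")
})
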