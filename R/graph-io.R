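# Readers and writers: SIF (Cytoscape dialect), edge-list TSV, GraphML,
# attribute TSV.  Node identity is the raw string id, case-sensitive,
# whitespace-stripped at field boundaries.  All writers end with a trailing
# newline, use tabs and '.' decimals.

# readers reject duplicate edges whose weights disagree: weights change
# shortest paths, so last-wins would be unsafe
.checkConflictingDuplicates <- function(edges, directed) {
    if (!nrow(edges) || all(is.na(edges$weight))) return(invisible())
    a <- edges$from; b <- edges$to
    if (!directed) {
        lo <- pmin(a, b); hi <- pmax(a, b)
        a <- lo; b <- hi
    }
    key <- paste(a, b, sep = "\r")
    spl <- split(edges$weight, key)
    bad <- names(spl)[vapply(spl, function(w) length(unique(w)) > 1L, logical(1))]
    if (length(bad))
        stop("duplicate edges with conflicting weights: ",
             paste(gsub("\r", "-", bad), collapse = ", "))
    invisible()
}

# drop exact duplicate edges (same endpoints, same weight; unordered when
# undirected)
.dedupeEdges <- function(edges, directed) {
    if (!nrow(edges)) return(edges)
    a <- edges$from; b <- edges$to
    if (!directed) {
        lo <- pmin(a, b); hi <- pmax(a, b)
        a <- lo; b <- hi
    }
    key <- paste(a, b, edges$weight, sep = "\r")
    out <- edges[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read a SIF interaction file
#'
#' Cytoscape's simple interaction format: tab-delimited lines
#' \code{source relation target [target2 ...]}; a line holding a single
#' field declares an isolated node.  The result is undirected and
#' unweighted; duplicate edges are collapsed.
#'
#' @param path file path.
#' @return a [Network-class].
#' @export
readSIF <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    nodes <- character(0)
    from <- character(0); to <- character(0)
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (!nzchar(trimws(ln))) next
        fields <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
        if (length(fields) == 1L) {
            nodes <- c(nodes, fields)
            next
        }
        if (length(fields) < 3L || any(!nzchar(fields)))
            stop(sprintf("malformed SIF line %d: expected 'source<TAB>relation<TAB>target...', got %d usable field(s)",
                         i, sum(nzchar(fields))))
        src <- fields[1L]
        tgts <- fields[-(1:2)]
        nodes <- c(nodes, src, tgts)
        from <- c(from, rep(src, length(tgts)))
        to <- c(to, tgts)
    }
    if (!length(nodes)) stop("empty SIF file: ", path)
    edges <- .dedupeEdges(
        data.frame(from = from, to = to,
                   weight = rep(NA_real_, length(from)),
                   stringsAsFactors = FALSE),
        directed = FALSE)
    Network(unique(nodes), edges, directed = FALSE,
            name = sub("\\.[^.]*$", "", basename(path)))
}

#' Read an edge-list TSV
#'
#' Tab-separated table with a header; \code{sourceColumn} and
#' \code{targetColumn} name the endpoints, and \code{weightColumn}, when
#' given, a strictly positive numeric distance attribute.  Exact duplicate
#' edges are collapsed; duplicates with conflicting weights are an error.
#'
#' @param path file path.
#' @param directed interpret rows as ordered pairs?
#' @param weightColumn optional name of the weight column.
#' @param sourceColumn,targetColumn endpoint column names.
#' @return a [Network-class].
#' @export
readEdgeList <- function(path, directed = FALSE, weightColumn = NULL,
                         sourceColumn = "source", targetColumn = "target") {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE, comment.char = "#")
    for (col in c(sourceColumn, targetColumn, weightColumn))
        if (!col %in% names(tab))
            stop(sprintf("column '%s' not found in %s (has: %s)", col, path,
                         paste(names(tab), collapse = ", ")))
    w <- NA_real_
    if (!is.null(weightColumn)) {
        raw <- tab[[weightColumn]]
        w <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(w) | !is.finite(w) | w <= 0)
        if (length(bad))
            stop(sprintf("non-positive or non-numeric weight in row(s) %s of %s",
                         paste(bad, collapse = ", "), path))
    }
    edges <- data.frame(from = trimws(as.character(tab[[sourceColumn]])),
                        to = trimws(as.character(tab[[targetColumn]])),
                        weight = w, stringsAsFactors = FALSE)
    .checkConflictingDuplicates(edges, directed)
    edges <- .dedupeEdges(edges, directed)
    Network(unique(c(edges$from, edges$to)), edges, directed = directed,
            name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a network as edge-list TSV
#'
#' Columns \code{source}, \code{target} and, for weighted networks,
#' \code{dist}; numbers carry 12 significant digits.
#'
#' @param graph a [Network-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
    stopifnot(is(graph, "Network"))
    e <- graph@edges
    if (isWeighted(graph)) {
        lines <- c("source\ttarget\tdist",
                   paste(e$from, e$to, .fmtNum(e$weight), sep = "\t"))
    } else {
        lines <- c("source\ttarget", paste(e$from, e$to, sep = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
}

## ---- GraphML --------------------------------------------------------------

.GRAPHML_NS <- "http://graphml.graphdrawing.org/xmlns"

#' Write a network as GraphML
#'
#' Open XML interchange readable by Cytoscape and igraph: nodes, edges,
#' directedness, the \code{weight} edge attribute and any node-scope
#' centrality results (one GraphML key per index).  Doubles are serialised
#' with 17 significant digits so a read/write round trip is exact.
#'
#' @param graph a [Network-class].
#' @param path output file.
#' @param results optional named list of node-scope
#'   [CentralityResult-class] objects to attach as node attributes.
#' @return \code{path}, invisibly.
#' @export
writeGraphML <- function(graph, path, results = NULL) {
    stopifnot(is(graph, "Network"))
    esc <- function(x) {
        x <- gsub("&", "&amp;", x, fixed = TRUE)
        x <- gsub("<", "&lt;", x, fixed = TRUE)
        x <- gsub(">", "&gt;", x, fixed = TRUE)
        gsub('"', "&quot;", x, fixed = TRUE)
    }
    num <- function(x) sprintf("%.17g", x)
    lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
               sprintf('<graphml xmlns="%s">', .GRAPHML_NS))
    if (isWeighted(graph))
        lines <- c(lines,
                   '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>')
    resNames <- character(0)
    if (!is.null(results)) {
        if (is(results, "CentralityResult")) results <- list(results)
        results <- Filter(function(r) r@scope == "node", results)
        resNames <- vapply(results, function(r) r@index, character(1))
        names(results) <- resNames
        for (nm in resNames)
            lines <- c(lines, sprintf(
                '  <key id="%s" for="node" attr.name="%s" attr.type="double"/>',
                esc(nm), esc(nm)))
    }
    lines <- c(lines, sprintf('  <graph id="%s" edgedefault="%s">',
                              esc(graph@name),
                              if (graph@directed) "directed" else "undirected"))
    for (v in graph@nodes) {
        if (length(resNames)) {
            data <- vapply(resNames, function(nm)
                sprintf('      <data key="%s">%s</data>', esc(nm),
                        num(results[[nm]]@values[[v]])), character(1))
            lines <- c(lines, sprintf('    <node id="%s">', esc(v)), data,
                       "    </node>")
        } else {
            lines <- c(lines, sprintf('    <node id="%s"/>', esc(v)))
        }
    }
    e <- graph@edges
    for (i in seq_len(nrow(e))) {
        if (isWeighted(graph)) {
            lines <- c(lines,
                       sprintf('    <edge source="%s" target="%s">',
                               esc(e$from[i]), esc(e$to[i])),
                       sprintf('      <data key="weight">%s</data>',
                               num(e$weight[i])),
                       "    </edge>")
        } else {
            lines <- c(lines, sprintf('    <edge source="%s" target="%s"/>',
                                      esc(e$from[i]), esc(e$to[i])))
        }
    }
    lines <- c(lines, "  </graph>", "</graphml>")
    writeLines(lines, path)
    invisible(path)
}

#' Read a GraphML file
#'
#' Parses nodes, edges, directedness (\code{edgedefault}), the
#' \code{weight} edge attribute and any double-typed node attributes.
#'
#' @param path file path.
#' @return list with \code{graph} (a [Network-class]) and
#'   \code{nodeAttributes} (an [AttributeTable-class], or \code{NULL} when
#'   the file carries no node attributes).
#' @export
readGraphML <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    doc <- xml2::read_xml(path)
    if (xml2::xml_name(doc) != "graphml")
        stop("not a GraphML document (root element is '",
             xml2::xml_name(doc), "'): ", path)
    ns <- c(g = .GRAPHML_NS)
    keys <- xml2::xml_find_all(doc, ".//g:key", ns)
    keyFor <- stats::setNames(xml2::xml_attr(keys, "for"),
                              xml2::xml_attr(keys, "id"))
    keyName <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                               xml2::xml_attr(keys, "id"))
    graphNode <- xml2::xml_find_first(doc, ".//g:graph", ns)
    if (inherits(graphNode, "xml_missing"))
        stop("no <graph> element in ", path)
    directed <- identical(xml2::xml_attr(graphNode, "edgedefault"), "directed")
    gname <- xml2::xml_attr(graphNode, "id")
    if (is.na(gname)) gname <- sub("\\.[^.]*$", "", basename(path))
    nodeEls <- xml2::xml_find_all(graphNode, "./g:node", ns)
    ids <- trimws(xml2::xml_attr(nodeEls, "id"))
    nodeAttr <- list()
    for (i in seq_along(nodeEls)) {
        for (d in xml2::xml_find_all(nodeEls[[i]], "./g:data", ns)) {
            k <- xml2::xml_attr(d, "key")
            nm <- if (!is.na(keyName[k])) keyName[[k]] else k
            if (is.null(nodeAttr[[nm]]))
                nodeAttr[[nm]] <- stats::setNames(rep(NA_real_, length(ids)), ids)
            nodeAttr[[nm]][[ids[i]]] <- as.numeric(xml2::xml_text(d))
        }
    }
    edgeEls <- xml2::xml_find_all(graphNode, "./g:edge", ns)
    from <- trimws(xml2::xml_attr(edgeEls, "source"))
    to <- trimws(xml2::xml_attr(edgeEls, "target"))
    missing <- setdiff(c(from, to), ids)
    if (length(missing))
        stop("edge endpoint(s) not declared as nodes: ",
             paste(missing, collapse = ", "))
    w <- rep(NA_real_, length(edgeEls))
    for (i in seq_along(edgeEls)) {
        for (d in xml2::xml_find_all(edgeEls[[i]], "./g:data", ns)) {
            k <- xml2::xml_attr(d, "key")
            nm <- if (!is.na(keyName[k])) keyName[[k]] else k
            if (identical(nm, "weight"))
                w[i] <- as.numeric(xml2::xml_text(d))
        }
    }
    edges <- if (length(from))
        data.frame(from = from, to = to, weight = w,
                   stringsAsFactors = FALSE) else NULL
    graph <- Network(ids, edges, directed = directed, name = gname)
    attrs <- if (length(nodeAttr))
        AttributeTable(as.data.frame(nodeAttr, check.names = FALSE), ids = ids)
    else NULL
    list(graph = graph, nodeAttributes = attrs)
}

## ---- attribute tables -----------------------------------------------------

#' Read a node attribute TSV
#'
#' First column: node id; remaining columns: numeric experimental values.
#' Empty cells become \code{NA} (missing), never 0.  When \code{graph} is
#' supplied, rows whose id is absent from the graph trigger a warning but
#' are retained.
#'
#' @param path file path.
#' @param graph optional [Network-class] to check ids against.
#' @return an [AttributeTable-class].
#' @export
readAttributes <- function(path, graph = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE, comment.char = "#",
                             na.strings = c("", "NA"))
    if (ncol(tab) < 2L)
        stop("attribute table needs a node-id column plus >= 1 value column: ",
             path)
    ids <- trimws(as.character(tab[[1L]]))
    if (anyDuplicated(ids))
        stop("duplicate node id(s) in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    vals <- tab[-1L]
    for (j in seq_along(vals)) vals[[j]] <- as.numeric(vals[[j]])
    if (!is.null(graph)) {
        extra <- setdiff(ids, nodeIds(graph))
        if (length(extra))
            warning("attribute row(s) for node(s) absent from the network ",
                    "(retained): ", paste(extra, collapse = ", "))
    }
    AttributeTable(vals, ids = ids)
}

#' Write a node attribute TSV
#'
#' One row per node, one column per attribute; missing values are written
#' as empty cells.
#'
#' @param attributes an [AttributeTable-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAttributes <- function(attributes, path) {
    stopifnot(is(attributes, "AttributeTable"))
    d <- attributes@data
    body <- vapply(seq_len(nrow(d)), function(i) {
        paste(c(rownames(d)[i], .fmtNum(as.numeric(d[i, ]))), collapse = "\t")
    }, character(1))
    writeLines(c(paste(c("node", colnames(d)), collapse = "\t"), body), path)
    invisible(path)
}

## ---- result writers -------------------------------------------------------

#' Write centrality results as TSV files
#'
#' Node-scope results go to \code{<prefix>.nodes.tsv} (one column per
#' index, computation mode recorded in a header comment), edge-scope
#' results to \code{<prefix>.edges.tsv}, and network scalars to the keyed
#' file \code{<prefix>.network.tsv}.
#'
#' @param results named list of [CentralityResult-class] objects (as from
#'   [computeCentralities()]).
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
writeResults <- function(results, prefix) {
    if (is(results, "CentralityResult")) results <- list(results)
    scopes <- vapply(results, function(r) r@scope, character(1))
    written <- character(0)
    modeComment <- function(r) {
        m <- r@mode
        sprintf("# mode: directed=%s weighted=%s semantics=%s orientation=%s",
                isTRUE(m$directed), isTRUE(m$weighted),
                if (is.null(m$semantics)) "distance" else m$semantics,
                if (is.null(m$orientation)) "out" else m$orientation)
    }
    nodeRes <- results[scopes == "node"]
    if (length(nodeRes)) {
        ids <- names(nodeRes[[1L]]@values)
        cols <- vapply(nodeRes, function(r) r@index, character(1))
        f <- paste0(prefix, ".nodes.tsv")
        body <- vapply(ids, function(v) {
            paste(c(v, vapply(nodeRes, function(r) .fmtNum(r@values[[v]]),
                              character(1))), collapse = "\t")
        }, character(1))
        writeLines(c(modeComment(nodeRes[[1L]]),
                     paste(c("node", cols), collapse = "\t"), body), f)
        written <- c(written, f)
    }
    edgeRes <- results[scopes == "edge"]
    if (length(edgeRes)) {
        f <- paste0(prefix, ".edges.tsv")
        r1 <- edgeRes[[1L]]
        labels <- names(r1@values)
        cols <- vapply(edgeRes, function(r) r@index, character(1))
        body <- vapply(seq_along(labels), function(i) {
            paste(c(sub("\\|", "\t", labels[i]),
                    vapply(edgeRes, function(r) .fmtNum(r@values[[i]]),
                           character(1))), collapse = "\t")
        }, character(1))
        writeLines(c(modeComment(r1),
                     paste(c("source", "target", cols), collapse = "\t"),
                     body), f)
        written <- c(written, f)
    }
    netRes <- results[scopes == "network"]
    if (length(netRes)) {
        f <- paste0(prefix, ".network.tsv")
        lines <- c(modeComment(netRes[[1L]]), "index\tvalue")
        for (r in netRes)
            lines <- c(lines, paste(names(r@values), .fmtNum(r@values),
                                    sep = "\t"))
        writeLines(lines, f)
        written <- c(written, f)
    }
    invisible(written)
}
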