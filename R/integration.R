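# Integration of topology with experiment: the boolean high/low panel over
# centralities and measured node attributes, plus plot-data export.

# gather named numeric vectors for all variables from centrality results
# and/or an AttributeTable
.variableVectors <- function(results = NULL, attributes = NULL) {
    vars <- list()
    if (!is.null(results)) {
        if (is(results, "CentralityResult")) results <- list(results)
        for (r in results) {
            stopifnot(is(r, "CentralityResult"))
            if (r@scope != "node") next
            vars[[r@index]] <- r@values
        }
    }
    if (!is.null(attributes)) {
        stopifnot(is(attributes, "AttributeTable"))
        for (a in attributeNames(attributes))
            vars[[a]] <- attributeValues(attributes, a)
    }
    if (anyDuplicated(names(vars)))
        stop("variable names collide between centralities and attributes: ",
             paste(unique(names(vars)[duplicated(names(vars))]), collapse = ", "))
    vars
}

.resolveThreshold <- function(values, rule) {
    if (rule == "mean") return(mean(values))
    if (rule == "median") return(stats::median(values))
    if (grepl("^value:", rule)) {
        x <- suppressWarnings(as.numeric(sub("^value:", "", rule)))
        if (is.na(x)) .usageStop("unparseable threshold rule '%s'", rule)
        return(x)
    }
    .usageStop("unknown threshold rule '%s'; use mean, median or value:x", rule)
}

#' Boolean high/low classification of nodes
#'
#' For every selected centrality and experimental attribute, a node is
#' called *high* when its value is at or above the per-variable threshold
#' (closed boundary, so a constant variable classifies everything high) and
#' *low* otherwise.  The threshold is resolved per variable over the nodes
#' that have a value; nodes missing a value are unclassified (\code{NA})
#' for that variable only, never dropped from the whole report.
#'
#' @param results a [CentralityResult-class] or list of them (node scope).
#' @param attributes optional [AttributeTable-class] of experimental values.
#' @param rule \code{"mean"}, \code{"median"} or \code{"value:x"} (a fixed
#'   numeric cut at x).
#' @return a [ClassificationReport-class].
#' @examples
#' at <- AttributeTable(data.frame(expr = c(1, 2, 3)), ids = c("A", "B", "C"))
#' rep <- classifyNodes(attributes = at, rule = "mean")
#' queryNodes(rep, "expr:high")   # B and C
#' @export
classifyNodes <- function(results = NULL, attributes = NULL, rule = "mean") {
    vars <- .variableVectors(results, attributes)
    if (!length(vars))
        stop("nothing to classify: supply centrality results and/or attributes")
    ids <- unique(unlist(lapply(vars, names), use.names = FALSE))
    calls <- matrix(NA, length(ids), length(vars),
                    dimnames = list(ids, names(vars)))
    thresholds <- stats::setNames(numeric(length(vars)), names(vars))
    for (v in names(vars)) {
        vals <- vars[[v]]
        ok <- !is.na(vals)
        thr <- .resolveThreshold(vals[ok], rule)
        thresholds[[v]] <- thr
        calls[names(vals)[ok], v] <- vals[ok] >= thr
    }
    new("ClassificationReport", calls = calls, thresholds = thresholds,
        rule = rule)
}

#' Query a classification report by conjunction
#'
#' Evaluates a conjunction of literals such as
#' \code{"betweenness:high AND expression:high"} against the report's
#' boolean columns and returns the matching node ids (sorted).  Only AND is
#' supported, mirroring a boolean result panel; nodes unclassified for any
#' mentioned variable never match.
#'
#' @param report a [ClassificationReport-class].
#' @param expression the conjunction string; each literal is
#'   \code{variable:high} or \code{variable:low}, joined by \code{AND}.
#' @return character vector of node ids.
#' @export
queryNodes <- function(report, expression) {
    stopifnot(is(report, "ClassificationReport"))
    lits <- strsplit(trimws(expression), "\\s+AND\\s+")[[1]]
    if (!length(lits) || any(!nzchar(lits)))
        .usageStop("empty query expression")
    keep <- rep(TRUE, nrow(report@calls))
    for (lit in lits) {
        parts <- strsplit(trimws(lit), ":", fixed = TRUE)[[1]]
        if (length(parts) != 2L || !parts[2] %in% c("high", "low"))
            .usageStop("malformed literal '%s'; expected variable:high or variable:low", lit)
        v <- parts[1]
        if (!v %in% colnames(report@calls))
            .usageStop("unknown variable '%s'; available: %s", v,
                       paste(colnames(report@calls), collapse = ", "))
        col <- report@calls[, v]
        want <- parts[2] == "high"
        keep <- keep & !is.na(col) & (col == want)
    }
    sort(rownames(report@calls)[keep])
}

#' Tabulate two variables for plotting
#'
#' Builds the (node, x, y) table behind a plot-by-centrality scatter: one
#' row per node carrying both variables.  Nodes missing either variable are
#' omitted from the table and reported via \code{message()}.
#'
#' @param results a [CentralityResult-class] or list of them.
#' @param x,y variable names (centrality index or attribute column).
#' @param attributes optional [AttributeTable-class].
#' @param render draw a base-graphics scatter as a side effect?
#' @return data.frame with columns \code{node}, \code{x}, \code{y}.
#' @export
plotData <- function(results = NULL, x, y, attributes = NULL, render = FALSE) {
    vars <- .variableVectors(results, attributes)
    for (v in c(x, y))
        if (!v %in% names(vars))
            stop(sprintf("unknown variable '%s'; available: %s", v,
                         paste(names(vars), collapse = ", ")))
    ids <- unique(c(names(vars[[x]]), names(vars[[y]])))
    xv <- vars[[x]][ids]
    yv <- vars[[y]][ids]
    ok <- !is.na(xv) & !is.na(yv)
    if (any(!ok))
        message("plotData: omitting ", sum(!ok),
                " node(s) missing a value for '", x, "' or '", y, "'")
    out <- data.frame(node = ids[ok], x = as.numeric(xv[ok]),
                      y = as.numeric(yv[ok]), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    if (render && nrow(out)) {
        graphics::plot(out$x, out$y, xlab = x, ylab = y, pch = 19,
                       main = sprintf("%s vs %s", y, x))
        graphics::text(out$x, out$y, out$node, pos = 3, cex = 0.7)
    }
    out
}

#' Export a classification report as TSV
#'
#' One boolean column per variable (TRUE/FALSE literals, empty where
#' unclassified); thresholds are recorded in a header comment.
#'
#' @param report a [ClassificationReport-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeClassification <- function(report, path) {
    stopifnot(is(report, "ClassificationReport"))
    m <- report@calls
    hdr <- sprintf("# rule: %s; thresholds: %s", report@rule,
                   paste(sprintf("%s=%s", colnames(m),
                                 .fmtNum(report@thresholds)), collapse = " "))
    body <- vapply(seq_len(nrow(m)), function(i) {
        cells <- ifelse(is.na(m[i, ]), "", ifelse(m[i, ], "TRUE", "FALSE"))
        paste(c(rownames(m)[i], cells), collapse = "\t")
    }, character(1))
    writeLines(c(hdr, paste(c("node", colnames(m)), collapse = "\t"), body),
               path)
    invisible(path)
}
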