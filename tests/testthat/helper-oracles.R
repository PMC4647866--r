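# Independent oracles, written directly from definitions and kept separate
# from the implementation under test: a cubic-time all-pairs relaxation for
# distances, and exhaustive simple-path enumeration for sigma / stress /
# betweenness / edge betweenness on tiny graphs.

ORACLE_TOL <- 1e-9

# Floyd-Warshall all-pairs distances from the raw edge table
oracleDistances <- function(g, orientation = "out") {
    ids <- nodeIds(g)
    n <- length(ids)
    e <- edgeTable(g)
    e <- e[e$from != e$to, , drop = FALSE]
    w <- if (nrow(e) == 0L || anyNA(e$weight)) rep(1, nrow(e)) else e$weight
    D <- matrix(Inf, n, n, dimnames = list(ids, ids))
    diag(D) <- 0
    for (i in seq_len(nrow(e))) {
        a <- e$from[i]; b <- e$to[i]
        if (isDirected(g)) {
            if (orientation == "in") { tmp <- a; a <- b; b <- tmp }
            D[a, b] <- min(D[a, b], w[i])
        } else {
            D[a, b] <- min(D[a, b], w[i])
            D[b, a] <- min(D[b, a], w[i])
        }
    }
    for (k in seq_len(n))
        D <- pmin(D, outer(D[, k], D[k, ], `+`))
    D
}

# exhaustive enumeration: for every ordered pair the full set of shortest
# simple paths (node sequences + traversed edge rows), then every
# path-based index from first principles
oraclePathCentralities <- function(g, orientation = "out") {
    ids <- nodeIds(g)
    n <- length(ids)
    e <- edgeTable(g)
    keep <- which(e$from != e$to)
    ef <- match(e$from[keep], ids)
    et <- match(e$to[keep], ids)
    w <- if (length(keep) == 0L || anyNA(e$weight)) rep(1, length(keep))
         else e$weight[keep]
    arcs <- vector("list", n)   # each: matrix cols (to, w, edgeRow)
    addArc <- function(a, b, wt, row) {
        arcs[[a]] <<- rbind(arcs[[a]], c(b, wt, row))
    }
    for (k in seq_along(ef)) {
        a <- ef[k]; b <- et[k]
        if (isDirected(g)) {
            if (orientation == "in") { tmp <- a; a <- b; b <- tmp }
            addArc(a, b, w[k], keep[k])
        } else {
            addArc(a, b, w[k], keep[k])
            addArc(b, a, w[k], keep[k])
        }
    }
    D <- matrix(Inf, n, n, dimnames = list(ids, ids)); diag(D) <- 0
    sigma <- matrix(0, n, n); diag(sigma) <- 1
    stress <- numeric(n)
    btw <- numeric(n)
    eb <- numeric(nrow(e))
    for (s in seq_len(n)) {
        # collect all simple paths from s: per target, list of (cost, nodes, edges)
        found <- lapply(seq_len(n), function(i) list())
        rec <- function(v, cost, nodes, edges, visited) {
            A <- arcs[[v]]
            if (is.null(A)) return()
            for (r in seq_len(nrow(A))) {
                b <- A[r, 1L]
                if (visited[b]) next
                nc <- cost + A[r, 2L]
                found[[b]][[length(found[[b]]) + 1L]] <<-
                    list(cost = nc, nodes = c(nodes, b), edges = c(edges, A[r, 3L]))
                visited[b] <- TRUE
                rec(b, nc, c(nodes, b), c(edges, A[r, 3L]), visited)
                visited[b] <- FALSE
            }
        }
        visited <- rep(FALSE, n); visited[s] <- TRUE
        rec(s, 0, s, integer(0), visited)
        for (t in seq_len(n)) {
            if (t == s || !length(found[[t]])) next
            costs <- vapply(found[[t]], `[[`, numeric(1), "cost")
            mn <- min(costs)
            sel <- which(abs(costs - mn) <=
                             ORACLE_TOL * pmax(1, abs(mn), abs(costs)))
            D[s, t] <- mn
            sig <- length(sel)
            sigma[s, t] <- sig
            for (j in sel) {
                p <- found[[t]][[j]]
                interior <- setdiff(p$nodes, c(s, t))
                stress[interior] <- stress[interior] + 1
                btw[interior] <- btw[interior] + 1 / sig
                eb[p$edges] <- eb[p$edges] + 1 / sig
            }
        }
    }
    if (!isDirected(g)) {   # ordered enumeration counted each pair twice
        stress <- stress / 2; btw <- btw / 2; eb <- eb / 2
    }
    list(dist = D,
         sigma = sigma,
         stress = stats::setNames(stress, ids),
         betweenness = stats::setNames(btw, ids),
         edgeBetweenness = stats::setNames(eb, paste(e$from, e$to, sep = "|")))
}

# distance-derived indices applied naively to an all-pairs matrix
oracleFromDistances <- function(D) {
    n <- nrow(D)
    ecc <- clo <- rad <- numeric(n)
    finite <- D[is.finite(D) & row(D) != col(D)]
    delta <- if (length(finite)) max(finite) else 0
    for (i in seq_len(n)) {
        d <- D[i, -i]; d <- d[is.finite(d)]
        ecc[i] <- if (length(d)) 1 / max(d) else 0
        clo[i] <- if (length(d)) 1 / sum(d) else 0
        rad[i] <- if (length(d) && n > 1L) sum(delta + 1 - d) / (n - 1) else 0
    }
    cen <- numeric(n)
    for (v in seq_len(n)) {
        if (n == 1L) break
        fs <- vapply(setdiff(seq_len(n), v), function(w) {
            u <- setdiff(seq_len(n), c(v, w))
            sum(D[v, u] < D[w, u]) - sum(D[w, u] < D[v, u])
        }, numeric(1))
        cen[v] <- min(fs)
    }
    list(eccentricity = stats::setNames(ecc, rownames(D)),
         closeness = stats::setNames(clo, rownames(D)),
         radiality = stats::setNames(rad, rownames(D)),
         centroid = stats::setNames(cen, rownames(D)),
         diameter = delta,
         averageDistance = if (length(finite)) mean(finite) else 0)
}
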