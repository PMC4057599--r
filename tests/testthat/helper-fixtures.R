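## shared in-code fixtures; no data files

## named undirected igraph from an edge list given as "a-b" strings
graphFromPairs <- function(pairs, extraNodes = character(0)) {
    el <- do.call(rbind, strsplit(pairs, "-", fixed = TRUE))
    nodes <- sort(unique(c(as.vector(el), extraNodes)))
    g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
    igraph::V(g)$name <- nodes
    igraph::add_edges(g, t(el))
}

## clique on the given node names
cliqueGraph <- function(nodes) {
    g <- igraph::make_full_graph(length(nodes))
    igraph::V(g)$name <- nodes
    g
}

## independent brute-force count of induced edges for a node subset
bruteInducedEdges <- function(nodes, g) {
    el <- igraph::as_edgelist(g, names = TRUE)
    sum(el[, 1] %in% nodes & el[, 2] %in% nodes)
}

## independent per-node cross-edge count: edges from s to (X u Y) \ S,
## counted straight off the edge list
bruteCrossEdges <- function(S, X, Y, g) {
    el <- igraph::as_edgelist(g, names = TRUE)
    cross <- setdiff(union(X, Y), S)
    vapply(S, function(s) {
        sum((el[, 1] == s & el[, 2] %in% cross) |
            (el[, 2] == s & el[, 1] %in% cross))
    }, numeric(1))
}

## two-cluster integrated network with a configurable shared set; every
## non-shared node of X gets edges from state 1, of Y from state 2, and
## shared nodes connect into both sides
toyIntegrated <- function(nX = 4, nY = 4, shared = "s1",
                          labs = c("YNG", "MID")) {
    xs <- paste0("x", seq_len(nX))
    ys <- paste0("y", seq_len(nY))
    e1 <- c(outer(c(xs, shared), c(xs, shared), paste, sep = "-"))
    e1 <- e1[as.vector(upper.tri(matrix(0, nX + length(shared),
                                        nX + length(shared))))]
    e2 <- c(outer(c(ys, shared), c(ys, shared), paste, sep = "-"))
    e2 <- e2[as.vector(upper.tri(matrix(0, nY + length(shared),
                                        nY + length(shared))))]
    g1 <- graphFromPairs(e1)
    g2 <- graphFromPairs(e2)
    net1 <- StateNetwork(g1, labs[1])
    net2 <- StateNetwork(g2, labs[2])
    clX <- DenseCluster(c(xs, shared), labs[1],
        density = clusterDensity(c(xs, shared), g1), clusterId = "X1")
    clY <- DenseCluster(c(ys, shared), labs[2],
        density = clusterDensity(c(ys, shared), g2), clusterId = "Y1")
    list(net1 = net1, net2 = net2, clusters = list(clX, clY),
         integrated = buildIntegrated(list(clX, clY), net1, net2))
}

## small OBO text writer
writeToyObo <- function(terms, path = tempfile(fileext = ".obo")) {
    lines <- c("format-version: 1.2", "")
    for (t in terms) {
        lines <- c(lines, "[Term]", paste0("id: ", t$id))
        for (p in t$is_a) lines <- c(lines, paste0("is_a: ", p, " ! x"))
        if (isTRUE(t$obsolete)) lines <- c(lines, "is_obsolete: true")
        lines <- c(lines, "")
    }
    writeLines(lines, path)
    path
}

## exhaustive common-ancestor DCP oracle on an OntologyDAG
bruteDcp <- function(dag, termsA, termsB, breadthMode = "sum") {
    anc <- function(t) termAncestors(dag, t)
    up <- function(terms, a) {
        ## min hops from any of `terms` up to ancestor a, by exhaustive
        ## path enumeration
        best <- Inf
        walk <- function(t, d) {
            if (t == a) best <<- min(best, d)
            for (p in dag@parents[[t]]) walk(p, d + 1)
        }
        for (t in terms) walk(t, 0)
        best
    }
    common <- intersect(unique(unlist(lapply(termsA, anc))),
                        unique(unlist(lapply(termsB, anc))))
    if (!length(common)) return(NULL)
    rows <- lapply(common, function(a) {
        ba <- up(termsA, a); bb <- up(termsB, a)
        breadth <- if (breadthMode == "sum") ba + bb else max(ba, bb)
        data.frame(dcp = a, depth = unname(termDepth(dag, a)),
                   breadth = breadth,
                   score = unname(termDepth(dag, a)) - breadth)
    })
    df <- do.call(rbind, rows)
    df[order(-df$score, -df$depth, df$dcp)[1], ]
}
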