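#' Density of a node subset
#'
#' \eqn{2e / (k(k-1))} for the \eqn{k} member nodes and the \eqn{e} edges
#' of the induced subgraph.
#'
#' @param nodes character vector of node names (>= 2), all present in the
#'   network.
#' @param network a \linkS4class{StateNetwork},
#'   \linkS4class{IntegratedNetwork} or igraph graph.
#' @return density in [0, 1].
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' clusterDensity(letters[1:5], g)   # 1
#' @export
clusterDensity <- function(nodes, network) {
    g <- .asGraph(network)
    if (length(nodes) < 2L) stop("at least 2 nodes are required")
    if (!all(nodes %in% igraph::V(g)$name))
        stop("nodes absent from the network")
    k <- length(nodes)
    e <- igraph::ecount(igraph::induced_subgraph(g, nodes))
    2 * e / (k * (k - 1))
}

.asGraph <- function(network) {
    if (is(network, "StateNetwork") || is(network, "IntegratedNetwork"))
        network@graph
    else if (igraph::is_igraph(network)) network
    else stop("not a network object")
}

## MCODE vertex weight: k-core number of the highest core of the closed
## neighbourhood times that core's density; 0 below the degree cutoff.
.mcodeScores <- function(g, degreeCutoff) {
    deg <- igraph::degree(g)
    score <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
    for (v in which(deg >= degreeCutoff)) {
        nb <- c(v, as.integer(igraph::neighbors(g, v)))
        h <- igraph::induced_subgraph(g, nb)
        core <- igraph::coreness(h)
        kmax <- max(core)
        hk <- igraph::induced_subgraph(h, which(core >= kmax))
        nk <- igraph::vcount(hk)
        d <- if (nk >= 2L)
            2 * igraph::ecount(hk) / (nk * (nk - 1)) else 0
        score[v] <- kmax * d
    }
    score
}

#' MCODE-style dense-cluster detection
#'
#' Reimplementation of the MCODE procedure used for dense-module detection
#' in correlation networks: (1) each node is weighted by the k-core number
#' of the densest core in its closed neighbourhood times that core's
#' density, with nodes below the degree cutoff weighted 0; (2) complexes
#' are grown greedily from unseen seed nodes in descending weight order,
#' admitting a neighbour when its weight is at least \code{(1 -
#' nodeScoreCutoff)} times the seed's; (3) a haircut (restriction to the
#' complex's 2-core) is applied and any complex whose maximum core number
#' is below \code{kCore} is discarded. With the defaults (degree cutoff 4,
#' k-core 4) no cluster smaller than 5 nodes — in particular no triangle —
#' can be reported. Ties in weight are broken by lexicographic node name,
#' making the output deterministic.
#'
#' @param network a \linkS4class{StateNetwork} (or igraph graph with a
#'   \code{stateLabel} argument).
#' @param degreeCutoff minimum degree for a node to receive a positive
#'   weight (default 4).
#' @param kCore minimum maximum-core number for a complex to be reported
#'   (default 4).
#' @param nodeScoreCutoff growth tolerance as a fraction of the seed
#'   weight (default 0.2).
#' @param haircut logical; restrict each complex to its 2-core.
#' @param stateLabel state label when \code{network} is a bare graph.
#' @return list of \linkS4class{DenseCluster}, in discovery (descending
#'   seed weight) order.
#' @export
mcodeClusters <- function(network, degreeCutoff = 4L, kCore = 4L,
                          nodeScoreCutoff = 0.2, haircut = TRUE,
                          stateLabel = NULL) {
    g <- .asGraph(network)
    if (is.null(stateLabel))
        stateLabel <- if (is(network, "StateNetwork"))
            network@stateLabel else "net"
    if (igraph::vcount(g) == 0L) return(list())
    score <- .mcodeScores(g, degreeCutoff)
    nm <- names(score)
    ord <- order(-score, nm)
    seen <- logical(length(nm))
    adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
    clusters <- list()
    for (i in ord) {
        if (seen[i] || score[i] <= 0) next
        thr <- score[i] * (1 - nodeScoreCutoff)
        members_i <- integer(0)
        queue <- i
        seen[i] <- TRUE
        while (length(queue)) {
            v <- queue[[1L]]; queue <- queue[-1L]
            members_i <- c(members_i, v)
            for (w in adj[[v]]) {
                if (!seen[w] && score[w] >= thr) {
                    seen[w] <- TRUE
                    queue <- c(queue, w)
                }
            }
        }
        members <- nm[members_i]
        if (length(members) < 2L) next
        sub <- igraph::induced_subgraph(g, members)
        if (haircut) {
            core2 <- igraph::coreness(sub)
            members <- members[core2 >= 2L]
            if (length(members) < 2L) next
            sub <- igraph::induced_subgraph(g, members)
        }
        if (max(igraph::coreness(sub)) < kCore) next
        clusters[[length(clusters) + 1L]] <- DenseCluster(
            members = sort(members), stateLabel = stateLabel,
            density = clusterDensity(members, g),
            clusterId = sprintf("%s_c%02d", stateLabel,
                                length(clusters) + 1L))
    }
    clusters
}

#' Filter clusters by minimum density
#'
#' Retains clusters whose density is at least \code{minDensity}; output
#' keeps a stable ordering by cluster id. The study's conventional cut
#' points are 0.65, 0.75 and 0.85, but any value in [0, 1] is allowed;
#' outputs at increasing cut points are nested.
#'
#' @param clusters list of \linkS4class{DenseCluster}.
#' @param minDensity density cut point in [0, 1].
#' @return the retained sublist, ordered by cluster id.
#' @export
filterByDensity <- function(clusters, minDensity) {
    stopifnot(minDensity >= 0, minDensity <= 1)
    keep <- vapply(clusters, function(cl) cl@density >= minDensity,
                   logical(1))
    out <- clusters[keep]
    out[order(vapply(out, clusterId, character(1)))]
}

#' Cluster table
#'
#' Flat summary of a cluster list, suitable for TSV export.
#'
#' @param clusters list of \linkS4class{DenseCluster}.
#' @return data.frame with columns \code{cluster_id}, \code{state},
#'   \code{size}, \code{density}, \code{members} (comma-separated).
#' @export
clusterTable <- function(clusters) {
    data.frame(
        cluster_id = vapply(clusters, clusterId, character(1)),
        state = vapply(clusters, stateLabel, character(1)),
        size = vapply(clusters, function(cl) length(cl@members), integer(1)),
        density = vapply(clusters, clusterDensityValue, numeric(1)),
        members = vapply(clusters, function(cl)
            paste(cl@members, collapse = ","), character(1)),
        stringsAsFactors = FALSE)
}
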