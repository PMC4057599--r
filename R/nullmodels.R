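#' Simulate a pair of Erdős–Rényi null networks
#'
#' Two independent G(n, p) draws over one shared, named node set. The
#' defaults (12,300 nodes, edge probability 10/10000) match the size of a
#' genome-wide probe-level correlation network, giving degree-homogeneous
#' null networks with no dense clusters.
#'
#' @param n node count (default 12300).
#' @param p edge probability (default 0.001).
#' @param seed integer seed (mandatory, for reproducibility).
#' @param stateLabels labels for the two draws.
#' @return list of two \linkS4class{StateNetwork} objects sharing a node
#'   set.
#' @export
simulateErPair <- function(n = 12300L, p = 10 / 10000, seed,
                           stateLabels = c("SIM1", "SIM2")) {
    stopifnot(p >= 0, p <= 1, length(stateLabels) == 2L)
    set.seed(seed)
    ids <- sprintf("n%06d", seq_len(n))
    draw <- function(lab) {
        g <- igraph::sample_gnp(n, p)
        igraph::V(g)$name <- ids
        StateNetwork(g, lab)
    }
    list(draw(stateLabels[1L]), draw(stateLabels[2L]))
}

#' Simulate a pair of scale-free null networks
#'
#' Static power-law random graphs (no self-loops or multi-edges) with the
#' requested expected degree exponent, sized to match a real network's
#' edge count. The default exponent of 2.5 is typical of co-expression
#' network degree distributions.
#'
#' @param n node count.
#' @param mEdges edge count per draw, at most \eqn{n(n-1)/2}.
#' @param exponent power-law exponent (> 2, default 2.5).
#' @param seed integer seed.
#' @param stateLabels labels for the two draws.
#' @return list of two \linkS4class{StateNetwork} objects sharing a node
#'   set.
#' @export
simulateScaleFreePair <- function(n, mEdges, exponent = 2.5, seed,
                                  stateLabels = c("SFSIM1", "SFSIM2")) {
    stopifnot(exponent > 2)
    if (mEdges > n * (n - 1) / 2)
        stop("'mEdges' exceeds the complete-graph bound n(n-1)/2")
    set.seed(seed)
    ids <- sprintf("n%06d", seq_len(n))
    draw <- function(lab) {
        g <- igraph::sample_fitness_pl(n, mEdges, exponent.out = exponent,
                                       loops = FALSE, multiple = FALSE)
        igraph::V(g)$name <- ids
        StateNetwork(g, lab)
    }
    list(draw(stateLabels[1L]), draw(stateLabels[2L]))
}

#' Gatewayness null distribution from a simulated network pair
#'
#' Runs the cluster-and-gateway analysis on a null pair. With
#' \code{enforceDensity = FALSE} (the null-model convention) cluster
#' density is not filtered, and if a network yields no clusters at all its
#' full node set is treated as one whole-network cluster with the
#' half-size restriction suspended — the convention under which every
#' shared node of a cluster-free G(n, p) pair is a gateway. Because a
#' whole-network cluster pair has no non-gateway nodes, each node's
#' cross-edge count falls back to its degree in the integrated graph, so
#' the null gatewayness is the node's degree share.
#'
#' @param pair list of two \linkS4class{StateNetwork} objects.
#' @param enforceDensity logical; filter clusters at \code{minDensity}
#'   before gateway analysis (default FALSE, the null convention).
#' @param minDensity density cut applied when \code{enforceDensity}.
#' @param degreeCutoff,kCore,nodeScoreCutoff clustering parameters.
#' @return numeric vector of gatewayness values of every null gateway
#'   node (named by node).
#' @export
nullGatewayDistribution <- function(pair, enforceDensity = FALSE,
                                    minDensity = 0.65, degreeCutoff = 4L,
                                    kCore = 4L, nodeScoreCutoff = 0.2) {
    stopifnot(length(pair) == 2L)
    net1 <- pair[[1L]]; net2 <- pair[[2L]]
    whole <- FALSE
    clusterOf <- function(net) {
        cl <- mcodeClusters(net, degreeCutoff, kCore, nodeScoreCutoff)
        if (enforceDensity) cl <- filterByDensity(cl, minDensity)
        if (!length(cl) && !enforceDensity) {
            whole <<- TRUE
            nodes <- igraph::V(net@graph)$name
            cl <- list(DenseCluster(nodes, net@stateLabel,
                density = clusterDensity(nodes, net@graph),
                clusterId = paste0(net@stateLabel, "_all")))
        }
        cl
    }
    cl <- c(clusterOf(net1), clusterOf(net2))
    if (length(cl) < 2L) return(stats::setNames(numeric(0), character(0)))
    integ <- buildIntegrated(cl, net1, net2)
    pairs <- findGatewaySets(integ, sizeRestriction = !whole)
    rec <- suppressWarnings(gatewayRecords(integ, pairs))
    if (!nrow(rec)) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(rec$gatewayness, rec$node)
}

#' Two-sample significance test for observed versus null gatewayness
#'
#' Classical pooled-variance two-sided Student's t-test comparing the
#' observed gatewayness values with the null distribution. When both
#' samples are constant with equal means the p-value is 1 (no evidence of
#' difference); constant samples with different means give p = 0.
#'
#' @param observed numeric vector of observed gatewayness values (>= 2).
#' @param null numeric vector of null gatewayness values (nonempty).
#' @return two-sided p-value.
#' @export
gatewaySignificance <- function(observed, null) {
    if (length(observed) < 2L) stop("need at least 2 observed values")
    if (!length(null)) stop("'null' is empty")
    if (stats::sd(observed) == 0 &&
        (length(null) < 2L || stats::sd(null) == 0)) {
        return(if (isTRUE(all.equal(mean(observed), mean(null)))) 1 else 0)
    }
    stats::t.test(observed, null, var.equal = TRUE)$p.value
}

#' Significance stars
#'
#' \code{"***"} for p < 0.0005, \code{"*"} for p < 0.05, otherwise
#' \code{"ns"}.
#'
#' @param p p-value(s).
#' @return character vector of markers.
#' @export
significanceStars <- function(p) {
    ifelse(p < 0.0005, "***", ifelse(p < 0.05, "*", "ns"))
}

#' Maximum-likelihood degree exponent
#'
#' Convenience wrapper fitting a discrete power law to a network's degree
#' sequence, used to sanity-check simulated scale-free null networks.
#'
#' @param network a \linkS4class{StateNetwork} or igraph graph.
#' @return the fitted exponent (alpha).
#' @export
degreeExponent <- function(network) {
    g <- .asGraph(network)
    d <- igraph::degree(g)
    igraph::fit_power_law(d[d > 0], implementation = "plfit")$alpha
}
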