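#' Build the integrated two-state network from retained clusters
#'
#' The node set is the union of the members of every retained cluster from
#' the two states; the edge set is every edge of either state's network
#' whose endpoints both lie in that node set. Each edge's \code{states}
#' attribute names the state(s) whose network contains it (comma-joined
#' when both do), giving the two-edge-type integrated graph the gateway
#' analysis runs on.
#'
#' @param clusters list of \linkS4class{DenseCluster} from exactly the two
#'   given states.
#' @param net1,net2 the two \linkS4class{StateNetwork} objects.
#' @return An \linkS4class{IntegratedNetwork}.
#' @export
buildIntegrated <- function(clusters, net1, net2) {
    lab1 <- net1@stateLabel; lab2 <- net2@stateLabel
    if (lab1 == lab2) stop("the two networks must have distinct state labels")
    labs <- vapply(clusters, stateLabel, character(1))
    if (length(clusters) && !all(labs %in% c(lab1, lab2)))
        stop("clusters from unknown state(s): ",
             paste(setdiff(labs, c(lab1, lab2)), collapse = ", "))
    nodes <- sort(unique(unlist(lapply(clusters, clusterMembers),
                                use.names = FALSE)))
    for (cl in clusters) {
        net <- if (cl@stateLabel == lab1) net1 else net2
        bad <- setdiff(cl@members, igraph::V(net@graph)$name)
        if (length(bad))
            stop("cluster '", cl@clusterId,
                 "' references nodes unknown to its state network: ",
                 paste(bad, collapse = ", "))
    }
    edge_keys <- function(net) {
        el <- igraph::as_edgelist(net@graph, names = TRUE)
        el <- el[el[, 1L] %in% nodes & el[, 2L] %in% nodes, , drop = FALSE]
        if (!nrow(el)) return(character(0))
        paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "\r")
    }
    k1 <- edge_keys(net1); k2 <- edge_keys(net2)
    keys <- sort(unique(c(k1, k2)))
    states <- ifelse(keys %in% k1 & keys %in% k2, paste(lab1, lab2, sep = ","),
              ifelse(keys %in% k1, lab1, lab2))
    g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
    igraph::V(g)$name <- nodes
    if (length(keys)) {
        ends <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
        g <- igraph::add_edges(g, t(ends))
        igraph::E(g)$states <- states
    }
    new("IntegratedNetwork", graph = g, clusters = clusters,
        stateLabels = c(lab1, lab2))
}

#' Identify gateway sets between cross-state cluster pairs
#'
#' For every pair (X, Y) with X a cluster of the first state and Y a
#' cluster of the second, the candidate gateway set is the node
#' intersection \eqn{S = V(X) \cap V(Y)}. A pair is reported only when S
#' is nonempty and, under the size restriction, \eqn{|S| \le
#' \min(|V(X)|, |V(Y)|)/2} — which also rules out the degenerate case
#' \eqn{V(X) = V(Y) = S}. Within-state pairs are never compared.
#'
#' @param integrated an \linkS4class{IntegratedNetwork}.
#' @param sizeRestriction logical; apply the half-size rule (default TRUE).
#'   Null-model analyses with whole-network clusters suspend it.
#' @return list of records, each a list with elements \code{x}, \code{y}
#'   (cluster ids), \code{X}, \code{Y} (member vectors) and \code{S}.
#' @export
findGatewaySets <- function(integrated, sizeRestriction = TRUE) {
    labs <- integrated@stateLabels
    cl1 <- Filter(function(cl) cl@stateLabel == labs[1L],
                  integrated@clusters)
    cl2 <- Filter(function(cl) cl@stateLabel == labs[2L],
                  integrated@clusters)
    out <- list()
    for (X in cl1) for (Y in cl2) {
        S <- intersect(X@members, Y@members)
        if (!length(S)) next
        if (sizeRestriction &&
            length(S) > min(length(X@members), length(Y@members)) / 2) {
            message("pair ", X@clusterId, " x ", Y@clusterId,
                    " excluded: |S| = ", length(S),
                    " exceeds half the smaller cluster")
            next
        }
        out[[length(out) + 1L]] <- list(
            x = X@clusterId, y = Y@clusterId,
            X = X@members, Y = Y@members, S = sort(S))
    }
    out
}

## cross-edge count e(s) for every member of S: edges of the integrated
## graph joining s to (V(X) u V(Y)) \ S.  S-S edges are excluded.  In the
## degenerate whole-overlap case (no non-S nodes, as in whole-network null
## clusters) the exclusion is suspended and e(s) is the full degree of s
## within the induced subgraph on V(X) u V(Y).
.crossEdgeCounts <- function(S, X, Y, integrated) {
    g <- integrated@graph
    un <- union(X, Y)
    cross <- setdiff(un, S)
    sub <- igraph::induced_subgraph(g, un)
    if (length(cross) == 0L)
        return(stats::setNames(igraph::degree(sub)[S], S))
    counts <- vapply(S, function(s) {
        nb <- igraph::V(sub)$name[
            as.integer(igraph::neighbors(sub, s))]
        sum(nb %in% cross)
    }, numeric(1))
    counts
}

#' Gatewayness of one node in a gateway set
#'
#' The fraction of cross-cluster bridging edges carried by node \code{s}:
#' \eqn{e(s) / \sum_{s' \in S} e(s')}, where \eqn{e(s')} counts the
#' integrated-network edges (of either state) joining \eqn{s'} to a
#' non-gateway node of \eqn{V(X) \cup V(Y)}. Edges between two gateway
#' nodes are excluded. A sole gateway therefore always scores exactly 1,
#' and the scores over one gateway set sum to 1.
#'
#' @param s node name, a member of the pair's gateway set.
#' @param pair one record from \code{\link{findGatewaySets}}.
#' @param integrated the \linkS4class{IntegratedNetwork} the pair came
#'   from.
#' @return the gatewayness fraction.
#' @export
gatewayness <- function(s, pair, integrated) {
    if (!s %in% pair$S) stop("'", s, "' is not in the pair's gateway set")
    counts <- .crossEdgeCounts(pair$S, pair$X, pair$Y, integrated)
    tot <- sum(counts)
    if (tot == 0)
        stop("degenerate pair: no cross-cluster edges through the gateway set")
    unname(counts[s] / tot)
}

#' Gateway records for a set of cluster pairs
#'
#' Computes cross-edge counts and gatewayness for every member of every
#' qualifying gateway set. Pairs whose gateway set carries no
#' cross-cluster edge at all are dropped with a warning.
#'
#' @param integrated an \linkS4class{IntegratedNetwork}.
#' @param pairs list from \code{\link{findGatewaySets}}; computed when
#'   omitted.
#' @param sizeRestriction passed to \code{\link{findGatewaySets}} when
#'   \code{pairs} is omitted.
#' @param densityThreshold optional annotation recorded in the output.
#' @return data.frame with columns \code{node}, \code{cluster_x},
#'   \code{cluster_y}, \code{cross_edges}, \code{gatewayness},
#'   \code{density_threshold}.
#' @export
gatewayRecords <- function(integrated, pairs = NULL, sizeRestriction = TRUE,
                           densityThreshold = NA_real_) {
    if (is.null(pairs))
        pairs <- findGatewaySets(integrated, sizeRestriction)
    rows <- lapply(pairs, function(pr) {
        counts <- .crossEdgeCounts(pr$S, pr$X, pr$Y, integrated)
        tot <- sum(counts)
        if (tot == 0) {
            warning("pair ", pr$x, " x ", pr$y,
                    " dropped: no cross-cluster edges")
            return(NULL)
        }
        data.frame(node = names(counts), cluster_x = pr$x, cluster_y = pr$y,
                   cross_edges = as.numeric(counts),
                   gatewayness = as.numeric(counts) / tot,
                   density_threshold = densityThreshold,
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(node = character(0), cluster_x = character(0),
                          cluster_y = character(0), cross_edges = numeric(0),
                          gatewayness = numeric(0),
                          density_threshold = numeric(0)))
    do.call(rbind, rows)
}

#' Full gateway pipeline over several density thresholds
#'
#' Clusters each state's network once, then for each density cut point
#' filters the clusters, builds the integrated network and computes
#' gateway records: cluster, filter, integrate, score.
#'
#' @param net1,net2 the two \linkS4class{StateNetwork} objects.
#' @param thresholds density cut points (default \code{c(0.65, 0.75,
#'   0.85)}).
#' @param degreeCutoff,kCore,nodeScoreCutoff clustering parameters, see
#'   \code{\link{mcodeClusters}}.
#' @return data.frame of gateway records over all thresholds (long
#'   format); see \code{\link{gatewayTable}} for the per-node wide view.
#' @export
gatewaysAtThresholds <- function(net1, net2,
                                 thresholds = c(0.65, 0.75, 0.85),
                                 degreeCutoff = 4L, kCore = 4L,
                                 nodeScoreCutoff = 0.2) {
    stopifnot(length(thresholds) >= 1L)
    cl1 <- mcodeClusters(net1, degreeCutoff, kCore, nodeScoreCutoff)
    cl2 <- mcodeClusters(net2, degreeCutoff, kCore, nodeScoreCutoff)
    out <- lapply(thresholds, function(th) {
        keep <- filterByDensity(c(cl1, cl2), th)
        if (!length(keep)) return(NULL)
        integ <- buildIntegrated(keep, net1, net2)
        gatewayRecords(integ, densityThreshold = th)
    })
    out <- out[!vapply(out, function(x) is.null(x) || !nrow(x), logical(1))]
    if (!length(out))
        return(gatewayRecords(
            buildIntegrated(list(), net1, net2), pairs = list()))
    do.call(rbind, out)
}

#' Wide per-node gateway table
#'
#' Reshapes long gateway records into one row per node with one column
#' per density threshold, holding the node's maximum gatewayness at that
#' threshold (a node can appear in several qualifying cluster pairs) and
#' \code{NA} where the node is not a gateway.
#'
#' @param records data.frame from \code{\link{gatewaysAtThresholds}}.
#' @return data.frame, one row per node, ordered by decreasing
#'   gatewayness at the lowest threshold.
#' @export
gatewayTable <- function(records) {
    if (!nrow(records))
        return(data.frame(node = character(0)))
    ths <- sort(unique(records$density_threshold))
    nodes <- unique(records$node)
    out <- data.frame(node = nodes, stringsAsFactors = FALSE)
    for (th in ths) {
        sub <- records[records$density_threshold == th, ]
        v <- tapply(sub$gatewayness, sub$node, max)
        out[[sprintf("gatewayness_%02d", round(100 * th))]] <-
            as.numeric(v[nodes])
    }
    first <- out[[2L]]
    out[order(-ifelse(is.na(first), -Inf, first), out$node), , drop = FALSE]
}
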