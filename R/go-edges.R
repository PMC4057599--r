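#' Annotate network edges with their deepest common parent term
#'
#' For every edge of the integrated network whose two endpoints both carry
#' at least one ontology term, finds the common ancestor of the two term
#' sets that maximises the edge score \code{depth - breadth}, where
#' \code{depth} is the candidate's hop distance from a root (longest path
#' by default, the usual term-depth convention) and \code{breadth} is the
#' combined hop distance from the two endpoints' terms up to the
#' candidate (sum of the two per-endpoint minimum distances by default,
#' or the maximum of the two). The maximising ancestor is the edge's
#' deepest common parent (DCP); ties are broken by the deeper term, then
#' lexicographic id. Edges with an unannotated endpoint, or whose term
#' sets share no ancestor, are dropped with a message. High scores mark
#' edges between specifically co-annotated genes; negative scores mark
#' pairs related only through shallow, distant ancestors.
#'
#' @param network an \linkS4class{IntegratedNetwork},
#'   \linkS4class{StateNetwork} or igraph graph.
#' @param dag an \linkS4class{OntologyDAG}.
#' @param geneTerms data.frame with columns \code{gene}, \code{term}.
#' @param breadthMode combine the two endpoint distances by \code{"sum"}
#'   (default) or \code{"max"}.
#' @param depthMode \code{"longest"} (default) or \code{"shortest"} root
#'   path for term depth.
#' @return data.frame with one row per annotated edge: \code{node_a},
#'   \code{node_b}, \code{dcp}, \code{depth}, \code{breadth},
#'   \code{score}.
#' @export
goEdgeAnnotate <- function(network, dag, geneTerms,
                           breadthMode = c("sum", "max"),
                           depthMode = c("longest", "shortest")) {
    breadthMode <- match.arg(breadthMode)
    depthMode <- match.arg(depthMode)
    stopifnot(all(c("gene", "term") %in% colnames(geneTerms)))
    g <- .asGraph(network)
    el <- igraph::as_edgelist(g, names = TRUE)
    geneTerms <- geneTerms[geneTerms$term %in% dag@terms, , drop = FALSE]
    term_sets <- split(geneTerms$term, geneTerms$gene)
    depths <- if (depthMode == "longest") dag@depth else dag@depthShortest
    updist <- new.env(parent = emptyenv())
    distOf <- function(gene) {
        d <- updist[[gene]]
        if (is.null(d)) {
            d <- .upDistances(dag, unique(term_sets[[gene]]))
            updist[[gene]] <- d
        }
        d
    }
    dropped <- 0L
    rows <- vector("list", nrow(el))
    for (i in seq_len(nrow(el))) {
        a <- el[i, 1L]; b <- el[i, 2L]
        if (is.null(term_sets[[a]]) || is.null(term_sets[[b]])) {
            dropped <- dropped + 1L
            next
        }
        da <- distOf(a); db <- distOf(b)
        common <- intersect(names(da), names(db))
        if (!length(common)) {
            dropped <- dropped + 1L
            next
        }
        breadth <- if (breadthMode == "sum") da[common] + db[common]
                   else pmax(da[common], db[common])
        score <- depths[common] - breadth
        best <- order(-score, -depths[common], common)[1L]
        rows[[i]] <- data.frame(
            node_a = a, node_b = b, dcp = common[best],
            depth = unname(depths[common][best]),
            breadth = unname(breadth[best]),
            score = unname(score[best]), stringsAsFactors = FALSE)
    }
    if (dropped > 0L)
        message(dropped, " edge(s) dropped: endpoint without annotation ",
                "or no common ancestor")
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(node_a = character(0), node_b = character(0),
                          dcp = character(0), depth = numeric(0),
                          breadth = numeric(0), score = numeric(0)))
    do.call(rbind, rows)
}

#' Rank gateways by mean annotated-edge score
#'
#' For each gateway node, counts its annotated incident edges (its degree
#' in the annotated network) and averages their DCP scores; the table is
#' sorted by mean score, best functional candidates first. Gateways with
#' no annotated incident edge are excluded with a message.
#'
#' @param gateways a character vector of gateway node names, or a
#'   data.frame with a \code{node} column (e.g. from
#'   \code{\link{gatewayRecords}}).
#' @param annotations data.frame from \code{\link{goEdgeAnnotate}}.
#' @return data.frame with columns \code{node}, \code{degree},
#'   \code{mean_score}, sorted by decreasing \code{mean_score}.
#' @export
rankGateways <- function(gateways, annotations) {
    nodes <- if (is.data.frame(gateways)) unique(gateways$node)
             else unique(as.character(gateways))
    rows <- lapply(nodes, function(nd) {
        inc <- annotations$node_a == nd | annotations$node_b == nd
        if (!any(inc)) return(NULL)
        data.frame(node = nd, degree = sum(inc),
                   mean_score = mean(annotations$score[inc]),
                   stringsAsFactors = FALSE)
    })
    excluded <- nodes[vapply(rows, is.null, logical(1))]
    if (length(excluded))
        message(length(excluded),
                " gateway(s) without annotated incident edges excluded: ",
                paste(excluded, collapse = ", "))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(node = character(0), degree = integer(0),
                          mean_score = numeric(0)))
    out <- do.call(rbind, rows)
    out[order(-out$mean_score, out$node), , drop = FALSE]
}
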