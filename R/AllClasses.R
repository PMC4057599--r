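#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom igraph is_igraph edge_attr vcount ecount V is_directed which_loop
#'   which_multiple E
NULL

setOldClass("igraph")

#' Single-state expression matrix
#'
#' A \linkS4class{SummarizedExperiment} holding one biological state's
#' probe-by-sample expression values (rows = probes, columns = samples),
#' tagged with the state's label (e.g. \code{"YNG"} or \code{"MID"}).
#' Values are stored exactly as provided (typically RMA-normalised log2
#' intensities); no re-normalisation is ever applied. Probes with missing
#' values must be dropped before construction.
#'
#' @slot stateLabel single character, the biological state name.
#' @export
setClass("StateExpression",
    contains = "SummarizedExperiment",
    slots = c(stateLabel = "character"))

setValidity("StateExpression", function(object) {
    msg <- NULL
    if (length(object@stateLabel) != 1L || !nzchar(object@stateLabel))
        msg <- c(msg, "'stateLabel' must be a single non-empty string")
    if (length(SummarizedExperiment::assays(object)) < 1L)
        msg <- c(msg, "one assay is required")
    else {
        a <- SummarizedExperiment::assay(object)
        if (!is.numeric(a))
            msg <- c(msg, "assay must be numeric")
        if (anyNA(a))
            msg <- c(msg, "assay contains missing values; drop incomplete probes first")
        if (is.null(rownames(a)) || is.null(colnames(a)))
            msg <- c(msg, "assay must carry probe (row) and sample (column) names")
        else if (anyDuplicated(colnames(a)))
            msg <- c(msg, "duplicate sample identifiers")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a StateExpression object
#'
#' @param values numeric matrix, probes in rows and samples in columns.
#' @param stateLabel single character state name.
#' @param probeIds,sampleIds optional dimension names; taken from
#'   \code{dimnames(values)} when omitted.
#' @return A \linkS4class{StateExpression}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' StateExpression(m, "YNG")
#' @export
StateExpression <- function(values, stateLabel, probeIds = rownames(values),
                            sampleIds = colnames(values)) {
    values <- as.matrix(values)
    rownames(values) <- probeIds
    colnames(values) <- sampleIds
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values))
    new("StateExpression", se, stateLabel = as.character(stateLabel))
}

#' Thresholded correlation network for one state
#'
#' Undirected graph whose nodes are probes and whose edges are the probe
#' pairs that survived the correlation threshold and significance filter.
#' Edges built from expression data carry the Pearson coefficient
#' (\code{rho}) and its two-sided p-value (\code{p}); simulated null
#' networks may omit them.
#'
#' @slot graph an undirected simple \pkg{igraph} graph with named vertices.
#' @slot stateLabel single character state name.
#' @export
setClass("StateNetwork",
    slots = c(graph = "igraph", stateLabel = "character"))

setValidity("StateNetwork", function(object) {
    g <- object@graph
    msg <- NULL
    if (length(object@stateLabel) != 1L || !nzchar(object@stateLabel))
        msg <- c(msg, "'stateLabel' must be a single non-empty string")
    if (!is_igraph(g))
        msg <- c(msg, "'graph' must be an igraph object")
    else {
        if (is_directed(g))
            msg <- c(msg, "graph must be undirected")
        if (is.null(V(g)$name))
            msg <- c(msg, "vertices must be named")
        if (ecount(g) > 0L) {
            if (any(which_loop(g)))
                msg <- c(msg, "self-loops are not allowed")
            if (any(which_multiple(g)))
                msg <- c(msg, "duplicate edges are not allowed")
            rho <- edge_attr(g, "rho")
            if (!is.null(rho) &&
                (!is.numeric(rho) || any(abs(rho) > 1 + 1e-12, na.rm = TRUE)))
                msg <- c(msg, "edge attribute 'rho' must lie in [-1, 1]")
            p <- edge_attr(g, "p")
            if (!is.null(p) &&
                (!is.numeric(p) || any(p < 0 | p > 1, na.rm = TRUE)))
                msg <- c(msg, "edge attribute 'p' must lie in [0, 1]")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname StateNetwork-class
#' @param graph an undirected named \pkg{igraph} graph.
#' @param stateLabel single character state name.
#' @export
StateNetwork <- function(graph, stateLabel) {
    new("StateNetwork", graph = graph, stateLabel = as.character(stateLabel))
}

#' Dense cluster of one state network
#'
#' A node subset of a \linkS4class{StateNetwork} reported by the
#' MCODE-style clusterer, together with its internal edge density
#' \eqn{2e / (k(k-1))} and the state it came from.
#'
#' @slot members character vector of probe identifiers.
#' @slot stateLabel originating state.
#' @slot density fraction in [0, 1].
#' @slot clusterId stable identifier used in tables and gateway records.
#' @export
setClass("DenseCluster",
    slots = c(members = "character", stateLabel = "character",
              density = "numeric", clusterId = "character"))

setValidity("DenseCluster", function(object) {
    msg <- NULL
    if (length(object@members) < 2L)
        msg <- c(msg, "a cluster needs at least 2 members")
    if (anyDuplicated(object@members))
        msg <- c(msg, "duplicate members")
    if (length(object@density) != 1L || object@density < 0 ||
        object@density > 1 + 1e-12)
        msg <- c(msg, "'density' must be a single value in [0, 1]")
    if (length(object@clusterId) != 1L || !nzchar(object@clusterId))
        msg <- c(msg, "'clusterId' must be a single non-empty string")
    if (length(object@stateLabel) != 1L)
        msg <- c(msg, "'stateLabel' must be a single string")
    if (is.null(msg)) TRUE else msg
})

#' @rdname DenseCluster-class
#' @param members character vector of probe identifiers.
#' @param stateLabel originating state.
#' @param density internal edge density.
#' @param clusterId stable identifier.
#' @export
DenseCluster <- function(members, stateLabel, density, clusterId) {
    new("DenseCluster", members = as.character(members),
        stateLabel = as.character(stateLabel), density = as.numeric(density),
        clusterId = as.character(clusterId))
}

#' Integrated two-state network
#'
#' Union graph over the retained clusters of both states: the node set is
#' the union of all cluster members and an edge is present whenever either
#' state's network contains it restricted to that node set. Each edge
#' carries a \code{states} attribute naming every state whose network
#' contributed it (comma-separated when both did).
#'
#' @slot graph undirected \pkg{igraph} graph with a \code{states} edge
#'   attribute.
#' @slot clusters list of the source \linkS4class{DenseCluster} objects.
#' @slot stateLabels the two state names, first state then second.
#' @export
setClass("IntegratedNetwork",
    slots = c(graph = "igraph", clusters = "list", stateLabels = "character"))

setValidity("IntegratedNetwork", function(object) {
    msg <- NULL
    if (length(object@stateLabels) != 2L ||
        object@stateLabels[1L] == object@stateLabels[2L])
        msg <- c(msg, "'stateLabels' must name two distinct states")
    if (!is_igraph(object@graph) || is_directed(object@graph))
        msg <- c(msg, "'graph' must be an undirected igraph object")
    else {
        nodes <- V(object@graph)$name
        for (cl in object@clusters) {
            if (!is(cl, "DenseCluster")) {
                msg <- c(msg, "'clusters' must contain DenseCluster objects")
                break
            }
            if (!all(cl@members %in% nodes)) {
                msg <- c(msg, sprintf(
                    "cluster '%s' references nodes absent from the graph",
                    cl@clusterId))
                break
            }
        }
        if (ecount(object@graph) > 0L &&
            is.null(edge_attr(object@graph, "states")))
            msg <- c(msg, "edges must carry a 'states' attribute")
    }
    if (is.null(msg)) TRUE else msg
})

#' Gene Ontology (or any is-a) directed acyclic graph
#'
#' Term hierarchy built from child-to-parent links, with the term depths
#' (longest and shortest hop count from a root) precomputed. Construction
#' fails on cyclic input, naming the offending terms.
#'
#' @slot terms character vector of term identifiers.
#' @slot parents named list: term -> character vector of direct parents.
#' @slot roots terms with no parents.
#' @slot depth named numeric: longest root-to-term path length.
#' @slot depthShortest named numeric: shortest root-to-term path length.
#' @export
setClass("OntologyDAG",
    slots = c(terms = "character", parents = "list", roots = "character",
              depth = "numeric", depthShortest = "numeric"))

#' @rdname OntologyDAG-class
#' @param parents named list mapping each term to a character vector of its
#'   direct parents (empty vector for roots). All parents must themselves be
#'   listed terms.
#' @export
OntologyDAG <- function(parents) {
    terms <- names(parents)
    if (is.null(terms) || anyDuplicated(terms))
        stop("'parents' must be a uniquely named list")
    parents <- lapply(parents, function(p) {
        p <- as.character(p)
        bad <- setdiff(p, terms)
        if (length(bad))
            stop("parent term(s) not defined: ", paste(bad, collapse = ", "))
        unique(p)
    })
    nparents <- lengths(parents)
    roots <- terms[nparents == 0L]
    if (length(roots) == 0L && length(terms) > 0L)
        stop("ontology has no root term (cycle through every term?)")
    ## Kahn topological order over child->parent edges, processed from roots
    children <- split(
        rep(terms, nparents),
        factor(unlist(parents, use.names = FALSE), levels = terms))
    depth <- depthS <- stats::setNames(rep(NA_real_, length(terms)), terms)
    depth[roots] <- depthS[roots] <- 0
    remaining <- nparents
    queue <- roots
    nseen <- 0L
    while (length(queue)) {
        t <- queue[[1L]]; queue <- queue[-1L]
        nseen <- nseen + 1L
        for (ch in children[[t]]) {
            depth[ch] <- max(depth[ch], depth[t] + 1, na.rm = TRUE)
            depthS[ch] <- min(depthS[ch], depthS[t] + 1, na.rm = TRUE)
            remaining[ch] <- remaining[ch] - 1L
            if (remaining[ch] == 0L) queue <- c(queue, ch)
        }
    }
    if (nseen < length(terms))
        stop("cycle detected in ontology involving term(s): ",
             paste(terms[remaining > 0L], collapse = ", "))
    new("OntologyDAG", terms = terms, parents = parents, roots = roots,
        depth = depth, depthShortest = depthS)
}

#' Planted two-state module design
#'
#' Describes a synthetic two-state expression experiment: per-state
#' co-expression modules generated from a shared latent signal, designated
#' gateway genes that load on one module's signal in each state, and
#' unstructured background genes. Both generated matrices share the full
#' gene universe, mirroring a two-group split of one platform.
#'
#' @slot modules named list (one element per state) of named lists of
#'   character gene vectors.
#' @slot gatewayGenes character; each must belong to exactly one module in
#'   each state.
#' @slot nSamples samples per state.
#' @slot withinModuleR target pairwise correlation of module members, in
#'   (0, 1].
#' @slot noiseSd standard deviation of independent per-gene noise.
#' @slot backgroundGenes number of pure-noise genes.
#' @slot seed integer default seed for generation.
#' @export
setClass("PlantedDesign",
    slots = c(modules = "list", gatewayGenes = "character",
              nSamples = "integer", withinModuleR = "numeric",
              noiseSd = "numeric", backgroundGenes = "integer",
              seed = "integer"))

setValidity("PlantedDesign", function(object) {
    msg <- NULL
    if (length(object@modules) != 2L || is.null(names(object@modules)) ||
        anyDuplicated(names(object@modules)))
        msg <- c(msg, "'modules' must be a named list for exactly 2 states")
    if (object@nSamples < 10L)
        msg <- c(msg, "'nSamples' must be at least 10")
    if (object@withinModuleR <= 0 || object@withinModuleR > 1)
        msg <- c(msg, "'withinModuleR' must lie in (0, 1]")
    if (object@withinModuleR == 1 && object@noiseSd > 0)
        msg <- c(msg,
            "withinModuleR = 1 with positive noiseSd is infeasible")
    if (object@noiseSd < 0)
        msg <- c(msg, "'noiseSd' must be non-negative")
    for (st in names(object@modules)) {
        mods <- object@modules[[st]]
        all_members <- unlist(mods, use.names = FALSE)
        nongw <- setdiff(all_members, object@gatewayGenes)
        if (anyDuplicated(c(nongw,
                unlist(lapply(mods, intersect, object@gatewayGenes)))))
            msg <- c(msg, sprintf(
                "in state '%s' some gene belongs to more than one module", st))
        for (gw in object@gatewayGenes)
            if (sum(vapply(mods, function(m) gw %in% m, logical(1))) != 1L)
                msg <- c(msg, sprintf(
                    "gateway gene '%s' must belong to exactly one module in state '%s'",
                    gw, st))
    }
    if (is.null(msg)) TRUE else msg
})

## ---- show methods ----------------------------------------------------

setMethod("show", "StateExpression", function(object) {
    cat(sprintf("StateExpression '%s': %d probes x %d samples\n",
        object@stateLabel, nrow(object), ncol(object)))
})

setMethod("show", "StateNetwork", function(object) {
    cat(sprintf("StateNetwork '%s': %d nodes, %d edges\n",
        object@stateLabel, vcount(object@graph), ecount(object@graph)))
})

setMethod("show", "DenseCluster", function(object) {
    cat(sprintf("DenseCluster %s [%s]: %d nodes, density %.3f\n",
        object@clusterId, object@stateLabel, length(object@members),
        object@density))
})

setMethod("show", "IntegratedNetwork", function(object) {
    cat(sprintf(
        "IntegratedNetwork %s + %s: %d nodes, %d edges, %d source clusters\n",
        object@stateLabels[1L], object@stateLabels[2L],
        vcount(object@graph), ecount(object@graph),
        length(object@clusters)))
})

setMethod("show", "OntologyDAG", function(object) {
    cat(sprintf("OntologyDAG: %d terms, %d roots, max depth %d\n",
        length(object@terms), length(object@roots),
        if (length(object@depth)) as.integer(max(object@depth)) else 0L))
})

setMethod("show", "PlantedDesign", function(object) {
    sizes <- vapply(object@modules, function(m)
        paste(lengths(m), collapse = "+"), character(1))
    cat(sprintf(
        "PlantedDesign: states %s (module sizes %s), %d gateway gene(s),\n  %d samples/state, target r = %.2f, noise sd = %.2f, %d background genes\n",
        paste(names(object@modules), collapse = "/"),
        paste(sizes, collapse = " vs "),
        length(object@gatewayGenes), object@nSamples,
        object@withinModuleR, object@noiseSd, object@backgroundGenes))
})
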