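#' Write a network in SIF format
#'
#' One line per edge, \code{nodeA<TAB>relation<TAB>nodeB}, in deterministic
#' lexicographic order (each edge's endpoints sorted, then lines sorted by
#' first endpoint, then second). For a \linkS4class{StateNetwork} the
#' relation is the state label; for an \linkS4class{IntegratedNetwork} it
#' is the contributing state's label, or \code{"BOTH"} for edges present in
#' both states. Isolated nodes are appended as single-column lines so the
#' node set round-trips.
#'
#' @param network a \linkS4class{StateNetwork} or
#'   \linkS4class{IntegratedNetwork}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSif <- function(network, path) {
    if (is(network, "StateNetwork")) {
        g <- network@graph
        rel <- rep(network@stateLabel, igraph::ecount(g))
    } else if (is(network, "IntegratedNetwork")) {
        g <- network@graph
        st <- igraph::edge_attr(g, "states")
        if (is.null(st)) st <- character(0)
        rel <- ifelse(grepl(",", st, fixed = TRUE), "BOTH", st)
    } else {
        stop("unsupported network class: ", class(network)[1L])
    }
    el <- igraph::as_edgelist(g, names = TRUE)
    lines <- character(0)
    if (nrow(el) > 0L) {
        a <- pmin(el[, 1L], el[, 2L])
        b <- pmax(el[, 1L], el[, 2L])
        ord <- order(a, b)
        lines <- paste(a[ord], rel[ord], b[ord], sep = "\t")
    }
    iso <- sort(setdiff(igraph::V(g)$name,
        unique(c(el[, 1L], el[, 2L]))))
    writeLines(c(lines, iso), path)
    invisible(path)
}

#' Read a SIF file
#'
#' @param path SIF file path.
#' @return data.frame with columns \code{from}, \code{relation}, \code{to};
#'   single-column lines (isolated nodes) come back with \code{relation}
#'   and \code{to} set to \code{NA}.
#' @export
readSif <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    data.frame(
        from = vapply(parts, `[[`, character(1), 1L),
        relation = vapply(parts, function(p)
            if (length(p) >= 2L) p[[2L]] else NA_character_, character(1)),
        to = vapply(parts, function(p)
            if (length(p) >= 3L) p[[3L]] else NA_character_, character(1)),
        stringsAsFactors = FALSE)
}
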