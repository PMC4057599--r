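#' Read an OBO 1.2 ontology file into an OntologyDAG
#'
#' Builds the term hierarchy from \code{is_a} links (optionally also
#' \code{relationship: part_of}); obsolete terms are excluded, and links
#' pointing at terms not defined in the file are dropped with a warning.
#' A cyclic hierarchy is a fatal error naming the terms involved.
#'
#' @param path path to the OBO flat file.
#' @param usePartOf logical; also treat \code{part_of} relationships as
#'   parent links (off by default).
#' @return An \linkS4class{OntologyDAG}.
#' @export
readObo <- function(path, usePartOf = FALSE) {
    lines <- readLines(path, warn = FALSE)
    stanza_starts <- grep("^\\[", lines)
    if (!length(stanza_starts)) stop("no stanzas found in ", path)
    stanza_ends <- c(stanza_starts[-1L] - 1L, length(lines))
    terms <- character(0)
    parents <- list()
    for (i in seq_along(stanza_starts)) {
        if (lines[stanza_starts[i]] != "[Term]") next
        body <- lines[stanza_starts[i]:stanza_ends[i]]
        idl <- grep("^id:", body, value = TRUE)
        if (!length(idl)) next
        id <- trimws(sub("^id:", "", idl[1L]))
        if (any(grepl("^is_obsolete:\\s*true", body))) next
        isa <- sub("\\s*!.*$", "", sub("^is_a:\\s*", "",
            grep("^is_a:", body, value = TRUE)))
        pars <- trimws(isa)
        if (usePartOf) {
            po <- grep("^relationship:\\s*part_of\\s", body, value = TRUE)
            po <- sub("\\s*!.*$", "",
                sub("^relationship:\\s*part_of\\s+", "", po))
            pars <- c(pars, trimws(po))
        }
        terms <- c(terms, id)
        parents[[id]] <- unique(pars[nzchar(pars)])
    }
    if (anyDuplicated(terms)) {
        warning("duplicate [Term] ids; keeping the first occurrence")
        parents <- parents[!duplicated(names(parents))]
        terms <- unique(terms)
    }
    ## drop links to terms excluded (obsolete) or never defined
    dropped <- 0L
    parents <- lapply(parents, function(p) {
        keep <- p %in% terms
        dropped <<- dropped + sum(!keep)
        p[keep]
    })
    if (dropped > 0L)
        warning(dropped, " parent link(s) to undefined/obsolete terms dropped")
    OntologyDAG(parents)
}

#' Ancestors of a term (inclusive)
#'
#' All terms reachable from \code{term} by following parent links,
#' including \code{term} itself.
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param term a term identifier.
#' @return character vector of ancestor term ids.
#' @export
termAncestors <- function(dag, term) {
    if (!term %in% dag@terms) stop("unknown term: ", term)
    seen <- character(0)
    queue <- term
    while (length(queue)) {
        t <- queue[[1L]]; queue <- queue[-1L]
        if (t %in% seen) next
        seen <- c(seen, t)
        queue <- c(queue, dag@parents[[t]])
    }
    seen
}

#' Term depth
#'
#' Number of hops from a root to the term along parent links; by
#' convention the longest such path (the usual GO term-depth convention),
#' or the shortest with \code{mode = "shortest"}.
#'
#' @param dag an \linkS4class{OntologyDAG}.
#' @param term a term identifier (vectorised).
#' @param mode \code{"longest"} or \code{"shortest"}.
#' @return numeric vector of depths.
#' @export
termDepth <- function(dag, term, mode = c("longest", "shortest")) {
    mode <- match.arg(mode)
    bad <- setdiff(term, dag@terms)
    if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
    if (mode == "longest") dag@depth[term] else dag@depthShortest[term]
}

## minimum upward hop count from each of `terms` to every reachable
## ancestor; returns a named numeric vector over ancestor ids
.upDistances <- function(dag, terms) {
    dist <- stats::setNames(numeric(0), character(0))
    for (t in terms) {
        d <- stats::setNames(0, t)
        queue <- t
        while (length(queue)) {
            cur <- queue[[1L]]; queue <- queue[-1L]
            for (p in dag@parents[[cur]]) {
                nd <- d[[cur]] + 1
                if (is.na(match(p, names(d))) || nd < d[[p]]) {
                    d[p] <- nd
                    queue <- c(queue, p)
                }
            }
        }
        for (a in names(d))
            if (is.na(match(a, names(dist))) || d[[a]] < dist[[a]])
                dist[a] <- d[[a]]
    }
    dist
}
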