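#' Lethality (essential-gene) enrichment of a gene set
#'
#' Log2 odds enrichment of lethal genes in a test set against a
#' background: \eqn{\log_2((b/n)/(B/N))} with \eqn{b} lethal genes among
#' the \eqn{n} test genes and \eqn{B} among the \eqn{N} background genes.
#' Significance is the hypergeometric tail probability of the observed
#' direction: \eqn{P(X \ge b)} for over-representation ("up"),
#' \eqn{P(X \le b)} for under-representation ("down"). With \eqn{b = 0}
#' the enrichment is \code{-Inf} while the p-value remains valid.
#'
#' @param testGenes character vector, a subset of \code{backgroundGenes}.
#' @param backgroundGenes character vector, the gene universe.
#' @param lethality either a data.frame from
#'   \code{\link{readMgiLethality}} or a character vector of lethal gene
#'   symbols.
#' @return one-row data.frame with columns \code{b}, \code{n}, \code{B},
#'   \code{N}, \code{enrichment}, \code{p_value}, \code{direction}.
#' @examples
#' lethalityEnrichment(c("a", "b"), letters[1:10], lethal = c("a", "b", "c"))
#' @export
lethalityEnrichment <- function(testGenes, backgroundGenes, lethality) {
    lethal <- if (is.data.frame(lethality))
        lethality$gene_symbol[lethality$is_lethal]
    else as.character(lethality)
    testGenes <- unique(testGenes)
    backgroundGenes <- unique(backgroundGenes)
    if (!all(testGenes %in% backgroundGenes))
        stop("'testGenes' must be a subset of 'backgroundGenes'")
    b <- sum(testGenes %in% lethal)
    n <- length(testGenes)
    B <- sum(backgroundGenes %in% lethal)
    N <- length(backgroundGenes)
    if (n == 0L || N == 0L) stop("empty test or background set")
    if (B == 0L) stop("no lethal genes in the background")
    .hyperEnrichment(b, n, B, N)
}

## shared log-odds + hypergeometric machinery
.hyperEnrichment <- function(b, n, B, N) {
    enr <- if (b == 0L) -Inf else log2((b / n) / (B / N))
    up <- (b / n) >= (B / N)
    p <- if (up)
        stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
    else
        stats::phyper(b, B, N - B, n)
    data.frame(b = b, n = n, B = B, N = N, enrichment = enr, p_value = p,
               direction = if (up) "up" else "down",
               stringsAsFactors = FALSE)
}

#' Per-term hypergeometric enrichment
#'
#' Over/under-representation of every annotation term in a test gene set
#' against a background universe. Deliberately applies no multiple-testing
#' correction (mirroring simple uncorrected set enrichment at p < 0.05);
#' terms with no background annotation are skipped.
#'
#' @param testGenes character vector, subset of \code{backgroundGenes}.
#' @param backgroundGenes the gene universe.
#' @param geneTerms data.frame with columns \code{gene}, \code{term} (as
#'   from \code{\link{readGeneTerms}}).
#' @param pCutoff significance cut for the \code{significant} flag
#'   (default 0.05).
#' @return data.frame, one row per tested term, with the
#'   \code{\link{lethalityEnrichment}} columns plus \code{term} and
#'   \code{significant}, ordered by p-value.
#' @export
termEnrichment <- function(testGenes, backgroundGenes, geneTerms,
                           pCutoff = 0.05) {
    stopifnot(all(c("gene", "term") %in% colnames(geneTerms)))
    testGenes <- unique(testGenes)
    backgroundGenes <- unique(backgroundGenes)
    if (!all(testGenes %in% backgroundGenes))
        stop("'testGenes' must be a subset of 'backgroundGenes'")
    ann <- unique(geneTerms[geneTerms$gene %in% backgroundGenes, ])
    rows <- lapply(split(ann$gene, ann$term), function(genes) {
        B <- length(genes)
        if (B == 0L) return(NULL)
        .hyperEnrichment(sum(testGenes %in% genes), length(testGenes),
                         B, length(backgroundGenes))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(term = character(0), b = integer(0),
                          n = integer(0), B = integer(0), N = integer(0),
                          enrichment = numeric(0), p_value = numeric(0),
                          direction = character(0),
                          significant = logical(0)))
    out <- do.call(rbind, rows)
    out <- cbind(term = names(rows), out, row.names = NULL)
    out$significant <- out$p_value < pCutoff
    out[order(out$p_value, out$term), , drop = FALSE]
}
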