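#' Pearson correlation of two expression profiles
#'
#' Standard sample Pearson coefficient. Vectors must have equal length of
#' at least 3 and nonzero variance; at the network level zero-variance
#' probes are skipped with a warning rather than raising.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return The correlation, in [-1, 1].
#' @examples
#' pearsonCorrelation(c(1, 2, 3), c(2, 4, 6))   # 1
#' pearsonCorrelation(1:4, c(1, 3, 2, 4))       # 0.8
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    if (length(x) < 3L) stop("at least 3 paired observations are required")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("correlation undefined: zero variance")
    stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Transforms the coefficient to \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}
#' and evaluates the two-sided tail of the t distribution on \eqn{n-2}
#' degrees of freedom; \eqn{|\rho| = 1} returns 0 exactly.
#'
#' @param rho correlation coefficient(s) in [-1, 1].
#' @param n number of paired samples (>= 3).
#' @return p-value(s) in [0, 1].
#' @examples
#' correlationPValue(0, 20)   # 1
#' correlationPValue(0.8, 12)
#' @export
correlationPValue <- function(rho, n) {
    if (any(n < 3L)) stop("'n' must be at least 3")
    if (any(abs(rho) > 1 + 1e-12)) stop("'rho' must lie in [-1, 1]")
    rho <- pmin(1, pmax(-1, rho))
    p <- numeric(length(rho))
    exact <- abs(rho) >= 1
    p[exact] <- 0
    t <- rho[!exact] * sqrt((n - 2) / (1 - rho[!exact]^2))
    p[!exact] <- 2 * stats::pt(-abs(t), df = n - 2)
    p
}

#' Coefficient of determination
#'
#' The squared correlation: the fraction of one variable's variance
#' explained by the other. At the network's default hard threshold of
#' 0.85 this is 0.7225, i.e. at least 72.25\% shared behaviour per edge.
#'
#' @param rho correlation coefficient(s).
#' @return \code{rho^2}.
#' @export
coefficientOfDetermination <- function(rho) rho^2

#' Edge count of the complete graph K_n
#'
#' \eqn{n(n-1)/2}: the number of probe pairs a correlation network starts
#' from before any thresholding.
#'
#' @param n node count.
#' @return number of unordered pairs.
#' @export
completeGraphEdges <- function(n) n * (n - 1) / 2

#' Build a thresholded, significance-filtered correlation network
#'
#' Computes every pairwise Pearson correlation between probes of one
#' state's expression matrix and keeps the edge (i, j) iff it passes both
#' the hard correlation threshold and the significance filter
#' (p < \code{pMax} on the t transform). The default
#' \code{signMode = "positive"} keeps \eqn{\rho \ge \rho_{min}} only
#' (the 0.85–1.00 band); \code{"absolute"} keeps \eqn{|\rho| \ge
#' \rho_{min}}. Zero-variance probes are skipped with a warning, self
#' pairs and duplicate pairs never arise (upper triangle only), and all
#' probes remain as nodes. Memory is quadratic in the probe count.
#'
#' @param x a \linkS4class{StateExpression}, or a numeric matrix with a
#'   \code{stateLabel} argument.
#' @param rhoMin hard correlation threshold (default 0.85).
#' @param pMax keep edges with p-value strictly below this (default 0.005).
#' @param signMode \code{"positive"} or \code{"absolute"}.
#' @param stateLabel required when \code{x} is a bare matrix.
#' @return A \linkS4class{StateNetwork} with edge attributes \code{rho}
#'   and \code{p}.
#' @export
buildStateNetwork <- function(x, rhoMin = 0.85, pMax = 0.005,
                              signMode = c("positive", "absolute"),
                              stateLabel = NULL) {
    signMode <- match.arg(signMode)
    if (is(x, "StateExpression")) {
        mat <- exprsValues(x)
        stateLabel <- stateLabel(x)
    } else {
        mat <- as.matrix(x)
        if (is.null(stateLabel))
            stop("'stateLabel' is required for a bare matrix")
    }
    if (anyNA(mat)) stop("expression matrix contains missing values")
    probes <- rownames(mat)
    nsamp <- ncol(mat)
    if (nrow(mat) < 2L) {
        warning("fewer than 2 probes: returning an edgeless network")
        g <- igraph::make_empty_graph(n = nrow(mat), directed = FALSE)
        if (nrow(mat)) igraph::V(g)$name <- probes
        return(StateNetwork(g, stateLabel))
    }
    if (nsamp < 3L) stop("at least 3 samples are required")
    sds <- apply(mat, 1L, stats::sd)
    if (any(sds == 0))
        warning(sum(sds == 0),
            " zero-variance probe(s) skipped in correlation")
    usable <- sds > 0
    C <- suppressWarnings(stats::cor(t(mat[usable, , drop = FALSE])))
    idx <- which(upper.tri(C), arr.ind = TRUE)
    rho <- C[idx]
    pass_rho <- if (signMode == "positive") rho >= rhoMin else
        abs(rho) >= rhoMin
    idx <- idx[pass_rho, , drop = FALSE]
    rho <- rho[pass_rho]
    p <- if (length(rho)) correlationPValue(rho, nsamp) else numeric(0)
    keep <- p < pMax
    idx <- idx[keep, , drop = FALSE]
    up <- probes[usable]
    g <- igraph::make_empty_graph(n = length(probes), directed = FALSE)
    igraph::V(g)$name <- probes
    if (nrow(idx)) {
        g <- igraph::add_edges(g,
            rbind(up[idx[, 1L]], up[idx[, 2L]]))
        igraph::E(g)$rho <- rho[keep]
        igraph::E(g)$p <- p[keep]
    }
    StateNetwork(g, stateLabel)
}
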