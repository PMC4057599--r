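#' Construct a planted two-state module design
#'
#' Describes the synthetic ground truth the generator plants: per-state
#' co-expression modules driven by a shared latent signal, gateway genes
#' that belong to one module of each state, and unstructured background
#' genes. The defaults describe the canonical test condition — two states
#' with two 10-gene modules each, one gateway gene shared between the
#' first module of each state, 30 samples per state, a target
#' within-module correlation of 0.95 (comfortably above the 0.85 network
#' threshold) and unit noise.
#'
#' @param states two state labels.
#' @param moduleSizes named list (per state) of integer module sizes.
#' @param nGateways number of gateway genes shared between module 1 of
#'   state 1 and module 1 of state 2; must satisfy the half-size rule so
#'   that the planted truth itself passes the gateway-set restriction.
#' @param nSamples samples per state (>= 10).
#' @param withinModuleR target pairwise correlation within a module,
#'   in (0, 1].
#' @param noiseSd standard deviation of independent per-gene noise.
#' @param backgroundGenes number of pure-noise genes.
#' @param seed default generation seed.
#' @return A \linkS4class{PlantedDesign}.
#' @examples
#' plantedDesign(seed = 1)
#' @export
plantedDesign <- function(states = c("YNG", "MID"),
                          moduleSizes = list(c(10L, 10L), c(10L, 10L)),
                          nGateways = 1L, nSamples = 30L,
                          withinModuleR = 0.95, noiseSd = 1,
                          backgroundGenes = 50L, seed = 20260101L) {
    stopifnot(length(states) == 2L, length(moduleSizes) == 2L)
    names(moduleSizes) <- states
    if (nGateways > min(moduleSizes[[1L]][1L], moduleSizes[[2L]][1L]) / 2)
        stop("'nGateways' violates the half-size gateway restriction")
    gw <- if (nGateways > 0L) sprintf("gw%02d", seq_len(nGateways))
          else character(0)
    modules <- list()
    counter <- 0L
    for (st in states) {
        mods <- list()
        for (m in seq_along(moduleSizes[[st]])) {
            size <- moduleSizes[[st]][m]
            own <- if (m == 1L) size - nGateways else size
            if (own < 0L) stop("module 1 smaller than the gateway count")
            counter <- counter + 1L
            genes <- sprintf("%s_m%d_g%02d", tolower(st), m, seq_len(own))
            if (m == 1L) genes <- c(gw, genes)
            mods[[paste0("M", m)]] <- genes
        }
        modules[[st]] <- mods
    }
    new("PlantedDesign", modules = modules, gatewayGenes = gw,
        nSamples = as.integer(nSamples),
        withinModuleR = as.numeric(withinModuleR),
        noiseSd = as.numeric(noiseSd),
        backgroundGenes = as.integer(backgroundGenes),
        seed = as.integer(seed))
}

#' Generate the two-state expression matrices of a planted design
#'
#' Each module's member genes are a shared standard-normal latent signal
#' plus independent Gaussian noise, with the signal amplitude calibrated
#' from the variance-ratio identity \eqn{r = \sigma^2_s / (\sigma^2_s +
#' \sigma^2_n)} so that the expected pairwise correlation of module
#' members equals \code{withinModuleR}; with \code{noiseSd = 0} module
#' members are pure signal and correlate exactly 1. Gateway genes load on
#' their host module's latent signal in each state; background genes (and
#' genes whose module belongs to the other state) are pure noise. Both
#' matrices span the same gene universe, and per-gene baselines loosely
#' mimic RMA log2 intensities. Fully reproducible for a given seed.
#'
#' @param design a \linkS4class{PlantedDesign}.
#' @param seed integer seed; defaults to the design's own.
#' @return Named list of two \linkS4class{StateExpression} matrices.
#' @export
generateTwoState <- function(design, seed = design@seed) {
    stopifnot(is(design, "PlantedDesign"))
    validObject(design)
    set.seed(seed)
    states <- names(design@modules)
    all_module_genes <- unique(unlist(design@modules, use.names = FALSE))
    bg <- if (design@backgroundGenes > 0L)
        sprintf("bg_g%03d", seq_len(design@backgroundGenes)) else character(0)
    genes <- c(all_module_genes, bg)
    ns <- design@nSamples
    r <- design@withinModuleR
    sdn <- design@noiseSd
    sig_a <- if (sdn == 0) 1 else sdn * sqrt(r / (1 - r))
    baseline <- stats::setNames(stats::runif(length(genes), 6, 12), genes)
    out <- lapply(states, function(st) {
        m <- matrix(stats::rnorm(length(genes) * ns, sd = sdn),
                    nrow = length(genes),
                    dimnames = list(genes,
                        sprintf("%s_s%02d", tolower(st), seq_len(ns))))
        for (mod in design@modules[[st]]) {
            z <- stats::rnorm(ns)
            m[mod, ] <- m[mod, , drop = FALSE] +
                matrix(sig_a * z, length(mod), ns, byrow = TRUE)
        }
        m <- m + baseline[genes]
        StateExpression(m, st)
    })
    stats::setNames(out, states)
}

#' Serialise a planted design as YAML
#'
#' Writes the design next to its generated fixtures so their provenance
#' travels with them.
#'
#' @param design a \linkS4class{PlantedDesign}.
#' @param path output YAML path.
#' @return Invisibly, \code{path}.
#' @export
writeDesign <- function(design, path) {
    yaml::write_yaml(list(
        states = names(design@modules),
        modules = design@modules,
        gateway_genes = design@gatewayGenes,
        n_samples = design@nSamples,
        within_module_r = design@withinModuleR,
        noise_sd = design@noiseSd,
        background_genes = design@backgroundGenes,
        seed = design@seed), path)
    invisible(path)
}
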