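#' Assemble and validate a pipeline configuration
#'
#' Collects every setting the end-to-end workflow needs. All referenced
#' input paths must exist at validation time and every density threshold
#' must lie in [0, 1]. All randomness downstream flows from the single
#' \code{seed}, expanded deterministically per stage.
#'
#' @param expressionPath series-matrix or TSV expression file.
#' @param sampleGroups named list: state label -> sample ids (exactly 2
#'   states).
#' @param rhoMin,pMax,signMode correlation-network settings (see
#'   \code{\link{buildStateNetwork}}).
#' @param degreeCutoff,kCore,nodeScoreCutoff clustering settings.
#' @param densityThresholds density cut points for the gateway tables.
#' @param nullModel \code{"er"}, \code{"scalefree"} or \code{"none"}.
#' @param nullN,nullP null-network size and ER edge probability.
#' @param nullExponent scale-free exponent.
#' @param seed integer master seed.
#' @param lethalityPath optional MGI phenotype report.
#' @param lethalitySymbolCol,lethalityPhenotypeCol its column indices.
#' @param oboPath optional ontology OBO file.
#' @param geneTermsPath optional gene-to-term TSV.
#' @param probeGenePath optional two-column TSV mapping probe ids to gene
#'   symbols for the annotation stages.
#' @return a validated \code{pipelineConfig} list.
#' @export
pipelineConfig <- function(expressionPath, sampleGroups, rhoMin = 0.85,
                           pMax = 0.005, signMode = "positive",
                           degreeCutoff = 4L, kCore = 4L,
                           nodeScoreCutoff = 0.2,
                           densityThresholds = c(0.65, 0.75, 0.85),
                           nullModel = "er", nullN = 12300L,
                           nullP = 10 / 10000, nullExponent = 2.5,
                           seed = 1L, lethalityPath = NULL,
                           lethalitySymbolCol = 7L,
                           lethalityPhenotypeCol = 11L, oboPath = NULL,
                           geneTermsPath = NULL, probeGenePath = NULL) {
    cfg <- as.list(environment())
    for (p in c("expressionPath", "lethalityPath", "oboPath",
                "geneTermsPath", "probeGenePath")) {
        if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
            stop("configured path does not exist: ", cfg[[p]])
    }
    if (!is.list(sampleGroups) || length(sampleGroups) != 2L)
        stop("'sampleGroups' must map exactly two states")
    if (any(densityThresholds < 0 | densityThresholds > 1))
        stop("density thresholds must lie in [0, 1]")
    if (!nullModel %in% c("er", "scalefree", "none"))
        stop("unknown null model: ", nullModel)
    structure(cfg, class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of \code{\link{pipelineConfig}}
#' (snake_case accepted).
#'
#' @param path YAML file.
#' @param overrides named list of values taking precedence over the file.
#' @return a validated \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
    raw <- yaml::read_yaml(path)
    camel <- function(x) gsub("_(\\w)", "\\U\\1", x, perl = TRUE)
    names(raw) <- camel(names(raw))
    names(overrides) <- camel(names(overrides))
    raw[names(overrides)] <- overrides
    known <- names(formals(pipelineConfig))
    unknown <- setdiff(names(raw), known)
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    do.call(pipelineConfig, raw)
}

.stageSeed <- function(seed, stage) (seed * 1000L + stage) %% .Machine$integer.max

#' Run the end-to-end gateway workflow
#'
#' Executes the full analysis: read the two-state expression table, build
#' one thresholded correlation network per state (SIF export), detect
#' dense clusters (TSV export), then per density threshold integrate the
#' retained clusters (SIF export) and write the gateway records and the
#' per-node wide table; simulate the configured null model and write the
#' significance summary; when annotation inputs are configured, write the
#' lethality enrichment and DCP-ranked gateway tables. A YAML run log with
#' versions, parameters, seeds and stage status is always written. Any
#' stage failure aborts with the stage name, leaving the log marked
#' incomplete. Outputs are a pure function of (inputs, config, seed):
#' reruns are byte-identical.
#'
#' @param config a \code{pipelineConfig}.
#' @param outDir output directory, created if needed.
#' @return Invisibly, a named list of the artifact paths plus the main
#'   in-memory results (\code{networks}, \code{clusters}, \code{records}).
#' @export
runPipeline <- function(config, outDir) {
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    log <- list(
        package = "gatewaynet",
        version = as.character(utils::packageVersion("gatewaynet")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = config$seed,
        parameters = config[setdiff(names(config),
            c("expressionPath", "sampleGroups"))],
        status = "incomplete", stages = list())
    logPath <- file.path(outDir, "run_log.yaml")
    writeLog <- function() yaml::write_yaml(log, logPath)
    stage <- function(name, expr) {
        res <- tryCatch(expr, error = function(e) {
            log$stages[[name]] <<- paste("failed:", conditionMessage(e))
            writeLog()
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE)
        })
        log$stages[[name]] <<- "ok"
        res
    }
    artifacts <- list(run_log = logPath)

    mats <- stage("read-expression",
        readSeriesMatrix(config$expressionPath, config$sampleGroups))
    nets <- stage("build-networks", lapply(mats, buildStateNetwork,
        rhoMin = config$rhoMin, pMax = config$pMax,
        signMode = config$signMode))
    for (st in names(nets)) {
        f <- file.path(outDir, sprintf("network_%s.sif", st))
        writeSif(nets[[st]], f)
        artifacts[[paste0("network_", st)]] <- f
    }
    clusters <- stage("cluster", {
        cl <- unlist(lapply(nets, mcodeClusters,
            degreeCutoff = config$degreeCutoff, kCore = config$kCore,
            nodeScoreCutoff = config$nodeScoreCutoff), recursive = FALSE)
        f <- file.path(outDir, "clusters.tsv")
        utils::write.table(clusterTable(cl), f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        artifacts$clusters <- f
        cl
    })
    net1 <- nets[[1L]]; net2 <- nets[[2L]]
    records <- stage("gateways", {
        all_rec <- list()
        for (th in sort(config$densityThresholds)) {
            keep <- filterByDensity(clusters, th)
            tag <- sprintf("%02d", round(100 * th))
            if (length(keep)) {
                integ <- buildIntegrated(keep, net1, net2)
                f <- file.path(outDir, sprintf("integrated_%s.sif", tag))
                writeSif(integ, f)
                artifacts[[paste0("integrated_", tag)]] <- f
                rec <- gatewayRecords(integ, densityThreshold = th)
            } else {
                rec <- gatewayRecords(
                    buildIntegrated(list(), net1, net2), pairs = list())
            }
            f <- file.path(outDir, sprintf("gateways_%s.tsv", tag))
            utils::write.table(rec, f, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            artifacts[[paste0("gateways_", tag)]] <- f
            all_rec[[tag]] <- rec
        }
        rec_long <- do.call(rbind, all_rec)
        f <- file.path(outDir, "gateway_table.tsv")
        utils::write.table(gatewayTable(rec_long), f, sep = "\t",
                           quote = FALSE, row.names = FALSE, na = "")
        artifacts$gateway_table <- f
        rec_long
    })
    stage("nulls", {
        if (config$nullModel != "none" && nrow(records) >= 2L) {
            nseed <- .stageSeed(config$seed, 4L)
            pair <- if (config$nullModel == "er")
                simulateErPair(config$nullN, config$nullP, seed = nseed)
            else
                simulateScaleFreePair(config$nullN,
                    mEdges = max(igraph::ecount(net1@graph),
                                 igraph::ecount(net2@graph), 1L),
                    exponent = config$nullExponent, seed = nseed)
            nulldist <- nullGatewayDistribution(pair)
            f <- file.path(outDir, "null_distribution.tsv")
            utils::write.table(
                data.frame(node = names(nulldist), gatewayness = nulldist),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
            artifacts$null_distribution <- f
            summ <- do.call(rbind, lapply(
                split(records, records$density_threshold), function(rec) {
                    p <- if (nrow(rec) >= 2L)
                        gatewaySignificance(rec$gatewayness, nulldist)
                    else NA_real_
                    data.frame(density_threshold = rec$density_threshold[1L],
                               n_gateways = nrow(rec),
                               n_null = length(nulldist), p_value = p,
                               significance = ifelse(is.na(p), "NA",
                                   significanceStars(p)))
                }))
            f <- file.path(outDir, "null_significance.tsv")
            utils::write.table(summ, f, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            artifacts$null_significance <- f
        }
        NULL
    })
    stage("annotate", {
        gw_nodes <- unique(records$node)
        toGene <- identity
        if (!is.null(config$probeGenePath)) {
            map <- readGeneTerms(config$probeGenePath)
            lut <- stats::setNames(map$term, map$gene)
            toGene <- function(x) unname(ifelse(is.na(lut[x]), x, lut[x]))
        }
        if (!is.null(config$lethalityPath) && length(gw_nodes)) {
            leth <- readMgiLethality(config$lethalityPath,
                config$lethalitySymbolCol, config$lethalityPhenotypeCol)
            background <- unique(toGene(
                unlist(lapply(nets, function(nw)
                    igraph::V(nw@graph)$name), use.names = FALSE)))
            test <- intersect(unique(toGene(gw_nodes)), background)
            if (length(test) && any(background %in%
                    leth$gene_symbol[leth$is_lethal])) {
                enr <- lethalityEnrichment(test, background, leth)
                f <- file.path(outDir, "lethality_enrichment.tsv")
                utils::write.table(enr, f, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
                artifacts$lethality_enrichment <- f
            }
        }
        if (!is.null(config$oboPath) && !is.null(config$geneTermsPath) &&
            length(gw_nodes)) {
            dag <- readObo(config$oboPath)
            gt <- readGeneTerms(config$geneTermsPath)
            keep <- filterByDensity(clusters,
                                    min(config$densityThresholds))
            if (length(keep)) {
                integ <- buildIntegrated(keep, net1, net2)
                ann <- goEdgeAnnotate(integ, dag, gt)
                f <- file.path(outDir, "edge_annotations.tsv")
                utils::write.table(ann, f, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
                artifacts$edge_annotations <- f
                ranked <- rankGateways(gw_nodes, ann)
                f <- file.path(outDir, "ranked_gateways.tsv")
                utils::write.table(ranked, f, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
                artifacts$ranked_gateways <- f
            }
        }
        NULL
    })
    log$status <- "complete"
    writeLog()
    invisible(c(artifacts, list(networks = nets, clusters = clusters,
                                records = records)))
}
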