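test_that("clusterDensity is 2e/(k(k-1))", {
    expect_equal(clusterDensity(letters[1:5], cliqueGraph(letters[1:5])), 1)
    cyc <- graphFromPairs(c("a-b", "b-c", "c-d", "d-a"))
    expect_equal(clusterDensity(letters[1:4], cyc), 4 / 6)
    expect_error(clusterDensity("a", cyc), "at least 2")
    ## random induced subgraph against a brute-force edge count
    set.seed(42)
    g <- igraph::sample_gnp(12, 0.4)
    igraph::V(g)$name <- sprintf("v%02d", 1:12)
    nodes <- sample(igraph::V(g)$name, 8)
    e <- bruteInducedEdges(nodes, g)
    expect_equal(clusterDensity(nodes, g), 2 * e / (8 * 7))
})

test_that("a 6-clique attached to a path is the only cluster found", {
    clique <- cliqueGraph(paste0("c", 1:6))
    path <- igraph::make_ring(10, circular = FALSE)
    igraph::V(path)$name <- paste0("p", 1:10)
    g <- igraph::disjoint_union(clique, path)
    cl <- mcodeClusters(StateNetwork(g, "T"))
    expect_length(cl, 1L)
    expect_setequal(clusterMembers(cl[[1]]), paste0("c", 1:6))
    expect_equal(clusterDensityValue(cl[[1]]), 1)
})

test_that("triangles are never reported under the default core settings", {
    k3 <- cliqueGraph(c("a", "b", "c"))
    expect_length(mcodeClusters(StateNetwork(k3, "T")), 0L)
    ## even with the degree cutoff lowered, the 4-core rule forbids K3
    expect_length(mcodeClusters(StateNetwork(k3, "T"), degreeCutoff = 2L),
                  0L)
})

test_that("disjoint cliques are recovered exactly", {
    sizes <- c(5, 6, 8)
    gs <- lapply(seq_along(sizes), function(i)
        cliqueGraph(sprintf("q%d_%02d", i, seq_len(sizes[i]))))
    g <- Reduce(igraph::disjoint_union, gs)
    cl <- mcodeClusters(StateNetwork(g, "T"))
    expect_length(cl, 3L)
    found <- lapply(cl, clusterMembers)
    for (i in seq_along(sizes)) {
        expected <- sprintf("q%d_%02d", i, seq_len(sizes[i]))
        expect_true(any(vapply(found, setequal, logical(1), expected)))
    }
    expect_true(all(vapply(cl, clusterDensityValue, numeric(1)) == 1))
})

test_that("two 5-cliques joined by a bridge merge into one maximal 4-core", {
    ## with a single bridge edge every node keeps degree >= 4, so the
    ## 10-node union is itself a maximal 4-core and the growth rule (all
    ## node weights tie at 4) crosses the bridge: one cluster, not two --
    ## the well-known size over-prediction of this clustering family
    a <- paste0("a", 1:5); b <- paste0("b", 1:5)
    g <- igraph::disjoint_union(cliqueGraph(a), cliqueGraph(b))
    g <- igraph::add_edges(g, c("a1", "b1"))
    expect_equal(min(igraph::coreness(g)), 4)  # oracle: whole graph is a 4-core
    cl <- mcodeClusters(StateNetwork(g, "T"))
    expect_length(cl, 1L)
    expect_setequal(clusterMembers(cl[[1]]), c(a, b))
    ## the merged cluster is too sparse to pass the 65% density screen
    expect_length(filterByDensity(cl, 0.65), 0L)
})

test_that("every reported cluster re-verifies its density and 4-core", {
    d <- plantedDesign(backgroundGenes = 20L)
    mats <- generateTwoState(d, seed = 9)
    net <- suppressWarnings(buildStateNetwork(mats$YNG))
    cl <- mcodeClusters(net)
    expect_gt(length(cl), 0L)
    for (x in cl) {
        expect_equal(clusterDensityValue(x),
                     clusterDensity(clusterMembers(x), networkGraph(net)))
        sub <- igraph::induced_subgraph(networkGraph(net),
                                        clusterMembers(x))
        expect_gte(max(igraph::coreness(sub)), 4)
        expect_gte(length(clusterMembers(x)), 5L)
    }
})

test_that("density filtering is monotone and identity at zero", {
    set.seed(3)
    clusters <- lapply(1:12, function(i)
        DenseCluster(sprintf("n%d_%d", i, 1:5), "T",
                     density = runif(1), clusterId = sprintf("c%02d", i)))
    expect_length(filterByDensity(clusters, 0), 12L)
    dens <- vapply(clusters, clusterDensityValue, numeric(1))
    expect_length(filterByDensity(clusters, 0.65), sum(dens >= 0.65))
    ids <- function(x) vapply(x, clusterId, character(1))
    nested <- lapply(c(0.65, 0.75, 0.85), function(th)
        ids(filterByDensity(clusters, th)))
    expect_true(all(nested[[2]] %in% nested[[1]]))
    expect_true(all(nested[[3]] %in% nested[[2]]))
})
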