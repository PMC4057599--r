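test_that("integration of disjoint clusters is their disjoint union", {
    g1 <- cliqueGraph(paste0("x", 1:5))
    g2 <- cliqueGraph(paste0("y", 1:5))
    net1 <- StateNetwork(g1, "YNG")
    net2 <- StateNetwork(g2, "MID")
    cl <- list(DenseCluster(paste0("x", 1:5), "YNG", 1, "X"),
               DenseCluster(paste0("y", 1:5), "MID", 1, "Y"))
    integ <- buildIntegrated(cl, net1, net2)
    expect_equal(igraph::vcount(networkGraph(integ)), 10L)
    expect_equal(igraph::ecount(networkGraph(integ)), 20L)
    expect_length(findGatewaySets(integ), 0L)
})

test_that("edge state labels match per-state membership exhaustively", {
    fx <- toyIntegrated(nX = 5, nY = 4, shared = c("s1", "s2"))
    g <- networkGraph(fx$integrated)
    el <- igraph::as_edgelist(g, names = TRUE)
    states <- igraph::E(g)$states
    in1 <- igraph::as_edgelist(networkGraph(fx$net1), names = TRUE)
    in2 <- igraph::as_edgelist(networkGraph(fx$net2), names = TRUE)
    key <- function(el) paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    k <- key(el); k1 <- key(in1); k2 <- key(in2)
    for (i in seq_along(k)) {
        expected <- paste(c("YNG", "MID")[c(k[i] %in% k1, k[i] %in% k2)],
                          collapse = ",")
        expect_identical(states[i], expected)
    }
    ## dual-state edge is stored once with both labels
    g1 <- graphFromPairs(c("a-b"))
    net1 <- StateNetwork(g1, "YNG")
    net2 <- StateNetwork(g1, "MID")
    cl <- list(DenseCluster(c("a", "b"), "YNG", 1, "X"),
               DenseCluster(c("a", "b"), "MID", 1, "Y"))
    integ <- buildIntegrated(cl, net1, net2)
    expect_equal(igraph::ecount(networkGraph(integ)), 1L)
    expect_equal(igraph::E(networkGraph(integ))$states, "YNG,MID")
})

test_that("clusters referencing unknown nodes are rejected", {
    g1 <- cliqueGraph(paste0("x", 1:5))
    net1 <- StateNetwork(g1, "YNG")
    net2 <- StateNetwork(cliqueGraph(paste0("y", 1:5)), "MID")
    cl <- list(DenseCluster(c(paste0("x", 1:4), "ghost"), "YNG", 1, "X"))
    expect_error(buildIntegrated(cl, net1, net2), "ghost")
})

test_that("gateway sets are cross-state intersections under the size rule", {
    fx <- toyIntegrated(nX = 4, nY = 4, shared = "s1")
    sets <- findGatewaySets(fx$integrated)
    expect_length(sets, 1L)
    expect_equal(sets[[1]]$S, "s1")

    ## |S| = 3 with clusters of size 4+3=7? exceed half of min(|X|,|Y|)
    fx3 <- toyIntegrated(nX = 1, nY = 1, shared = c("s1", "s2", "s3"))
    expect_message(sets3 <- findGatewaySets(fx3$integrated), "excluded")
    expect_length(sets3, 0L)

    ## identical clusters (V(X) = V(Y) = S) are always excluded
    g <- cliqueGraph(letters[1:6])
    net1 <- StateNetwork(g, "YNG"); net2 <- StateNetwork(g, "MID")
    cl <- list(DenseCluster(letters[1:6], "YNG", 1, "X"),
               DenseCluster(letters[1:6], "MID", 1, "Y"))
    expect_message(out <- findGatewaySets(buildIntegrated(cl, net1, net2)))
    expect_length(out, 0L)

    ## boundary: |S| exactly half the smaller cluster is allowed
    fx2 <- toyIntegrated(nX = 2, nY = 6, shared = c("s1", "s2"))
    expect_length(findGatewaySets(fx2$integrated), 1L)
})

test_that("a sole gateway always scores exactly 1", {
    for (nX in c(3, 5, 9)) {
        fx <- toyIntegrated(nX = nX, nY = 4, shared = "s1")
        pair <- findGatewaySets(fx$integrated)[[1]]
        expect_identical(gatewayness("s1", pair, fx$integrated), 1)
    }
})

test_that("symmetric gateways split gatewayness evenly", {
    ## two shared nodes, each with identical cross-edge structure
    fx <- toyIntegrated(nX = 4, nY = 4, shared = c("s1", "s2"))
    pair <- findGatewaySets(fx$integrated)[[1]]
    expect_equal(gatewayness("s1", pair, fx$integrated), 0.5)
    expect_equal(gatewayness("s2", pair, fx$integrated), 0.5)
})

test_that("a 14-node instance matches brute-force per-edge counting", {
    ## clusters X (7 nodes) and Y (9 nodes) sharing s1, s2; asymmetric
    ## wiring, including an s1-s2 edge that must not be counted
    xs <- paste0("x", 1:5); ys <- paste0("y", 1:7)
    e1 <- c("x1-x2", "x1-x3", "x2-x3", "x3-x4", "x4-x5", "x2-x5",
            "s1-x1", "s1-x2", "s1-x3", "s2-x4", "s1-s2")
    e2 <- c("y1-y2", "y2-y3", "y3-y4", "y4-y5", "y5-y6", "y6-y7", "y1-y7",
            "s1-y1", "s2-y2", "s2-y3", "s2-y4")
    net1 <- StateNetwork(graphFromPairs(e1), "YNG")
    net2 <- StateNetwork(graphFromPairs(e2), "MID")
    X <- c(xs, "s1", "s2"); Y <- c(ys, "s1", "s2")
    cl <- list(
        DenseCluster(X, "YNG", clusterDensity(X, graphFromPairs(e1)), "X"),
        DenseCluster(Y, "MID", clusterDensity(Y, graphFromPairs(e2)), "Y"))
    integ <- buildIntegrated(cl, net1, net2)
    pair <- findGatewaySets(integ)[[1]]
    oracle <- bruteCrossEdges(pair$S, X, Y, networkGraph(integ))
    expect_equal(unname(oracle), c(4, 4))  # fixture sanity
    for (s in pair$S)
        expect_equal(gatewayness(s, pair, integ),
                     unname(oracle[s] / sum(oracle)))
    rec <- gatewayRecords(integ)
    expect_equal(sum(rec$gatewayness), 1)
    expect_equal(rec$cross_edges, unname(oracle[rec$node]))
})

test_that("gatewayness sums to 1 per gateway set on random instances", {
    set.seed(77)
    for (rep in 1:10) {
        nX <- sample(3:7, 1); nY <- sample(3:7, 1)
        nS <- sample(1:2, 1)
        fx <- toyIntegrated(nX = nX, nY = nY,
                            shared = paste0("s", seq_len(nS)))
        rec <- suppressWarnings(gatewayRecords(fx$integrated))
        if (!nrow(rec)) next
        sums <- tapply(rec$gatewayness,
                       paste(rec$cluster_x, rec$cluster_y), sum)
        expect_equal(as.numeric(sums), rep(1, length(sums)))
    }
})

test_that("removing the gateway set disconnects the cluster pair", {
    fx <- toyIntegrated(nX = 5, nY = 6, shared = c("s1", "s2"))
    pair <- findGatewaySets(fx$integrated)[[1]]
    g <- networkGraph(fx$integrated)
    un <- union(pair$X, pair$Y)
    sub <- igraph::induced_subgraph(g, setdiff(un, pair$S))
    comp <- igraph::components(sub)$membership
    xonly <- setdiff(pair$X, pair$S); yonly <- setdiff(pair$Y, pair$S)
    expect_true(all(outer(comp[xonly], comp[yonly], "!=")))
})

test_that("gatewayness is invariant under node relabeling", {
    fx <- toyIntegrated(nX = 5, nY = 4, shared = c("s1", "s2"))
    rec <- gatewayRecords(fx$integrated)
    ## one global renaming applied consistently to both state graphs
    allnm <- sort(unique(c(igraph::V(networkGraph(fx$net1))$name,
                           igraph::V(networkGraph(fx$net2))$name)))
    lut <- setNames(sprintf("Z%02d", rev(seq_along(allnm))), allnm)
    mapnm <- function(g) {
        igraph::V(g)$name <- unname(lut[igraph::V(g)$name])
        g
    }
    net1 <- StateNetwork(mapnm(networkGraph(fx$net1)), "YNG")
    net2 <- StateNetwork(mapnm(networkGraph(fx$net2)), "MID")
    cl <- lapply(fx$clusters, function(x)
        DenseCluster(unname(lut[clusterMembers(x)]), stateLabel(x),
                     clusterDensityValue(x), clusterId(x)))
    integ2 <- buildIntegrated(cl, net1, net2)
    rec2 <- gatewayRecords(integ2)
    expect_setequal(rec2$gatewayness, rec$gatewayness)
    expect_equal(sum(rec2$gatewayness), 1)
})

test_that("threshold sweep reports gateways only where clusters survive", {
    d <- plantedDesign()
    mats <- generateTwoState(d, seed = 31)
    nets <- suppressWarnings(lapply(mats, buildStateNetwork))
    rec <- gatewaysAtThresholds(nets[[1]], nets[[2]],
                                thresholds = c(0.65, 0.75, 0.85))
    expect_true(all(rec$node == "gw01"))
    expect_true(all(rec$gatewayness == 1))
    wide <- gatewayTable(rec)
    expect_equal(wide$node[1], "gw01")
    ## empty intersections give an empty table
    g1 <- cliqueGraph(paste0("x", 1:5))
    g2 <- cliqueGraph(paste0("y", 1:5))
    rec0 <- gatewaysAtThresholds(StateNetwork(g1, "YNG"),
                                 StateNetwork(g2, "MID"))
    expect_equal(nrow(rec0), 0L)
})
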