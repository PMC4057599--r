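test_that("lethality enrichment follows the log2 odds formula", {
    bg <- sprintf("g%03d", 1:400)
    lethal <- bg[1:100]
    ## b/n = B/N gives zero enrichment
    r0 <- lethalityEnrichment(c(bg[1], bg[101], bg[102], bg[103]), bg, lethal)
    expect_equal(r0$enrichment, 0)
    ## b=5, n=10, B=100, N=400: log2(0.5/0.25) = 1
    test <- c(bg[1:5], bg[101:105])
    r1 <- lethalityEnrichment(test, bg, lethal)
    expect_equal(r1$enrichment, 1)
    expect_equal(r1$direction, "up")
    ## b = 0 reports the -Inf sentinel with a valid p-value
    r2 <- lethalityEnrichment(bg[101:110], bg, lethal)
    expect_identical(r2$enrichment, -Inf)
    expect_true(r2$p_value >= 0 && r2$p_value <= 1)
    expect_error(lethalityEnrichment("nope", bg, lethal), "subset")
})

test_that("hypergeometric p matches exhaustive subset enumeration", {
    ## universe of 10 genes, 4 lethal; test set of 3 with b = 2
    bg <- letters[1:10]
    lethal <- letters[1:4]
    test <- c("a", "b", "e")
    r <- lethalityEnrichment(test, bg, lethal)
    ## brute force over all C(10,3) subsets: P(X >= 2)
    subsets <- combn(10, 3)
    hits <- colSums(matrix(subsets %in% 1:4, nrow = 3))
    expect_equal(r$b, 2)
    expect_equal(r$p_value, mean(hits >= 2))
    ## under-representation tail, same oracle
    r_dn <- lethalityEnrichment(c("e", "f", "g"), bg, lethal)
    expect_equal(r_dn$direction, "down")
    expect_equal(r_dn$p_value, mean(hits <= 0))
})

test_that("swapping test-set ratios negates the enrichment", {
    bg <- sprintf("g%03d", 1:200)
    lethal <- bg[1:50]
    hi <- c(bg[1:10], bg[51:60])    # b/n = 0.50 = 2 x B/N
    lo <- c(bg[1:5], bg[51:85])     # b/n = 0.125 = B/N / 2
    r_hi <- lethalityEnrichment(hi, bg, lethal)
    r_lo <- lethalityEnrichment(lo, bg, lethal)
    expect_equal(r_lo$enrichment, -r_hi$enrichment)
    expect_equal(r_lo$direction, "down")
})

test_that("term enrichment flags a planted over-represented term", {
    set.seed(21)
    bg <- sprintf("g%03d", 1:100)
    ann <- rbind(
        data.frame(gene = bg[1:10], term = "T:planted"),
        data.frame(gene = bg, term = "T:universal"),
        data.frame(gene = sample(bg, 30), term = "T:random"))
    test <- bg[1:10]
    res <- termEnrichment(test, bg, ann)
    planted <- res[res$term == "T:planted", ]
    expect_true(planted$significant)
    expect_equal(planted$direction, "up")
    expect_equal(planted$p_value,
                 phyper(9, 10, 90, 10, lower.tail = FALSE))
    ## a term annotating every gene is never significant
    expect_false(res[res$term == "T:universal", "significant"])
    ## identical test and background sets: nothing significant
    res_all <- termEnrichment(bg, bg, ann)
    expect_false(any(res_all$significant))
})

test_that("uncorrected null false-positive rate is near the nominal level", {
    set.seed(99)
    bg <- sprintf("g%03d", 1:200)
    ann <- do.call(rbind, lapply(1:120, function(i)
        data.frame(gene = sample(bg, 40), term = sprintf("T:%03d", i))))
    test <- sample(bg, 30)  # no association with any term
    res <- termEnrichment(test, bg, ann)
    expect_equal(mean(res$significant), 0.05, tolerance = 0.06)
})

test_that("DCP edge scoring matches the stated conventions", {
    p <- writeToyObo(list(
        list(id = "root", is_a = character(0)),
        list(id = "A", is_a = "root"),
        list(id = "B", is_a = "A"),
        list(id = "C", is_a = "B"),
        list(id = "D", is_a = "root")))
    dag <- readObo(p)
    g <- graphFromPairs(c("g1-g2", "g1-g3", "g2-g4"))
    ## both genes on C at depth 3: DCP C, breadth 0, score 3
    gt <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     term = c("C", "C", "A", "D"))
    ann <- suppressMessages(goEdgeAnnotate(g, dag, gt))
    e12 <- ann[ann$node_a == "g1" & ann$node_b == "g2", ]
    expect_equal(e12[, c("dcp", "depth", "breadth", "score")],
                 data.frame(dcp = "C", depth = 3, breadth = 0, score = 3),
                 ignore_attr = TRUE)
    ## chain: g1 on C, g3 on A -> DCP A, depth 1, breadth 2, score -1
    e13 <- ann[ann$node_a == "g1" & ann$node_b == "g3", ]
    expect_equal(e13$dcp, "A")
    expect_equal(e13$score, -1)
    ## genes sharing only the root: score = -breadth <= 0
    e24 <- ann[ann$node_a == "g2" & ann$node_b == "g4", ]
    expect_equal(e24$dcp, "root")
    expect_equal(e24$score, -(3 + 1))
})

test_that("edges without annotation or common ancestor are dropped", {
    p <- writeToyObo(list(
        list(id = "r1", is_a = character(0)),
        list(id = "r2", is_a = character(0)),
        list(id = "A", is_a = "r1"),
        list(id = "B", is_a = "r2")))
    dag <- readObo(p)
    g <- graphFromPairs(c("g1-g2", "g1-g3"))
    gt <- data.frame(gene = c("g1", "g2"), term = c("A", "B"))
    expect_message(ann <- goEdgeAnnotate(g, dag, gt), "dropped")
    expect_equal(nrow(ann), 0L)  # no common root, no annotation for g3
})

test_that("DCP search agrees with exhaustive common-ancestor enumeration", {
    set.seed(12)
    ## random DAG: term i may have parents among earlier terms
    terms <- sprintf("t%02d", 1:12)
    spec <- lapply(seq_along(terms), function(i) {
        pool <- terms[seq_len(i - 1)]
        npar <- if (i == 1) 0 else sample(0:min(2, i - 1), 1, prob =
            c(0.2, rep(0.8 / min(2, i - 1), min(2, i - 1))))
        list(id = terms[i], is_a = if (npar) sample(pool, npar) else
            character(0))
    })
    dag <- readObo(writeToyObo(spec))
    genes <- sprintf("g%d", 1:6)
    gt <- do.call(rbind, lapply(genes, function(g)
        data.frame(gene = g, term = sample(terms, sample(1:3, 1)))))
    g <- graphFromPairs(c("g1-g2", "g2-g3", "g3-g4", "g4-g5", "g5-g6",
                          "g1-g6"))
    for (mode in c("sum", "max")) {
        ann <- suppressMessages(goEdgeAnnotate(g, dag, gt,
                                               breadthMode = mode))
        for (i in seq_len(nrow(ann))) {
            ta <- gt$term[gt$gene == ann$node_a[i]]
            tb <- gt$term[gt$gene == ann$node_b[i]]
            oracle <- bruteDcp(dag, ta, tb, breadthMode = mode)
            expect_equal(ann$score[i], oracle$score)
            expect_equal(ann$dcp[i], oracle$dcp)
        }
    }
})

test_that("gateway ranking averages incident annotated edge scores", {
    ann <- data.frame(
        node_a = c("gw1", "gw1", "x1", "gw2", "x2"),
        node_b = c("x1", "x2", "gw1", "x3", "gw3"),
        dcp = "t", depth = 1,
        breadth = 0, score = c(3, 3, 3, -1.5, 2))
    expect_message(rk <- rankGateways(c("gw1", "gw2", "gw3", "gw4"), ann),
                   "gw4")
    expect_equal(rk$node, c("gw1", "gw3", "gw2"))
    expect_equal(rk$degree, c(3L, 1L, 1L))
    expect_equal(rk$mean_score, c(3, 2, -1.5))
    ## brute-force recomputation over the raw edge table
    for (i in seq_len(nrow(rk))) {
        inc <- ann$node_a == rk$node[i] | ann$node_b == rk$node[i]
        expect_equal(rk$mean_score[i], mean(ann$score[inc]))
    }
})
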