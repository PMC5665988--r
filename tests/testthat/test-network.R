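test_that("median split mirrors the inclusive >=/<= rule", {
    sp <- medianSplit(letters[1:4], c(1, 2, 3, 4))
    expect_identical(sp$low, c("a", "b"))
    expect_identical(sp$high, c("c", "d"))
    ## 22 distinct values -> 11 + 11 disjoint
    sp22 <- medianSplit(sprintf("s%02d", 1:22), seq(0.1, 2.2, by = 0.1))
    expect_length(sp22$low, 11); expect_length(sp22$high, 11)
    expect_length(intersect(sp22$low, sp22$high), 0)
    ## odd n: the median station joins both groups
    sp21 <- medianSplit(sprintf("s%02d", 1:21), 1:21)
    expect_length(sp21$low, 11); expect_length(sp21$high, 11)
    expect_identical(intersect(sp21$low, sp21$high), "s11")
    expect_warning(medianSplit(letters[1:6], rep(2, 6)), "unequal")
    expect_error(medianSplit(letters[1:3], 1:3), "at least 4")
})

test_that("network construction applies both thresholds and the sign rule", {
    ids <- paste0("o", 1:4)
    corr <- diag(4); dimnames(corr) <- list(ids, ids)
    corr["o1", "o2"] <- corr["o2", "o1"] <- 0.9    # strong, significant
    corr["o3", "o4"] <- corr["o4", "o3"] <- -0.85  # strong, significant
    corr["o1", "o3"] <- corr["o3", "o1"] <- 0.95   # strong, NOT significant
    corr["o2", "o4"] <- corr["o4", "o2"] <- 0.5    # weak
    pv <- matrix(0.01, 4, 4, dimnames = list(ids, ids))
    pv["o1", "o3"] <- pv["o3", "o1"] <- 0.2
    net <- buildNetwork(corr, pv)
    e <- networkEdges(net)
    expect_identical(nrow(e), 2L)
    expect_setequal(e$sign, c("positive", "negative"))
    expect_identical(e$sign[e$otu_a == "o3"], "negative")
    ## nothing exceeds |r| = 1
    expect_identical(nrow(networkEdges(buildNetwork(corr, pv,
                                                    rThreshold = 1))), 0L)
    ## the printed-direction override keeps only non-significant edges
    flip <- buildNetwork(corr, pv, pDirection = "greater")
    expect_identical(networkEdges(flip)$otu_a, "o1")
    expect_identical(networkEdges(flip)$otu_b, "o3")
    expect_error(buildNetwork(corr, pv[1:3, 1:3]), "dimensions")
})

test_that("raising the correlation threshold never adds edges", {
    set.seed(31)
    n <- 10
    corr <- cor(matrix(rnorm(40 * n), 40, n))
    dimnames(corr) <- list(paste0("o", 1:n), paste0("o", 1:n))
    pv <- matrix(runif(n * n, 0, 0.1), n, n, dimnames = dimnames(corr))
    pv <- (pv + t(pv)) / 2
    prev <- Inf
    for (thr in c(0.1, 0.3, 0.5, 0.7)) {
        cnt <- nrow(networkEdges(buildNetwork(corr, pv, rThreshold = thr)))
        expect_lte(cnt, prev)
        prev <- cnt
    }
})

test_that("hand-computable topologies come out exactly", {
    triangle <- matrix(0, 3, 3); triangle[cbind(c(1, 2, 3), c(2, 3, 1))] <- 1
    triangle <- triangle + t(triangle)
    mt <- topologyMetrics(networkFromAdjacency(triangle))
    expect_equal(mt$density, 1)
    expect_equal(mt$clustering_coefficient, 1)
    expect_equal(mt$characteristic_path_length, 1)
    expect_equal(mt$centralization, 0)
    ## path on 4 nodes: pairs at distances 1,1,1,2,2,3
    p4 <- matrix(0, 4, 4); p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
    mp <- topologyMetrics(networkFromAdjacency(p4))
    expect_equal(mp$density, 0.5)
    expect_equal(mp$clustering_coefficient, 0)
    expect_equal(mp$characteristic_path_length, 10 / 6)
    expect_equal(mp$diameter, 3)
    ## star with 3 leaves: maximal degree centralization
    star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
    ms <- topologyMetrics(networkFromAdjacency(star))
    expect_equal(ms$centralization, 1)
    expect_equal(ms$avg_connected_neighbors, 2 * 3 / 4)
    ## edgeless network is an explicit error
    empty <- buildNetwork(diag(3), matrix(1, 3, 3))
    expect_error(topologyMetrics(empty), "no edges")
})

test_that("all metrics agree with brute-force enumeration on random graphs", {
    set.seed(32)
    for (rep in 1:12) {
        n <- sample(4:12, 1)
        adj <- matrix(0, n, n)
        adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.35)
        adj <- adj + t(adj)
        keep <- rowSums(adj) > 0
        if (sum(keep) < 2) next
        adj <- adj[keep, keep, drop = FALSE]
        net <- networkFromAdjacency(adj)
        mt <- topologyMetrics(net)
        oracle <- bruteTopology(adj)
        for (f in c("n_nodes", "n_edges", "avg_connected_neighbors",
                    "density", "centralization", "clustering_coefficient",
                    "characteristic_path_length", "diameter"))
            expect_equal(mt[[f]], oracle[[f]], tolerance = 1e-12,
                         label = f)
        ## igraph orders vertices by first appearance; match on node id
        ord <- as.integer(sub("OTU_", "", mt$nodeMetrics$id))
        expect_equal(unname(mt$nodeMetrics$betweenness),
                     oracle$betweenness[ord], tolerance = 1e-10)
        expect_equal(unname(mt$nodeMetrics$closeness),
                     oracle$closeness[ord], tolerance = 1e-12)
    }
})

test_that("network comparison tables are consistent and round-trip", {
    p4 <- matrix(0, 4, 4); p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
    net <- networkFromAdjacency(p4)
    cmp <- compareNetworks(net, net)
    expect_true(all(cmp$ratio_low_high[cmp$low != 0] == 1))
    dir <- withr::local_tempdir()
    writeTopologyTable(cmp, file.path(dir, "cmp.tsv"))
    back <- read.delim(file.path(dir, "cmp.tsv"))
    expect_equal(back$low, cmp$low)
    writeEdgeList(net, file.path(dir, "edges.tsv"))
    edges <- read.delim(file.path(dir, "edges.tsv"))
    expect_identical(nrow(edges), 3L)
    mt <- topologyMetrics(net)
    writeNodeMetrics(mt, file.path(dir, "nodes.tsv"))
    expect_equal(nrow(read.delim(file.path(dir, "nodes.tsv"))), 4)
})

test_that("isolated nodes can be folded back into the metrics", {
    ids <- paste0("o", 1:5)
    corr <- diag(5); dimnames(corr) <- list(ids, ids)
    corr["o1", "o2"] <- corr["o2", "o1"] <- 0.9
    pv <- matrix(0.01, 5, 5, dimnames = list(ids, ids))
    net <- buildNetwork(corr, pv)
    expect_equal(topologyMetrics(net)$n_nodes, 2)
    withIso <- topologyMetrics(net, includeIsolates = TRUE)
    expect_equal(withIso$n_nodes, 5)
    expect_equal(withIso$density, 2 * 1 / (5 * 4))
})
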