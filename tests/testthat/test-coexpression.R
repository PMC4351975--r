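test_that("power adjacency follows |r|^beta exactly", {
    r2 <- matrix(c(1, 0.5, 0.5, 1), 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
    expect_equal(powerAdjacency(r2, 1)["a", "b"], 0.5)
    r2[1, 2] <- r2[2, 1] <- -0.5
    expect_equal(powerAdjacency(r2, 5)["a", "b"], 0.03125)

    ## random 6x6 correlation fixture against element-wise evaluation
    x <- makeExactCorrData(40, diag(6) * 0.5 + 0.5, seed = 31)
    r <- cor(t(x))
    a <- powerAdjacency(x, 5)
    for (i in 1:6) for (j in 1:6) {
        expect_equal(a[i, j], if (i == j) 1 else abs(r[i, j])^5,
                     tolerance = 1e-12)
    }

    ## raising beta never increases an off-diagonal entry
    a1 <- powerAdjacency(x, 2); a2 <- powerAdjacency(x, 6)
    off <- upper.tri(a1)
    expect_true(all(a2[off] <= a1[off] + 1e-15))

    ## constant probes are named in the error
    bad <- rbind(x, flat = rep(1, ncol(x)))
    expect_error(powerAdjacency(bad, 5), "flat")
})

test_that("topological overlap matches direct formula evaluation", {
    ## 2-gene network: l = 0, k = a12 on both sides
    a2 <- matrix(c(1, 0.6, 0.6, 1), 2)
    expect_equal(tomSimilarity(a2)[1, 2], 0.6 / (0.6 + 1 - 0.6),
                 tolerance = 1e-12)

    ## no edges: off-diagonal TOM is zero
    expect_true(all(tomSimilarity(diag(4))[upper.tri(diag(4))] == 0))

    ## 3-gene hand case
    a3 <- matrix(c(1, 0.5, 0.2,
                   0.5, 1, 0.4,
                   0.2, 0.4, 1), 3, byrow = TRUE)
    expect_equal(tomSimilarity(a3), tomByHand(a3), tolerance = 1e-12)

    ## asymmetric input rejected
    bad <- a3; bad[1, 2] <- 0.9
    expect_error(tomSimilarity(bad), "symmetric")
})

test_that("TOM is symmetric and bounded on random adjacencies", {
    for (s in 1:100) {
        a <- randomAdjacency(6, seed = 100 + s)
        tm <- tomSimilarity(a)
        expect_true(isSymmetric(unname(tm)))
        expect_true(all(tm >= 0 & tm <= 1))
        expect_true(all(diag(tm) == 1))
    }
})

test_that("scale-free fit index is exact on a planted power law", {
    ## frequency proportional to k^-1: counts (64, 32, 16, 8) at
    ## connectivities (1, 2, 4, 8) are exactly log-log linear, each in
    ## its own equal-width bin
    k <- rep(c(1, 2, 4, 8), times = c(64, 32, 16, 8))
    fit <- scaleFreeFitIndex(k, nBreaks = 10)
    expect_equal(fit$scaleFreeR2, 1, tolerance = 1e-10)
    expect_equal(fit$slope, -1, tolerance = 1e-10)
})

test_that("soft-threshold selection is consistent and monotone", {
    sim <- generateCohorts(simulationConfig(
        nProbes = 150, moduleSpecs = defaultModuleSpecs()[1:3, ],
        seed = 32))
    res <- adjustCovariates(sim$cohortA)
    st <- pickSoftThreshold(res, powers = 1:8)
    expect_true(all(diff(st$table$meanK) < 0))
    if (!is.na(st$powerEstimate)) {
        expect_gte(st$powerEstimate, 1)
        ## the recommendation is the smallest power reaching the target
        hits <- st$table$power[!is.na(st$table$scaleFreeR2) &
                               st$table$scaleFreeR2 >= 0.8]
        expect_identical(st$powerEstimate, min(hits))
    }
    ## a tighter target can only raise (or NA) the recommendation
    st81 <- pickSoftThreshold(res, powers = 1:8, targetR2 = 0.81)
    if (!is.na(st81$powerEstimate) && !is.na(st$powerEstimate))
        expect_gte(st81$powerEstimate, st$powerEstimate)
    expect_error(pickSoftThreshold(res[1:10, ]), "20 probes")
})

test_that("separable blocks are recovered as correctly sized modules", {
    x <- twoBlockExpr(sizes = c(30, 20), n = 50, seed = 33)
    net <- buildCoexpressionNetwork(x, beta = 5)
    cm <- clusterModules(net, hierCutoff = 0.99, minModuleSize = 10)
    sz <- moduleSizes(cm$partition)
    expect_identical(length(sz), 2L)
    expect_identical(unname(sz), c(30L, 20L))
    expect_identical(names(sz), c("turquoise", "blue"))
    lab <- moduleLabels(cm$partition)
    ## block membership is exact
    expect_identical(length(unique(lab[sprintf("g%02d", 1:30)])), 1L)
    expect_identical(length(unique(lab[sprintf("g%02d", 31:50)])), 1L)
})

test_that("planted modules are recovered with high Rand agreement", {
    sim <- generateCohorts(simulationConfig(seed = 34))
    res <- adjustCovariates(sim$cohortA)
    net <- buildCoexpressionNetwork(res, beta = 5)
    cm <- clusterModules(net, 0.99, 10)
    ari <- adjustedRandIndex(moduleLabels(cm$partition),
                             sim$truth@partition)
    expect_gte(ari, 0.8)
    ## the minimum module size is honoured
    expect_true(all(moduleSizes(cm$partition) >= 10))
    ## identical input gives an identical partition
    cm2 <- clusterModules(net, 0.99, 10)
    expect_identical(moduleLabels(cm$partition),
                     moduleLabels(cm2$partition))
})

test_that("probe order does not change module membership", {
    x <- twoBlockExpr(sizes = c(15, 12), n = 40, seed = 35)
    ## tiny jitter so profiles within a block are not exact duplicates
    set.seed(35)
    x <- x + matrix(rnorm(length(x), sd = 0.05), nrow(x))
    net <- buildCoexpressionNetwork(x, beta = 5)
    cm <- clusterModules(net, 0.99, 5)
    perm <- sample(nrow(x))
    netP <- buildCoexpressionNetwork(x[perm, ], beta = 5)
    cmP <- clusterModules(netP, 0.99, 5)
    labA <- moduleLabels(cm$partition)
    labB <- moduleLabels(cmP$partition)[names(labA)]
    ## same co-membership structure (labels may permute)
    expect_equal(adjustedRandIndex(labA, labB), 1)
})

test_that("oversized minimum module size grays everything with a warning", {
    x <- twoBlockExpr(sizes = c(5, 4), n = 30, seed = 36)
    net <- buildCoexpressionNetwork(x, beta = 2)
    expect_warning(cm <- clusterModules(net, 0.99, 50), "gray")
    expect_true(all(moduleLabels(cm$partition) == "gray"))
})

test_that("intramodular connectivity and hubs match hand sums", {
    ## star: center tied to 10 leaves at 0.9, leaves mutually disconnected
    p <- 11
    a <- diag(p)
    a[1, 2:p] <- a[2:p, 1] <- 0.9
    dimnames(a) <- list(paste0("n", 1:p), paste0("n", 1:p))
    net <- new("WeightedNetwork", beta = 1, correlation = a,
               adjacency = a, tom = tomSimilarity(a))
    part <- partitionFromSets(list(star = rownames(a)))
    conn <- intramodularConnectivity(net, part)
    expect_identical(unname(conn$hubs["star"]), "n1")
    expect_equal(conn$probes["n1", "kTotal"], 9, tolerance = 1e-12)

    ## 4-gene toy: within-module sums against explicit arithmetic
    a4 <- matrix(c(1, 0.5, 0.3, 0.1,
                   0.5, 1, 0.2, 0.4,
                   0.3, 0.2, 1, 0.6,
                   0.1, 0.4, 0.6, 1), 4, byrow = TRUE,
                 dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
    net4 <- new("WeightedNetwork", beta = 1, correlation = a4,
                adjacency = a4, tom = tomSimilarity(a4))
    part4 <- partitionFromSets(list(m1 = c("g1", "g2"),
                                    m2 = c("g3", "g4")))
    conn4 <- intramodularConnectivity(net4, part4)
    expect_equal(conn4$probes["g1", "kWithinAdjacency"], 0.5,
                 tolerance = 1e-12)
    expect_equal(conn4$probes["g3", "kWithinAdjacency"], 0.6,
                 tolerance = 1e-12)
    expect_equal(conn4$probes["g2", "kTotal"], 0.5 + 0.2 + 0.4,
                 tolerance = 1e-12)
    ## hubs belong to their module
    members <- moduleMembers(part4)
    for (m in names(conn4$hubs))
        expect_true(conn4$hubs[m] %in% members[[m]])
})
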