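test_that("detection filter keeps exactly the qualifying probes", {
    set.seed(21)
    x <- matrix(rnorm(50 * 100), 50, 100,
                dimnames = list(sprintf("p%02d", 1:50),
                                sprintf("s%03d", 1:100)))
    ## plant per-probe detection counts spanning the 90% boundary
    detected <- sample(rep(c(100, 95, 90, 89, 50), each = 10))
    dp <- matrix(0.5, 50, 100, dimnames = dimnames(x))
    for (i in 1:50) dp[i, seq_len(detected[i])] <- 0.005

    out <- filterProbes(x, dp, pMax = 0.01, sampleFrac = 0.9)
    ## brute-force oracle: count qualifying samples per probe
    pass <- vapply(1:50, function(i) sum(dp[i, ] <= 0.01) >= 0.9 * 100,
                   logical(1))
    expect_identical(rownames(out), rownames(x)[pass])
    expect_identical(nrow(out), sum(detected >= 90))

    ## boundary: 89 of 100 detected is below 90% and must be removed
    expect_false(rownames(x)[which(detected == 89)[1]] %in% rownames(out))
    ## vacuous filter retains everything
    expect_identical(nrow(filterProbes(x, dp * 0, 0.01, 0.9)), 50L)
    ## misaligned matrices rejected
    expect_error(filterProbes(x, dp[, 1:99]), "dimensions")
})

test_that("covariate adjustment matches the normal equations", {
    ## 4-sample toy solved directly
    ages <- c(20, 30, 40, 50)
    y <- c(1, 2, 3, 5)
    x <- matrix(y, 1, 4, dimnames = list("g1", paste0("s", 1:4)))
    cov <- data.frame(age = ages, sex = c("F", "F", "F", "F"))
    D <- cbind(1, ages)  # sex is constant and dropped
    betaHat <- solve(t(D) %*% D, t(D) %*% y)
    oracle <- y - drop(D %*% betaHat)
    adj <- adjustCovariates(x, cov)
    expect_equal(unname(adj[1, ]), oracle, tolerance = 1e-12)

    ## constant covariates leave mean-centred expression
    covConst <- data.frame(age = rep(35, 4), sex = rep("M", 4))
    adjC <- adjustCovariates(x, covConst)
    expect_equal(unname(adjC[1, ]), y - mean(y), tolerance = 1e-12)
})

test_that("residuals are orthogonal to covariates and adjustment is idempotent", {
    sim <- generateCohorts(simulationConfig(
        nProbes = 60, moduleSpecs = defaultModuleSpecs()[1, , drop = FALSE],
        covariateEffects = c(age = 0.05, sex = 0.5), seed = 22))
    res <- adjustCovariates(sim$cohortA)
    x <- assay(res, "exprs")
    age <- colData(sim$cohortA)$age
    sexNum <- as.numeric(colData(sim$cohortA)$sex == "M")
    for (g in seq_len(nrow(x))) {
        expect_lt(abs(cor(x[g, ], age)), 1e-10)
        expect_lt(abs(cor(x[g, ], sexNum)), 1e-10)
    }
    twice <- adjustCovariates(res)
    expect_lt(max(abs(assay(twice, "exprs") - x)), 1e-10)
})

test_that("rank-deficient designs name the collinear columns", {
    x <- matrix(rnorm(8), 2, 4)
    rownames(x) <- c("g1", "g2")
    ## age perfectly aligned with sex coding -> collinear after intercept
    cov <- data.frame(age = c(1, 1, 2, 2), sex = c("F", "F", "M", "M"))
    expect_error(adjustCovariates(x, cov), "collinear")
})

test_that("differential expression matches the pooled t-test", {
    ## identical groups: null case
    a <- matrix(rep(c(10, 11, 12), each = 2), 2, 3,
                dimnames = list(c("g1", "g2"), paste0("a", 1:3)))
    de0 <- differentialExpression(a, a, a, a)
    expect_equal(de0$t, c(0, 0))
    expect_equal(de0$p, c(1, 1))
    expect_equal(de0$foldChange, c(1, 1))
    expect_false(any(de0$significant))

    ## 3 vs 3 toy against the textbook computation and t.test
    va <- c(10, 11, 12); vb <- c(13, 14, 15)
    A <- matrix(va, 1, 3, dimnames = list("g1", paste0("a", 1:3)))
    B <- matrix(vb, 1, 3, dimnames = list("g1", paste0("b", 1:3)))
    de <- differentialExpression(A, B, A, B)
    sp2 <- (2 * var(va) + 2 * var(vb)) / 4
    tHand <- (mean(vb) - mean(va)) / sqrt(sp2 * (1 / 3 + 1 / 3))
    expect_equal(de$t, tHand, tolerance = 1e-12)
    expect_equal(de$p, 2 * pt(-abs(tHand), 4), tolerance = 1e-12)
    tt <- t.test(vb, va, var.equal = TRUE)
    expect_equal(de$p, tt$p.value, tolerance = 1e-12)
    expect_equal(de$foldChange, mean(vb) / mean(va), tolerance = 1e-12)
    expect_identical(de$direction, "up")

    ## swapping cohorts inverts the fold change and negates t
    deSwap <- differentialExpression(B, A, B, A)
    expect_equal(deSwap$foldChange, 1 / de$foldChange, tolerance = 1e-12)
    expect_equal(deSwap$t, -de$t, tolerance = 1e-12)

    ## non-positive intensities are rejected
    expect_error(differentialExpression(A - 20, B, A, B), "non-positive")
})

test_that("planted mean shifts are recovered and nulls stay quiet", {
    ms <- data.frame(size = 40, lambdaA = 0, lambdaB = 0,
                     rhoTrait = 0, delta = 1)
    sim <- generateCohorts(simulationConfig(
        nProbes = 1000, moduleSpecs = ms,
        covariateEffects = c(age = 0, sex = 0), seed = 23))
    ## joint adjustment preserves the between-cohort shift
    adj <- adjustCovariatesJoint(sim$cohortA, sim$cohortB)
    de <- differentialExpression(sim$cohortA, sim$cohortB,
                                 adj$A, adj$B)
    planted <- sim$truth@deProbes
    expect_identical(length(planted), 40L)
    expect_true(all(de[planted, "significant"]))
    ## null probes: large-t exceedances co-move with the intensity fold
    ## change, so the gate holds the false rate near the t-test level
    falseFlags <- sum(de$significant[!rownames(de) %in% planted])
    expect_lt(falseFlags / 960, 0.06)
})

test_that("trait correlation reproduces the exact permutation law", {
    ## perfect monotone association
    x <- matrix(1:8, 1, 8, dimnames = list("g1", paste0("s", 1:8)))
    ph <- data.frame(S_I = (1:8)^2)
    tc <- traitCorrelation(x, ph, trait = "S_I")
    expect_equal(tc$rho, 1)

    ## n = 5 with a tie: rho and p against exhaustive enumeration;
    ## with mid-ranks for the tie, rho = 2 / sqrt(2.5 * 2.375)
    probe <- c(1, 2, 3, 4, 5)
    trait <- c(5, 6, 7, 8, 7)
    rhoOracle <- 2 / sqrt(2.5 * 2.375)
    expect_equal(cor(rank(probe), rank(trait)), rhoOracle,
                 tolerance = 1e-12)
    perms <- allPermutations(5)
    rhoNull <- vapply(perms, function(p)
        abs(cor(rank(probe), rank(trait)[p])), numeric(1))
    pOracle <- mean(rhoNull >= rhoOracle - 1e-12)
    x5 <- matrix(probe, 1, 5, dimnames = list("g1", paste0("s", 1:5)))
    tc5 <- traitCorrelation(x5, data.frame(S_I = trait), trait = "S_I")
    expect_equal(tc5$rho, rhoOracle, tolerance = 1e-12)
    expect_equal(tc5$p, pOracle, tolerance = 1e-12)

    ## constant probes are excluded from the ranking
    xc <- rbind(g1 = rep(1, 10), g2 = 1:10)
    colnames(xc) <- paste0("s", 1:10)
    tcc <- traitCorrelation(xc, data.frame(S_I = rnorm(10)), trait = "S_I")
    expect_true(is.na(tcc["g1", "rho"]))
    expect_true(is.na(tcc["g1", "q"]))
    expect_false(is.na(tcc["g2", "q"]))
})

test_that("null trait screens produce no FDR discoveries", {
    cfg <- simulationConfig(
        nProbes = 1000,
        moduleSpecs = data.frame(size = 50, lambdaA = 0.8, lambdaB = 0.8,
                                 rhoTrait = 0, delta = 0),
        seed = 24)
    sim <- generateCohorts(cfg)
    res <- adjustCovariates(sim$cohortA)
    tc <- traitCorrelation(res, trait = "S_I")
    expect_identical(sum(tc$associated), 0L)
})

test_that("Benjamini-Hochberg q-values follow the step-up rule", {
    expect_equal(bhFDR(0.03), 0.03)
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFDR(rep(1, 5)), rep(1, 5))
    expect_identical(bhFDR(numeric(0)), numeric(0))

    ## direct step-up evaluation oracle on random p-values
    set.seed(25)
    p <- runif(20)
    m <- length(p)
    ord <- order(p)
    stepUp <- numeric(m)
    stepUp[ord] <- rev(cummin(rev(p[ord] * m / seq_len(m))))
    expect_equal(bhFDR(p), pmin(1, stepUp), tolerance = 1e-12)

    ## monotonicity: raising one p-value never lowers any q-value
    p2 <- p
    p2[7] <- min(1, p2[7] + 0.2)
    expect_true(all(bhFDR(p2) >= bhFDR(p) - 1e-12))
})
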