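test_that("hypergeometric overlap matches exhaustive enumeration", {
    ## small universe: count all possible draws of set B directly
    N <- 12; sA <- 5; sB <- 4; k <- 3
    universe <- seq_len(N)
    setA <- seq_len(sA)
    draws <- combn(N, sB)
    exceed <- mean(apply(draws, 2, function(d)
        length(intersect(d, setA)) >= k))
    got <- overlapTestP(k, sA, sB, N)
    expect_equal(got$p, exceed, tolerance = 1e-12)

    ## zero overlap has upper-tail probability 1
    expect_equal(overlapTestP(0, 5, 4, 12)$p, 1)
})

test_that("module overlap table applies the Bonferroni rule symmetrically", {
    probes <- sprintf("p%03d", 1:100)
    pa <- partitionFromSets(list(a1 = probes[1:30], a2 = probes[31:50]),
                            grayProbes = probes[51:100])
    pb <- partitionFromSets(list(b1 = probes[c(1:20, 51:60)],
                                 b2 = probes[21:40]),
                            grayProbes = probes[c(41:50, 61:100)])
    ov <- moduleOverlap(pa, pb, alpha = 0.05)
    expect_identical(nrow(ov), 4L)
    expect_true(all(ov$bonferroniThreshold == 0.05 / 4))
    expect_identical(ov$significant, ov$fetP <= ov$bonferroniThreshold)
    row <- ov[ov$moduleA == "a1" & ov$moduleB == "b1", ]
    expect_identical(row$overlap, 20L)
    expect_equal(row$fetP,
                 phyper(19, 30, 70, 30, lower.tail = FALSE),
                 tolerance = 1e-12)

    ## swapping the partitions transposes the table, p-values unchanged
    ovT <- moduleOverlap(pb, pa, alpha = 0.05)
    key <- paste(ov$moduleA, ov$moduleB)
    keyT <- paste(ovT$moduleB, ovT$moduleA)
    expect_equal(ov$fetP, ovT$fetP[match(key, keyT)], tolerance = 1e-15)

    ## a universe smaller than a module is rejected
    expect_error(moduleOverlap(pa, pb, universe = 10), "universe")
})

test_that("log-space evaluation keeps extreme overlaps representable", {
    got <- overlapTestP(452, 1027, 1980, 17434)
    expect_gt(got$p, 0)
    expect_equal(got$log10p, log10(got$p), tolerance = 1e-9)
    ## far beyond double underflow the log10 tail is still finite
    deep <- overlapTestP(900, 1000, 1000, 20000)
    expect_true(is.finite(deep$log10p))
    expect_lt(deep$log10p, -300)
})

test_that("signature enrichment matches the closed-form point mass", {
    probes <- sprintf("p%04d", 1:1000)
    part <- partitionFromSets(list(m1 = probes[1:20]),
                              grayProbes = probes[21:1000])
    ## signature identical to the module: p is the single-table mass
    enr <- signatureEnrichment(part, list(sig = probes[1:20]), probes)
    oracle <- exp(lchoose(980, 0) + lchoose(20, 20) - lchoose(1000, 20))
    expect_equal(enr$fetP, oracle, tolerance = 1e-9)
    expect_equal(enr$correctedP, min(1, enr$fetP * 1))

    ## disjoint signature: p = 1
    enr0 <- signatureEnrichment(part, list(sig = probes[900:950]), probes)
    expect_equal(enr0$fetP, 1)

    ## members outside the universe are trimmed with a warning
    expect_warning(
        signatureEnrichment(part, list(sig = c(probes[1:5], "alien")),
                            probes),
        "trimmed")
})

test_that("random signatures rarely reach corrected significance", {
    set.seed(61)
    probes <- sprintf("p%04d", 1:400)
    part <- partitionFromSets(
        list(m1 = probes[1:40], m2 = probes[41:100]),
        grayProbes = probes[101:400])
    hits <- 0L
    for (i in 1:60) {
        sig <- list(s = sample(probes, 25))
        enr <- signatureEnrichment(part, sig, probes)
        if (any(enr$correctedP <= 0.05)) hits <- hits + 1L
    }
    expect_lte(hits / 60, 0.05 + 0.05)
})

test_that("conservation calls follow the overlap and enrichment rule", {
    ov <- data.frame(
        moduleA = c("m1", "m1", "m2", "m2"),
        moduleB = c("x", "y", "x", "y"),
        overlap = c(30, 1, 0, 2), sizeA = 40, sizeB = 40,
        universeN = 1000,
        fetP = c(1e-10, 0.9, 0.5, 0.7),
        log10P = NA_real_,
        bonferroniThreshold = 0.05 / 4,
        significant = c(TRUE, FALSE, FALSE, FALSE))
    enrBoth <- data.frame(module = c("m1", "m2"), signature = "si",
                          overlap = 5, moduleSize = 40,
                          signatureSize = 30,
                          fetP = c(1e-4, 0.3), log10P = NA,
                          correctedP = c(1e-3, 0.6))
    enrOnlyB <- data.frame(module = c("m1", "m2"), signature = "si",
                           overlap = 5, moduleSize = 40,
                           signatureSize = 30,
                           fetP = c(1e-4, 1e-5), log10P = NA,
                           correctedP = c(1e-3, 1e-4))
    calls <- classifyConservation(ov, enrBoth, enrOnlyB)
    expect_identical(calls$status[calls$module == "m1"], "conserved")
    ## m2: enriched only for cohort B's trait genes, no partner
    expect_identical(calls$status[calls$module == "m2"], "specific")
    expect_true(calls$highlySpecific[calls$module == "m2"])
    expect_identical(calls$bestPartner[calls$module == "m1"], "x")
    expect_error(classifyConservation(ov, enrBoth[1, ], enrOnlyB),
                 "m2")
})

test_that("planted shared and cohort-specific trait modules classify correctly", {
    ## five planted modules; the trait is wired to modules 1-3 in both
    ## cohorts and additionally to 4-5 only in cohort B
    sim <- generateCohorts(simulationConfig(
        nProbes = 300, nSamplesB = 80,
        moduleSpecs = data.frame(size = rep(40L, 5), lambdaA = 0.85,
                                 lambdaB = 0.85, rhoTrait = 0, delta = 0),
        seed = 62))
    loadA <- c(0.38, 0.38, -0.38, 0, 0)
    loadB <- c(0.38, 0.38, -0.38, 0.38, 0.38)
    seA <- sim$cohortA; seB <- sim$cohortB
    ## exact sample correlations so the planted wiring is realized
    colData(seA)$S_I <- exactTraitForFactors(sim$truth@factorsA, loadA,
                                             seed = 63)
    colData(seB)$S_I <- exactTraitForFactors(sim$truth@factorsB, loadB,
                                             seed = 64)
    resA <- adjustCovariates(seA)
    resB <- adjustCovariates(seB)
    part <- truthPartition(sim$truth)
    tcA <- traitCorrelation(resA, trait = "S_I")
    tcB <- traitCorrelation(resB, trait = "S_I")
    universe <- rownames(seA)
    ov <- moduleOverlap(part, part, universe = universe)
    enrA <- signatureEnrichment(part,
                                list(si_A = tcA$probe[tcA$associated]),
                                universe)
    enrB <- signatureEnrichment(part,
                                list(si_B = tcB$probe[tcB$associated]),
                                universe)
    calls <- classifyConservation(ov, enrA, enrB)
    got <- setNames(calls$status, calls$module)
    expect_identical(unname(got[c("M1", "M2", "M3")]),
                     rep("conserved", 3))
    expect_identical(unname(got[c("M4", "M5")]), rep("specific", 2))
})

test_that("GMT files round-trip", {
    sets <- list(alpha = c("p1", "p2", "p3"), beta = c("p4", "p5"))
    f <- withr::local_tempfile(fileext = ".gmt")
    writeGMT(sets, f, description = c("first", "second"))
    back <- readGMT(f)
    expect_identical(back, sets)
    writeLines("broken line without members", f)
    expect_error(readGMT(f), "malformed")
})
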