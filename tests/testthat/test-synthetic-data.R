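test_that("the generator is deterministic given config + seed", {
    cfg <- scenarioConfig(nOtus = 30, seed = 9)
    b1 <- simulateScenario(cfg)
    b2 <- simulateScenario(cfg)
    expect_identical(otuCounts(b1@otu), otuCounts(b2@otu))
    expect_identical(b1@stations, b2@stations)
    expect_identical(b1@winds, b2@winds)
    expect_identical(b1@trueNcp, b2@trueNcp)
    ## stages regenerate in isolation from their own substream
    expect_identical(generateCompositions(cfg)$counts, otuCounts(b1@otu))
})

test_that("counts close to the drawn depths; depths track meanDepth", {
    cfg <- scenarioConfig(nStations = 500, nOtus = 50, seed = 2)
    comp <- generateCompositions(cfg)
    expect_equal(unname(colSums(comp$counts)), comp$depths)
    expect_lt(abs(mean(comp$depths) / cfg@meanDepth - 1), 0.05)
    expect_true(all(comp$counts >= 0))
    expect_true(all(comp$counts == round(comp$counts)))
})

test_that("rank-abundance is non-increasing under sorted dominance weights", {
    cfg <- scenarioConfig(nStations = 100, nOtus = 40, basisLogSd = 0.3,
                          seed = 3)
    comp <- generateCompositions(cfg)
    meanRel <- rowMeans(sweep(comp$counts, 2, colSums(comp$counts), `/`))
    ## allow tiny multinomial jitter between near-equal neighbours
    expect_true(all(diff(meanRel) < 1e-3))
    ## hyperdominance: top-20 of the default 464-OTU spectrum near 78%
    w <- scenarioConfig()@dominanceWeights
    expect_equal(sum(w[1:20]) / sum(w), 0.78, tolerance = 0.005)
})

test_that("log-basis correlation structure is what the config planted", {
    ## diagonal covariance: all sample correlations near zero
    cfg <- scenarioConfig(nStations = 200, nOtus = 12, basisLogSd = 1,
                          seed = 4,
                          plantedEffects = data.frame(otu = integer(),
                                                      beta = numeric()))
    comp <- generateCompositions(cfg)
    logBasis <- t(log(comp$basis))
    cors <- cor(logBasis)
    expect_lt(max(abs(cors[upper.tri(cors)])), 0.2)
    expect_equal(comp$trueBasisCorrelations, diag(12),
                 ignore_attr = TRUE)
    ## planted 0.9 pair recovered in the sample log basis
    corr <- diag(12); corr[1, 2] <- corr[2, 1] <- 0.9
    cfg2 <- scenarioConfig(nStations = 200, nOtus = 12, basisLogSd = 1,
                           basisCorrelation = corr, seed = 4,
                           plantedEffects = data.frame(otu = integer(),
                                                       beta = numeric()))
    comp2 <- generateCompositions(cfg2)
    r12 <- cor(log(comp2$basis[1, ]), log(comp2$basis[2, ]))
    expect_gt(r12, 0.8); expect_lt(r12, 0.97)
    expect_equal(comp2$trueBasisCorrelations[1, 2], 0.9)
    ## non-PSD covariance is rejected
    bad <- diag(12); bad[1, 2] <- bad[2, 1] <- 2
    expect_error(generateCompositions(
        scenarioConfig(nOtus = 12, basisCorrelation = bad, seed = 1,
                       plantedEffects = data.frame(otu = integer(),
                                                   beta = numeric()))),
        "positive semi-definite")
})

test_that("the planted NCP link is an exact sparse linear model", {
    ## noiseless single effect: regression recovers slope 5, R2 = 1
    cfg <- scenarioConfig(nStations = 30, nOtus = 15, noiseSd = 0,
                          plantedEffects = data.frame(otu = 1L, beta = 5),
                          seed = 6)
    comp <- generateCompositions(cfg)
    link <- plantNcpLink(comp$counts, cfg)
    rel <- t(sweep(comp$counts, 2, colSums(comp$counts), `/`)) * 100
    z1 <- as.numeric(scale(rel[, 1]))
    fit <- lm(link$trueNcp ~ z1)
    expect_equal(unname(coef(fit)["z1"]), 5, tolerance = 1e-9)
    expect_equal(suppressWarnings(summary(fit)$r.squared), 1,
                 tolerance = 1e-12)
    expect_equal(sum(link$trueEffects != 0), 1L)
    ## three planted effects -> exactly three nonzeros
    link3 <- plantNcpLink(comp$counts, scenarioConfig(nStations = 30,
        nOtus = 15, seed = 6))
    expect_equal(sum(link3$trueEffects != 0), 3L)
    ## null scenario: NCP uncorrelated with every OTU at large n
    cfg0 <- scenarioConfig(nStations = 400, nOtus = 15, noiseSd = 1,
                           plantedEffects = data.frame(otu = integer(),
                                                       beta = numeric()),
                           seed = 7)
    comp0 <- generateCompositions(cfg0)
    link0 <- plantNcpLink(comp0$counts, cfg0)
    rel0 <- t(sweep(comp0$counts, 2, colSums(comp0$counts), `/`))
    expect_lt(max(abs(cor(link0$trueNcp, rel0))), 0.2)
    ## POC positive always
    expect_true(all(link0$poc > 0))
    ## zero-variance planted predictor is an explicit error
    mono <- comp$counts; mono[2, ] <- 0
    expect_error(plantNcpLink(mono, scenarioConfig(nStations = 30,
        nOtus = 15, plantedEffects = data.frame(otu = 2L, beta = 1),
        seed = 1)), "zero-variance")
})

test_that("station environment honours the configured physics", {
    cfg <- scenarioConfig(seed = 8)
    env <- generateStationEnvironment(cfg)
    expect_true(all(env$stations$mld >= 11 & env$stations$mld <= 22))
    expect_identical(dim(env$winds), c(21L, 60L))
    ## profile threshold-MLD equals the drawn MLD exactly
    for (i in c(1, 10, 21)) {
        pr <- env$profiles[env$profiles$station_id ==
                           env$stations$station_id[i], ]
        expect_equal(mixedLayerDepth(pr$depth_m, pr$sigma_theta),
                     env$stations$mld[i], tolerance = 1e-9)
    }
    ## degenerate AR(1): zero innovation sd gives constant wind at the mean
    cfg0 <- scenarioConfig(windAr1 = c(7, 0, 0), seed = 8)
    env0 <- generateStationEnvironment(cfg0)
    expect_true(all(env0$winds == 7))
    ## seeded rerun byte-identical
    expect_identical(generateStationEnvironment(cfg)$stations,
                     env$stations)
})

test_that("tables and truth round-trip through the plain-text writers", {
    bundle <- simulateScenario(scenarioConfig(nOtus = 20, seed = 10))
    dir <- withr::local_tempdir()
    sp <- file.path(dir, "stations.csv")
    writeStationTable(bundle@stations, sp)
    st <- readStationTable(sp)
    expect_equal(st$mld, bundle@stations$mld)
    expect_identical(st$station_id, bundle@stations$station_id)
    writeScenarioTruth(bundle, dir)
    eff <- read.csv(file.path(dir, "true_effects.csv"))
    expect_equal(sum(eff$beta != 0), 3)
})
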