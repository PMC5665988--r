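test_that("OLS coefficients match the normal-equations oracle", {
    set.seed(11)
    for (rep in 1:20) {
        n <- sample(8:25, 1); p <- sample(1:4, 1)
        X <- matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("x", seq_len(p))))
        y <- rnorm(n)
        fit <- fitMlr(X, y)
        expect_equal(unname(fit$coefficients), unname(bruteOls(X, y)),
                     tolerance = 1e-10)
        expect_lte(fit$adj_r2, fit$r2)
    }
})

test_that("fit statistics behave at the noiseless and orthogonal extremes", {
    set.seed(12)
    X <- matrix(rnorm(15 * 2), 15, 2, dimnames = list(NULL, c("a", "b")))
    yExact <- 2 + 3 * X[, 1] - X[, 2]
    fit <- fitMlr(X, yExact)
    expect_equal(fit$r2, 1, tolerance = 1e-12)
    expect_equal(fit$rss, 0, tolerance = 1e-18)
    ## construct y orthogonal to the column space (pure residual)
    D <- cbind(1, X)
    proj <- D %*% solve(crossprod(D)) %*% t(D)
    yOrth <- (diag(15) - proj) %*% rnorm(15)
    expect_lt(fitMlr(X, yOrth)$r2, 1e-12)
    ## rank deficiency names the collinear column
    Xdup <- cbind(X, dup = X[, 1])
    expect_error(fitMlr(Xdup, yExact), "dup")
})

test_that("AICc applies the small-sample correction", {
    ## n = 21, 3 coefficients + variance -> k = 4, correction 2*4*5/16 = 2.5
    rss <- 7.3
    aic <- 21 * log(rss / 21) + 2 * 4
    expect_equal(aicc(rss, 21, 3), aic + 2.5)
    ## positive correction for any k; vanishes as n grows
    expect_gt(aicc(rss, 21, 2), 21 * log(rss / 21) + 2 * 3)
    bigN <- 1e7
    expect_equal(aicc(rss, bigN, 3) - (bigN * log(rss / bigN) + 8), 0,
                 tolerance = 1e-4)
    expect_error(aicc(rss, 5, 4), "undefined")
})

test_that("forward stepwise under AICc finds planted structure and stops on noise", {
    set.seed(13)
    X <- matrix(rnorm(21 * 10), 21, 10,
                dimnames = list(NULL, paste0("x", 1:10)))
    y <- 6 * X[, 3] + rnorm(21, 0, 0.8)
    sw <- forwardStepwiseAicc(X, y)
    expect_identical(sw$trace$added[2], "x3")      # enters at step 1
    expect_true(all(diff(sw$trace$aicc) < 0))      # AICc strictly improves
    ## pure noise: the stopping rule keeps the model at or near null
    yNoise <- rnorm(21)
    sw0 <- forwardStepwiseAicc(X, yNoise)
    if (length(sw0$selected))
        expect_lt(sw0$model$aicc, aicc(sum((yNoise - mean(yNoise))^2), 21, 1))
    expect_lte(length(sw0$selected), 2)
})

test_that("stepwise confirms the SSVS selection on the default scenario", {
    agree <- 0
    for (s in 1:5) {
        bundle <- simulateScenario(scenarioConfig(nOtus = 60,
                                                  seed = 500 + s))
        panel <- topKOtus(bundle@otu, 20)
        X <- relativeAbundance(bundle@otu)[, panel]
        fit <- ssvsFit(X, trueNcp(bundle),
                       ssvsConfig(iterations = 4000, burnIn = 2000,
                                  seed = s))
        sw <- forwardStepwiseAicc(X, trueNcp(bundle))
        if (all(selectedPredictors(fit) %in% sw$selected)) agree <- agree + 1
    }
    expect_gte(agree, 4)
})

test_that("variance partitioning solves the inclusion-exclusion system", {
    ## orthogonal designs: shared fraction ~ 0, uniques ~ marginal adj R2
    ## (the adjustment makes these approximate at order 1/n)
    n <- 400
    x1 <- rep(c(1, -1), n / 2); x2 <- rep(c(1, 1, -1, -1), n / 4)
    X <- cbind(a = x1, b = x2)
    set.seed(14)
    y <- 2 * x1 + 1 * x2 + rnorm(n, 0, 0.5)
    vp <- variancePartition(y, list(A = "a", B = "b"), X)
    expect_lt(abs(vp$fractions["A&B"]), 0.01)
    expect_equal(unname(vp$fractions["A"]),
                 fitMlr(X[, "a", drop = FALSE], y)$adj_r2, tolerance = 0.05)
    ## recomposition identity to 1e-9, also for three sets
    expect_equal(sum(vp$fractions), vp$totalAdjR2, tolerance = 1e-9)
    X3 <- cbind(X, c = rnorm(n))
    y3 <- y + 0.5 * X3[, "c"]
    vp3 <- variancePartition(y3, list(A = "a", B = "b", C = "c"), X3)
    expect_equal(sum(vp3$fractions), vp3$totalAdjR2, tolerance = 1e-9)
    expect_length(vp3$fractions, 7)
    expect_error(variancePartition(y, list(A = "a", B = c("a", "b")), X),
                 "disjoint")
})

test_that("variance partitioning agrees with vegan::varpart", {
    skip_if_not_installed("vegan")
    set.seed(15)
    n <- 30
    X <- matrix(rnorm(n * 4), n,
                dimnames = list(NULL, c("a", "b", "c", "d")))
    y <- X %*% c(2, 1, -1, 0.5) + rnorm(n)
    vp <- variancePartition(y, list(S1 = c("a", "b"), S2 = c("c", "d")), X)
    vv <- vegan::varpart(y, X[, c("a", "b")], X[, c("c", "d")])
    ind <- vv$part$indfract$Adj.R.squared
    ## vegan order: [a] unique X1, [b] unique X2, [c] shared
    expect_equal(unname(vp$fractions[c("S1", "S2", "S1&S2")]),
                 ind[1:3], tolerance = 1e-8)
})

test_that("the univariate scan equals squared Pearson correlation", {
    set.seed(16)
    X <- matrix(rnorm(21 * 4), 21,
                dimnames = list(NULL, paste0("t", 1:4)))
    y <- X[, 1] * 2 + rnorm(21)
    scan <- simpleR2Scan(X, y)
    expect_equal(scan$r2, as.numeric(cor(X, y))^2, tolerance = 1e-12)
    exact <- suppressWarnings(simpleR2Scan(cbind(z = y), y))
    expect_equal(exact$r2, 1)
    flag <- simpleR2Scan(cbind(ok = X[, 1], const = rep(1, 21)), y)
    expect_true(flag$flagged[2] && is.na(flag$r2[2]))
})

test_that("null p-values from the scan are uniform", {
    set.seed(17)
    pvals <- replicate(500, {
        simpleR2Scan(cbind(x = rnorm(21)), rnorm(21))$p_value
    })
    ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.01)
})
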