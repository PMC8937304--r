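test_that("linear-sum pairs reproduce hand-computed means and sems", {
    ## single-ROI session: a-trials {0.7, 1.3} (mean 1), b-trials {1.5, 2.5}
    ## (mean 2), mixture trials {1.9, 2.1} (mean 2)
    rm <- exactResponseMatrix(list(
        "EB" = list(0.7, 1.3), "MB" = list(1.5, 2.5),
        "EB+MB" = list(1.9, 2.1)))
    pr <- linearSumPairs(rm, "EB", "MB")
    expect_equal(pr$rObserved, 2)
    expect_equal(pr$rLinear, 3)
    semA <- sd(c(0.7, 1.3)) / sqrt(2)
    semB <- sd(c(1.5, 2.5)) / sqrt(2)
    expect_equal(pr$semLinear, semA + semB)
    expect_equal(pr$nTrialsMixture, 2L)
    ## sems add: 0.3 + 0.2 = 0.5 on an independent construction
    expect_equal(deviationFromLinearity(3, 1, 0.5, 0.5), 2)
    expect_error(linearSumPairs(rm, "EB", "MV"), "insufficient")
})

test_that("fractional deviation follows its defining formula", {
    expect_equal(fractionalDeviation(1, 1), 0, ignore_attr = TRUE)
    expect_equal(fractionalDeviation(0.61, 1), -0.39, ignore_attr = TRUE)
    ## sign handling with a negative linear sum, against the formula
    ## evaluated literally: (2 - (-1)) / |-1| = 3
    expect_equal(fractionalDeviation(2, -1), 3, ignore_attr = TRUE)
    ## scale invariance: multiplying all amplitudes by k > 0
    set.seed(4)
    obs <- rnorm(50); lin <- rnorm(50, 1)
    fd1 <- fractionalDeviation(obs, lin, floor = 0)
    fd2 <- fractionalDeviation(5.7 * obs, 5.7 * lin, floor = 0)
    expect_equal(fd1, fd2, tolerance = 1e-12)
    ## exclusion floor marks small linear sums as NA
    fd <- fractionalDeviation(c(1, 1), c(0.01, 1))
    expect_true(is.na(fd[1]) && !is.na(fd[2]))
    expect_equal(attr(fd, "excluded"), c(TRUE, FALSE))
})

test_that("joint-sem deviation classifies a panel like a brute-force tally", {
    expect_equal(deviationFromLinearity(5, 5, 0.1, 0.3), 0)
    set.seed(5)
    obs <- rnorm(200); lin <- rnorm(200)
    s1 <- runif(200, 0.01, 0.3); s2 <- runif(200, 0.01, 0.3)
    dev <- deviationFromLinearity(obs, lin, s1, s2)
    cls <- classifyLinearity(dev)
    ## independent tally loop
    nSub <- 0L; nLin <- 0L; nSup <- 0L
    for (i in seq_len(200)) {
        z <- (obs[i] - lin[i]) / (s1[i] + s2[i])
        if (z < -2) nSub <- nSub + 1L
        else if (z > 2) nSup <- nSup + 1L
        else nLin <- nLin + 1L
    }
    expect_equal(unname(table(cls)), c(nSub, nLin, nSup), ignore_attr = TRUE)
    expect_warning(deviationFromLinearity(1, 2, 0, 0), "zero joint")
})

test_that("noiseless linear sessions classify 100% linear with zero medians", {
    p <- makePanel(50, 3, c(0.6, 0.3), seed = 51)
    st <- StateProfile("lin", gain = 1, trialNoiseSd = 0, summation = "linear")
    cfg <- syntheticConfig(makeTrialList(p, 3, seed = 52), seed = 53,
                           frameNoiseSd = 0)
    rm <- buildResponseMatrix(simulateSession(p, st, cfg))
    pr <- linearSumPairs(rm)
    fd <- fractionalDeviation(pr)
    expect_equal(max(abs(fd), na.rm = TRUE), 0, tolerance = 1e-10)
    dev <- suppressWarnings(deviationFromLinearity(pr))
    expect_true(all(classifyLinearity(dev[!is.na(dev)]) == "linear"))
    expect_equal(medianFractionalDeviation(pr)$pooled$median, 0,
                 tolerance = 1e-10)
})

test_that("saturating sessions are sublinear where linear sessions are not", {
    mk <- function(summation, seed) {
        p <- makePanel(200, 3, c(0.7, 0.3), seed = seed)
        st <- StateProfile("s", gain = 1, trialNoiseSd = 0.2,
                           summation = summation)
        cfg <- syntheticConfig(makeTrialList(p, 4, seed = seed + 1),
                               seed = seed + 2)
        fractionalDeviation(
            linearSumPairs(buildResponseMatrix(simulateSession(p, st, cfg))))
    }
    fdSat <- mk(NormalisationParams(6, 0.2), 61)
    fdLin <- mk("linear", 71)
    ## sign test at 200 ROIs: saturating median clearly negative (its
    ## magnitude varies with the masker's drawn potency)
    expect_lt(median(fdSat, na.rm = TRUE), -0.05)
    expect_gt(sum(fdSat < 0, na.rm = TRUE), 0.8 * sum(!is.na(fdSat)))
    expect_lt(abs(median(fdLin, na.rm = TRUE)), 0.05)
})

test_that("per-field medians use the midpoint convention and pool fields", {
    pr <- data.frame(rObserved = c(0.5, 0.61, 1.1), rLinear = c(1, 1, 1),
                     semObserved = 0.1, semLinear = 0.1, fovId = "f1")
    out <- medianFractionalDeviation(pr)
    expect_equal(out$perField$median, -0.39)
    ## single ROI: that value; even count: midpoint, against a sort oracle
    pr2 <- data.frame(rObserved = c(2, 1, 1.5, 0.8), rLinear = 1,
                      semObserved = 0.1, semLinear = 0.1,
                      fovId = c("a", rep("b", 3)))
    out2 <- medianFractionalDeviation(pr2)
    expect_equal(out2$perField$median[out2$perField$fovId == "a"], 1)
    bVals <- sort(c(0, 0.5, -0.2))
    expect_equal(out2$perField$median[out2$perField$fovId == "b"], bVals[2])
    expect_equal(out2$pooled$nFields, 2L)
    evens <- sort(c(-0.4, -0.1, 0.2, 0.6))
    prE <- data.frame(rObserved = 1 + evens, rLinear = 1, semObserved = 0.1,
                      semLinear = 0.1, fovId = "e")
    expect_equal(medianFractionalDeviation(prE)$perField$median,
                 mean(evens[2:3]))
    ## all ROIs excluded in a field is an error
    prX <- data.frame(rObserved = 1, rLinear = 0.001, semObserved = 0.1,
                      semLinear = 0.1, fovId = "x")
    expect_error(medianFractionalDeviation(prX), "empty field")
})

test_that("joint sem shrinks like sqrt(n) under trial resampling", {
    p <- makePanel(40, 3, c(0.6, 0.3), seed = 81)
    st <- statePreset("anaesthetised")
    mkPairs <- function(nBlocks, seed) {
        cfg <- syntheticConfig(makeTrialList(p, nBlocks, seed = seed),
                               seed = seed + 1)
        linearSumPairs(buildResponseMatrix(simulateSession(p, st, cfg)))
    }
    s4 <- mean(mkPairs(4, 91)$semLinear)
    s16 <- mean(mkPairs(16, 95)$semLinear)
    expect_equal(s4 / s16, 2, tolerance = 0.35)
})

test_that("added Gaussian noise broadens deviations without moving the median", {
    s <- quickSession("anaesthetised", nRois = 120, nBlocks = 6, seed = 101)
    rm <- buildResponseMatrix(s$trials)
    nr <- noiseRobustness(rm, noiseSds = c(0, 0.4, 0.8), nReps = 100,
                          seed = 102)
    sm <- nr$summary[order(nr$summary$noiseSd), ]
    ## SD = 0 reproduces the unperturbed deviations exactly
    base <- fractionalDeviation(linearSumPairs(rm))
    d0 <- nr$deviations$deviation[nr$deviations$noiseSd == 0]
    expect_equal(unname(d0), unname(as.numeric(base)))
    ## IQR broadens with noise; the median moves by less than twice the
    ## Monte-Carlo jitter of the median itself
    expect_true(all(diff(sm$iqrMean) > 0))
    for (k in 2:3)
        expect_lt(abs(sm$medianMean[k] - sm$medianMean[1]),
                  2 * sm$medianSd[k])
    expect_error(noiseRobustness(rm, noiseSds = -1), "nonnegative")
    ## numerator-only noise: broadening with an unbiased median
    nrM <- noiseRobustness(rm, noiseSds = c(0, 0.3, 0.6), nReps = 100,
                           seed = 103, applyTo = "mixture")
    smM <- nrM$summary[order(nrM$summary$noiseSd), ]
    expect_true(all(diff(smM$iqrMean) > 0))
    for (k in 2:3)
        expect_lt(abs(smM$medianMean[k] - smM$medianMean[1]),
                  2 * smM$medianSd[k])
})

test_that("masking index measures clipped overlap on target glomeruli", {
    ## 20 glomeruli; target pattern strong on the first 3 (z > 2 there)
    tgt <- c(10, 10, 10, rep(0, 17))
    mk <- function(bg) exactResponseMatrix(list(
        "EB" = list(tgt, tgt, tgt), "MB" = list(bg, bg, bg)))
    ## identical pattern: index 1 (the per-glomerulus maximum)
    expect_equal(maskingIndex(mk(tgt))$maskingIndex, c(1, 1))
    ## orthogonal pattern (zero on target glomeruli): 0
    orth <- c(0, 0, 0, rep(3, 17))
    mi <- maskingIndex(mk(orth))
    expect_equal(mi$maskingIndex[mi$odourId == "MB"], 0)
    expect_equal(unique(mi$nTargetGlomeruli), 3L)
    ## half-amplitude pattern: 0.5, identically under both overlap rules
    expect_equal(maskingIndex(mk(tgt / 2))$maskingIndex[2], 0.5)
    expect_equal(maskingIndex(mk(tgt / 2), overlap = "min")$maskingIndex[2],
                 0.5)
    ## negative background responses clip to zero overlap
    expect_equal(maskingIndex(mk(-tgt))$maskingIndex[2], 0)
    ## guards: trial count and responsive-set existence
    rmShort <- exactResponseMatrix(list("EB" = list(tgt, tgt, tgt),
                                        "MB" = list(tgt)))
    expect_error(maskingIndex(rmShort), "fewer than 3")
    flat <- rep(1, 20)
    expect_error(maskingIndex(mk2 <- exactResponseMatrix(list(
        "EB" = list(flat, flat, flat), "MB" = list(flat, flat, flat)))),
        "no target-responsive")
})
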