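test_that("the saturating transform matches its closed form", {
    expect_equal(normaliseResponse(0), 0)
    expect_equal(normaliseResponse(1e9), 6)             # ceiling Rmax
    expect_equal(normaliseResponse(5, NormalisationParams(6, 0.2)),
                 6 * (2 / (1 + exp(-1)) - 1))
    ## odd, strictly monotone, bounded
    r <- seq(-40, 40, by = 0.5)
    v <- normaliseResponse(r)
    expect_equal(v, -rev(v), tolerance = 1e-12)
    expect_true(all(diff(v) > 0))
    expect_true(all(abs(v) < 6))
    ## derivative at 0 equals Rmax * s / 2
    h <- 1e-6
    expect_equal((normaliseResponse(h) - normaliseResponse(-h)) / (2 * h),
                 6 * 0.2 / 2, tolerance = 1e-6)
    expect_error(NormalisationParams(-1, 0.2), "positive")
})

test_that("normalisation parameters are recovered from noisy pairs", {
    set.seed(16)
    lin <- runif(200, -2, 18)          # spans the bend of the curve
    obs <- normaliseResponse(lin, NormalisationParams(6, 0.2)) +
        rnorm(200, 0, 0.25)
    fit <- fitNormalisation(data.frame(rLinear = lin, rObserved = obs))
    expect_true(fit$identifiable)
    expect_equal(Rmax(fit$params), 6, tolerance = 0.1)
    expect_equal(slopeParam(fit$params), 0.2, tolerance = 0.1)
    ## noiseless data leave essentially no residuals
    fit0 <- fitNormalisation(data.frame(
        rLinear = lin, rObserved = normaliseResponse(lin)))
    expect_lt(fit0$residualSd, 1e-6)
    ## purely linear shallow data cannot pin the ceiling
    linS <- runif(100, -1, 1)
    expect_warning(
        fitL <- fitNormalisation(data.frame(rLinear = linS,
                                            rObserved = 0.6 * linS)),
        "not identifiable")
    expect_false(fitL$identifiable)
    expect_error(fitNormalisation(data.frame(rLinear = 1:5,
                                             rObserved = 1:5)),
                 "at least 10")
})

test_that("noise slope regression recovers constructed dispersion scaling", {
    ## build trials whose per-ROI SD is exactly 0.1 + 0.3 * mean
    set.seed(17)
    nRois <- 60
    mu <- runif(nRois, 0.5, 5)
    trials <- lapply(1:12, function(i)
        stepTrial(rnorm(nRois, mu, 0.1 + 0.3 * mu), stimulus = "EB"))
    rm <- buildResponseMatrix(trials)
    nm <- fitNoiseSlope(rm, sigma0 = 0.2)
    expect_equal(nm@slope, 0.3, tolerance = 0.25)
    expect_equal(nm@sigma0, 0.2)
    ## homoscedastic data: slope near zero (possibly clipped)
    trialsH <- lapply(1:12, function(i)
        stepTrial(rnorm(nRois, mu, 0.4), stimulus = "EB"))
    nmH <- suppressWarnings(fitNoiseSlope(buildResponseMatrix(trialsH),
                                          sigma0 = 2))
    expect_lt(nmH@slope, 0.08)
    expect_error(fitNoiseSlope(buildResponseMatrix(
        list(stepTrial(1:3), stepTrial(2:4))), 0.2), "insufficient")
})

test_that("the identity condition reproduces plain decoder accuracy", {
    s <- quickSession("anaesthetised", nRois = 50, nBlocks = 3, seed = 161)
    rm <- buildResponseMatrix(s$trials)
    noNoise <- NoiseModel(sigma0 = 0, slope = 0)
    lin <- simulateMixtureTest(rm, NULL, noNoise, nReps = 3, seed = 162)
    ## oracle: train on singles, classify the exact linear sums directly
    lab <- trialLabels(rm)
    single <- lab$nComponents == 1L
    dec <- trainLinearDecoder(amplitudes(rm)[single, , drop = FALSE],
                              lab$targetPresent[single])
    odours <- unique(lab$stimulus[single])
    means <- vapply(odours, function(o)
        colMeans(amplitudes(rm)[single & lab$stimulus == o, , drop = FALSE]),
        numeric(ncol(amplitudes(rm))))
    combos <- combn(odours, 2)
    sums <- t(vapply(seq_len(ncol(combos)), function(k)
        means[, combos[1, k]] + means[, combos[2, k]],
        numeric(nrow(means))))
    oracle <- mean(predict(dec, sums) ==
                   apply(combos, 2, function(p) "EB" %in% p))
    expect_equal(unique(as.numeric(accuracies(lin))), oracle)
    ## vanishing slope with Rmax*s/2 = 1 rescaling converges to identity
    nearIdentity <- NormalisationParams(Rmax = 2 / 1e-4, s = 1e-4)
    sub <- simulateMixtureTest(rm, nearIdentity, noNoise, nReps = 3,
                               seed = 162)
    expect_equal(accuracies(sub), accuracies(lin))
})

test_that("accuracy ratios and phase summaries follow their definitions", {
    mk <- function(vals) new("DecodingResult",
                             timePoints = c(0.5, 1, 2, 3),
                             accuracy = matrix(vals, 2, 4, byrow = TRUE),
                             splitSpec = "simulated_mixture_linear",
                             nSplits = 2L, seed = 1L, fovId = "f")
    a <- mk(rep(c(0.8, 0.8, 0.8, 0.8), 2))
    expect_equal(accuracyRatio(a, a)$timecourse$ratio, rep(1, 4))
    half <- mk(rep(c(0.4, 0.4, 0.4, 0.4), 2))
    ar <- accuracyRatio(half, a)
    expect_equal(ar$timecourse$ratio, rep(0.5, 4))
    expect_equal(ar$early, 0.5)
    expect_equal(ar$late, 0.5)
    ## zero-baseline bins are dropped with a warning
    z <- mk(rep(c(0, 0.8, 0.8, 0.8), 2))
    expect_warning(arz <- accuracyRatio(a, z), "zero baseline")
    expect_true(is.na(arz$timecourse$ratio[1]))
    ## phase comparison plumbing
    set.seed(19)
    ra <- lapply(1:6, function(i) list(early = 0.95 + rnorm(1, 0, 0.01),
                                       late = 0.7 + rnorm(1, 0, 0.01),
                                       fovId = "x"))
    rb <- lapply(1:6, function(i) list(early = 0.96 + rnorm(1, 0, 0.01),
                                       late = 0.95 + rnorm(1, 0, 0.01),
                                       fovId = "y"))
    cmp <- compareRatioPhases(ra, rb)
    expect_equal(cmp$phase, c("early", "late"))
    expect_lt(cmp$pPaired[2], 0.01)
})
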