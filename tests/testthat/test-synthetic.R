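test_that("panel tuning overlaps match the requested correlations", {
    ## orthogonal and proportional limiting cases
    p0 <- makePanel(500, 2, 0, seed = 11)
    r0 <- cor(tuningMatrix(p0)[, 1], tuningMatrix(p0)[, 2])
    expect_lt(abs(r0), 0.1)
    p1 <- makePanel(500, 2, 1, seed = 12)
    r1 <- cor(tuningMatrix(p1)[, 1], tuningMatrix(p1)[, 2])
    expect_gt(r1, 0.9)
    ## graded overlaps: empirical correlations close and ordered
    p <- makePanel(200, 4, c(0.2, 0.5, 0.8), seed = 13)
    r <- cor(tuningMatrix(p))[1, -1]
    expect_equal(unname(r), c(0.2, 0.5, 0.8), tolerance = 0.1)
    expect_true(all(diff(r) > 0))
    expect_error(makePanel(100, 2, NaN, seed = 1), "finite")
    expect_error(makePanel(100, 4, c(0.2, 0.5), seed = 1), "nOdours")
})

test_that("sessions are deterministic given config and seed", {
    s1 <- quickSession(seed = 5)
    s2 <- quickSession(seed = 5)
    expect_identical(lapply(s1$trials, fluorescence),
                     lapply(s2$trials, fluorescence))
    s3 <- quickSession(seed = 6)
    expect_false(identical(fluorescence(s1$trials[[1]]),
                           fluorescence(s3$trials[[1]])))
})

test_that("noiseless linear sessions sum mixtures exactly", {
    p <- makePanel(40, 3, c(0.6, 0.3), seed = 2)
    st <- StateProfile("quiet", gain = 0.7, trialNoiseSd = 0,
                       summation = "linear")
    cfg <- syntheticConfig(list("EB", "MB", c("EB", "MB")), seed = 3,
                           frameNoiseSd = 0)
    rm <- buildResponseMatrix(simulateSession(p, st, cfg))
    a <- amplitudes(rm)
    expect_equal(a[3, ], a[1, ] + a[2, ], tolerance = 1e-12)
    ## and the amplitudes equal gain x tuning
    expect_equal(unname(a[1, ]),
                 unname(0.7 * tuningMatrix(p)[, "EB"]), tolerance = 1e-9)
})

test_that("saturating summation bounds mixture amplitudes below Rmax", {
    p <- makePanel(80, 3, c(0.9, 0.5), seed = 4, amplitudeMean = 20,
                   amplitudeSd = 5)  # large tuning sums
    st <- StateProfile("anae", gain = 1, trialNoiseSd = 0,
                       summation = NormalisationParams(6, 0.2))
    cfg <- syntheticConfig(list(c("EB", "MB"), c("EB", "ET")), seed = 5,
                           frameNoiseSd = 0)
    rm <- buildResponseMatrix(simulateSession(p, st, cfg))
    expect_true(all(amplitudes(rm) < 6))
    ## >2 components refused
    cfgBad <- syntheticConfig(list(c("EB", "MB", "ET")), seed = 1)
    expect_error(simulateSession(p, st, cfgBad), "unsupported")
})

test_that("trial-averaged amplitudes converge to the generating means", {
    p <- makePanel(30, 2, 0.5, seed = 6)
    sd <- 0.5
    st <- StateProfile("s", gain = 1, trialNoiseSd = sd,
                       summation = "linear")
    nTrials <- 50L
    cfg <- syntheticConfig(rep(list("EB"), nTrials), seed = 7,
                           frameNoiseSd = 0)
    rm <- buildResponseMatrix(simulateSession(p, st, cfg))
    est <- colMeans(amplitudes(rm))
    se <- sd / sqrt(nTrials)
    expect_true(all(abs(est - tuningMatrix(p)[, "EB"]) < 3 * se +
                    4 * se * sqrt(2 / 30)))  # allow MC slack on the SD itself
    ## empirical trial SD close to the requested noise
    expect_equal(mean(apply(amplitudes(rm), 2, sd)), sd, tolerance = 0.15)
})

test_that("state presets order amplitude and reliability as expected", {
    mk <- function(state) {
        s <- quickSession(state, nRois = 100, seed = 21)
        rm <- buildResponseMatrix(s$trials)
        amp <- amplitudes(rm)
        stim <- trialLabels(rm)$stimulus
        ## trial-averaged (evoked) amplitude per stimulus, and mean
        ## within-stimulus trial-to-trial correlation distance
        sig <- vapply(unique(stim), function(o)
            mean(abs(colMeans(amp[stim == o, , drop = FALSE]))), numeric(1))
        ds <- unlist(lapply(unique(stim), function(o) {
            i <- which(stim == o)
            if (length(i) < 2) return(NULL)
            cc <- cor(t(amp[i, , drop = FALSE]))
            1 - cc[upper.tri(cc)]
        }))
        c(amp = mean(sig), dist = mean(ds))
    }
    anae <- mk("anaesthetised")
    behav <- mk("behaving")
    expect_gt(anae[["amp"]], behav[["amp"]])
    expect_lt(anae[["dist"]], behav[["dist"]])
})

test_that("behavioural simulation matches its generating probabilities", {
    ## perfect performance: flat learning curve at 1
    b1 <- simulateBehaviour(200, pCorrect = 1, seed = 31)
    lc <- learningCurve(b1)
    expect_true(all(lc$blocks$accuracy == 1))
    ## no unrewarded licking: full preference for every background
    lp <- lickPreferenceIndex(simulateBehaviour(600, pCorrect = 1,
                                                lickRateUnrewarded = 0,
                                                seed = 32))
    expect_true(all(lp$index == 1))
    ## chance performance: block accuracies within 3 binomial SEs of 0.5
    b05 <- simulateBehaviour(500, pCorrect = 0.5, seed = 33)
    acc <- learningCurve(b05, block = 50)$blocks$accuracy
    expect_true(all(abs(acc - 0.5) < 3 * sqrt(0.25 / 50)))
    expect_error(simulateBehaviour(10, lickRateRewarded = -1), "nonnegative")
})
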