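## Synthetic ROI calcium sessions and behavioural trials.
##
## The generator emulates the statistical structure the downstream analyses
## assume: a panel of odours with graded tuning overlap to a target, 30-Hz
## transients with 200 baseline + 200 post-onset frames, state-dependent
## response gain and trial noise, and configurable mixture summation
## (linear vs. saturating).

## Standard panel labels: target ester (EB), its closest neighbour (MB),
## further esters and non-esters.
.panelLabels <- c("EB", "MB", "ET", "MV", "BB", "MT", "MS", "SA", "AP",
                  "MA", "EU")

## Evaluate `code` under `seed` without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("'seed' must be a single finite number")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
    code
}

#' Generate an odour panel with graded tuning overlap to the target
#'
#' Builds an ROI x odour tuning matrix in which each non-target odour's
#' tuning vector has a requested Pearson correlation with the target's.
#' Target tuning amplitudes are drawn from a gamma distribution (positive,
#' right-skewed, as typical for mean delta-F/F responses); each non-target
#' vector is constructed from the standardised target vector and an
#' orthogonalised independent draw so that the empirical correlation equals
#' the requested overlap exactly (up to the `overlap = 1` proportionality
#' case).
#'
#' @param nRois number of ROIs.
#' @param nOdours number of odours including the target; must equal
#'   `length(targetOverlaps) + 1`.
#' @param targetOverlaps numeric in \[0, 1\], requested tuning correlation of
#'   each non-target odour with the target, in panel order.
#' @param seed integer seed.
#' @param odourIds optional character labels (target first); defaults to a
#'   standard ester/non-ester panel.
#' @param potencyRange range of per-odour amplitude scale factors, drawn
#'   uniformly per non-target odour (odours in a panel differ widely in
#'   evoked-response strength; set `c(1, 1)` for equal-potency odours).
#' @param amplitudeMean,amplitudeSd scale of mean tuning amplitudes
#'   (delta-F/F).  Tuning means are the synaptic drive before the state's
#'   saturating transform; observed responses stay bounded by its ceiling.
#'   The defaults are near the largest scale at which the anaesthetised
#'   preset both exhibits clearly sublinear mixture summation (median
#'   fractional deviation around -0.2) and still evokes larger observed
#'   responses than the dampened awake gain, as anaesthetised recordings
#'   do; pushing the drive higher deepens the sublinearity but inverts the
#'   state amplitude contrast.
#' @return an [OdourPanel-class].
#' @examples
#' p <- makePanel(nRois = 120, nOdours = 4,
#'                targetOverlaps = c(0.8, 0.5, 0.2), seed = 1)
#' cor(tuningMatrix(p)[, "EB"], tuningMatrix(p)[, "MB"])
#' @export
makePanel <- function(nRois, nOdours, targetOverlaps, seed,
                      odourIds = NULL, amplitudeMean = 6,
                      amplitudeSd = 4, potencyRange = c(0.4, 1.2)) {
    if (any(!is.finite(targetOverlaps)))
        stop("'targetOverlaps' must be finite")
    if (any(targetOverlaps < 0 | targetOverlaps > 1))
        stop("'targetOverlaps' must lie in [0, 1]")
    if (nOdours != length(targetOverlaps) + 1L)
        stop("'nOdours' must equal length(targetOverlaps) + 1")
    if (nRois < 3L)
        stop("'nRois' must be at least 3")
    if (is.null(odourIds)) {
        odourIds <- if (nOdours <= length(.panelLabels))
            .panelLabels[seq_len(nOdours)]
        else c(.panelLabels,
               paste0("OD", seq_len(nOdours - length(.panelLabels))))
    }
    stopifnot(length(odourIds) == nOdours, !anyDuplicated(odourIds))
    target <- odourIds[1L]

    withSeed(seed, {
        shape <- (amplitudeMean / amplitudeSd)^2
        rate <- amplitudeMean / amplitudeSd^2
        tgt <- stats::rgamma(nRois, shape = shape, rate = rate)
        tgtC <- as.numeric(scale(tgt))
        tuning <- matrix(NA_real_, nRois, nOdours,
                         dimnames = list(paste0("roi", seq_len(nRois)),
                                         odourIds))
        tuning[, 1L] <- tgt
        for (k in seq_along(targetOverlaps)) {
            rho <- targetOverlaps[k]
            if (rho >= 1) {
                tuning[, k + 1L] <- tgt
                next
            }
            z <- stats::rgamma(nRois, shape = shape, rate = rate)
            zPerp <- stats::resid(stats::lm(z ~ tgtC))
            zC <- as.numeric(scale(zPerp))
            mStd <- rho * tgtC + sqrt(1 - rho^2) * zC
            pot <- stats::runif(1, potencyRange[1], potencyRange[2])
            tuning[, k + 1L] <- pot * (amplitudeMean + stats::sd(tgt) * mStd)
        }
        ov <- stats::setNames(targetOverlaps, odourIds[-1L])
        new("OdourPanel", odourIds = odourIds, targetId = target,
            tuning = tuning, overlapSpectrum = ov)
    })
}

#' Brain-state presets for the synthetic generator
#'
#' Named presets capturing the qualitative state contrasts the analyses
#' probe: anaesthetised responses are large, reliable and saturating;
#' awake/behaving responses are dampened (gain 0.4) and far more variable
#' (trial SD 2 delta-F/F, the awake baseline SD used in the sublinearity
#' simulation; the anaesthetised value is 0.2), summing linearly in the
#' early phase.  Naive awake states sit between these.  Amplitude scales are
#' order-of-magnitude choices; treat them as defaults, not measurements.
#'
#' @param name one of `"anaesthetised"`, `"behaving"`, `"naive_engaged"`,
#'   `"naive_disengaged"`.
#' @return a [StateProfile-class].
#' @export
statePreset <- function(name = c("anaesthetised", "behaving",
                                 "naive_engaged", "naive_disengaged")) {
    name <- match.arg(name)
    switch(name,
        anaesthetised = StateProfile("anaesthetised", gain = 1,
                                     trialNoiseSd = 0.2,
                                     summation = NormalisationParams(6, 0.2),
                                     onsetLagS = 0.1, decayTauS = 4),
        behaving = StateProfile("behaving", gain = 0.4, trialNoiseSd = 2,
                                summation = "linear",
                                onsetLagS = 0.1, decayTauS = 4),
        naive_engaged = StateProfile("naive_engaged", gain = 0.5,
                                     trialNoiseSd = 1.2,
                                     summation = "linear",
                                     onsetLagS = 0.1, decayTauS = 4),
        naive_disengaged = StateProfile("naive_disengaged", gain = 0.6,
                                        trialNoiseSd = 1.5,
                                        summation = "linear",
                                        onsetLagS = 0.1, decayTauS = 4))
}

#' Acquisition/stimulus configuration for synthetic sessions
#'
#' Defaults mirror the standard acquisition: 400 frames at 30 Hz with 200
#' baseline frames before final-valve opening and a 0.5-s odour pulse.
#'
#' @param trialList list of character vectors, one per trial; each vector
#'   holds 1 (single odour) or 2 (binary mixture) odour labels.
#' @param seed integer seed for the session's randomness.
#' @param frameRateHz,nFrames,onsetFrame,stimDurationS acquisition geometry;
#'   `onsetFrame` is 0-based.
#' @param frameNoiseSd SD of additive per-frame Gaussian noise (default
#'   0.05, a photon/readout noise floor; set 0 for exactly noiseless
#'   traces).  Its contribution to window-averaged amplitudes is
#'   `frameNoiseSd / sqrt(window frames)`, negligible against
#'   `trialNoiseSd` at the defaults.
#' @param gainJitterSd SD of a per-trial shared multiplicative gain jitter
#'   (default 0 = off).
#' @param riseTauS rise time constant of the transient kernel (s).
#' @return a list of class `"SyntheticConfig"`.
#' @seealso [simulateSession()], [makeTrialList()]
#' @export
syntheticConfig <- function(trialList, seed, frameRateHz = 30,
                            nFrames = 400L, onsetFrame = 200L,
                            stimDurationS = 0.5, frameNoiseSd = 0.05,
                            gainJitterSd = 0, riseTauS = 0.15) {
    cfg <- list(trialList = trialList, seed = seed,
                frameRateHz = frameRateHz, nFrames = as.integer(nFrames),
                onsetFrame = as.integer(onsetFrame),
                stimDurationS = stimDurationS, frameNoiseSd = frameNoiseSd,
                gainJitterSd = gainJitterSd, riseTauS = riseTauS)
    class(cfg) <- "SyntheticConfig"
    if (cfg$onsetFrame >= cfg$nFrames)
        stop("'onsetFrame' must be smaller than 'nFrames'")
    if (!length(trialList)) stop("'trialList' must contain at least one trial")
    cfg
}

#' Build a session trial list with scheduled core trials
#'
#' Mirrors the session design in which the target, the closest masker and
#' their binary mixture each appear once in every block of 10 trials, with
#' the remaining trials drawn from other singles and mixtures.
#'
#' @param panel an [OdourPanel-class].
#' @param nBlocks number of 10-trial blocks.
#' @param seed integer seed.
#' @param masker masker odour label; defaults to the second panel odour.
#' @param scheduledCoreTrials if `TRUE` (default), every block contains the
#'   target, the masker and their mixture.
#' @return list of character vectors usable as `trialList`.
#' @export
makeTrialList <- function(panel, nBlocks = 4L, seed = 1L, masker = NULL,
                          scheduledCoreTrials = TRUE) {
    target <- targetId(panel)
    others <- setdiff(odourIds(panel), target)
    if (is.null(masker)) masker <- others[1L]
    stopifnot(masker %in% others)
    withSeed(seed, {
        trials <- list()
        for (b in seq_len(nBlocks)) {
            block <- list()
            nFill <- if (scheduledCoreTrials) 7L else 10L
            for (i in seq_len(nFill)) {
                kind <- sample(c("single", "targetMix", "otherMix"), 1L,
                               prob = c(0.4, 0.3, 0.3))
                block[[i]] <- switch(kind,
                    single = sample(others, 1L),
                    targetMix = c(target, sample(setdiff(others, masker), 1L)),
                    otherMix = sample(others, 2L))
            }
            if (scheduledCoreTrials)
                block <- c(block, list(target, masker, c(target, masker)))
            trials <- c(trials, sample(block))
        }
        trials
    })
}

#' Build a class-balanced session trial list
#'
#' Produces equally many target-present trials (target alone, or target +
#' random masker) and target-absent trials (single non-target odours and
#' non-target mixtures), shuffled.  Balanced designs are the appropriate
#' fixture for decoder-calibration checks, where class imbalance would
#' shift the chance level away from 0.5.
#'
#' @param panel an [OdourPanel-class].
#' @param nPerClass trials per class.
#' @param seed integer seed.
#' @return list of character vectors usable as `trialList`.
#' @export
balancedTrialList <- function(panel, nPerClass = 20L, seed = 1L) {
    tgt <- targetId(panel)
    others <- setdiff(odourIds(panel), tgt)
    nSingle <- nPerClass %/% 2L
    nMix <- nPerClass - nSingle
    withSeed(seed, {
        pos <- c(replicate(nSingle, tgt, simplify = FALSE),
                 replicate(nMix, c(tgt, sample(others, 1L)),
                           simplify = FALSE))
        neg <- c(lapply(seq_len(nSingle), function(i) sample(others, 1L)),
                 lapply(seq_len(nMix), function(i) sample(others, 2L)))
        sample(c(pos, neg))
    })
}

## Transient kernel sampled at the session's frame times; unit mean over the
## 1-s response window.
.transientKernel <- function(cfg, state) {
    frames <- seq_len(cfg$nFrames) - 1L
    tRel <- (frames - cfg$onsetFrame) / cfg$frameRateHz
    tt <- tRel - state@onsetLagS
    h <- ifelse(tt > 0,
                exp(-tt / state@decayTauS) - exp(-tt / cfg$riseTauS), 0)
    win <- frames >= cfg$onsetFrame &
        frames < cfg$onsetFrame + round(cfg$frameRateHz)
    m <- mean(h[win])
    if (m <= 0) stop("degenerate transient kernel: check lag/tau settings")
    h / m
}

## Mean amplitude per ROI for a stimulus under a state: component tuning
## summed, optionally passed through the saturating transform, then gain.
.meanAmplitude <- function(panel, state, comps) {
    bad <- setdiff(comps, odourIds(panel))
    if (length(bad))
        stop("stimulus references odours not in the panel: ",
             paste(bad, collapse = ", "))
    if (length(comps) > 2L)
        stop("unsupported stimulus: mixtures must have exactly 2 components")
    base <- rowSums(tuningMatrix(panel)[, comps, drop = FALSE])
    if (is(state@summation, "NormalisationParams"))
        base <- normaliseResponse(base, state@summation)
    state@gain * base
}

#' Simulate one imaging session
#'
#' Generates a list of [TrialRecording-class] objects.  Each trial's mean
#' amplitude over the 1-s response window equals
#' `gain * f(sum of component tuning)` — where `f` is the identity for
#' linear summation or the saturating transform for a
#' [NormalisationParams-class] `summation` — plus per-trial Gaussian noise
#' of SD `trialNoiseSd`.  The waveform is a difference of exponentials
#' (fast rise, slow decay) starting `onsetLagS` after the final-valve
#' frame, scaled so its mean over the response window is 1; baseline frames
#' have mean 0 (traces are generated directly as delta-F/F).
#'
#' @param panel an [OdourPanel-class].
#' @param state a [StateProfile-class] (see [statePreset()]).
#' @param cfg a [syntheticConfig()] list.
#' @param fovId field-of-view label stamped on every trial.
#' @return list of [TrialRecording-class].
#' @examples
#' p <- makePanel(60, 3, c(0.7, 0.2), seed = 1)
#' cfg <- syntheticConfig(makeTrialList(p, nBlocks = 2, seed = 2), seed = 3)
#' trials <- simulateSession(p, statePreset("anaesthetised"), cfg)
#' trials[[1]]
#' @export
simulateSession <- function(panel, state, cfg, fovId = "fov1") {
    stopifnot(is(panel, "OdourPanel"), is(state, "StateProfile"),
              inherits(cfg, "SyntheticConfig"))
    h <- .transientKernel(cfg, state)
    n <- nRois(panel)
    target <- targetId(panel)
    withSeed(cfg$seed, {
        lapply(cfg$trialList, function(comps) {
            mu <- .meanAmplitude(panel, state, comps)
            amp <- mu + stats::rnorm(n, 0, state@trialNoiseSd)
            if (cfg$gainJitterSd > 0)
                amp <- amp * (1 + stats::rnorm(1L, 0, cfg$gainJitterSd))
            mat <- outer(amp, h)
            if (cfg$frameNoiseSd > 0)
                mat <- mat + matrix(stats::rnorm(length(mat), 0,
                                                 cfg$frameNoiseSd),
                                    nrow = n)
            rownames(mat) <- rownames(tuningMatrix(panel))
            TrialRecording(mat, frameRateHz = cfg$frameRateHz,
                           onsetFrame = cfg$onsetFrame, stimulus = comps,
                           rewarded = target %in% comps, state = state@name,
                           fovId = fovId, isDff = TRUE)
        })
    })
}

#' Simulate Go/No-Go behavioural trials
#'
#' Generates trials of a target-detection task: on each trial a background
#' odour is drawn, the trial is rewarded (target present) with probability
#' `pRewarded`, and the animal responds correctly with probability
#' `pCorrect` (scalar, or named per background).  Anticipatory lick counts
#' are Poisson-like: go responses emit at least `threshold` licks with mean
#' `lickRateRewarded`; withheld responses emit licks with mean
#' `lickRateUnrewarded`, truncated below `threshold`.
#'
#' @param nTrials number of trials.
#' @param pCorrect probability of a correct response, scalar or named
#'   vector over `backgrounds`.
#' @param lickRateRewarded,lickRateUnrewarded mean anticipatory lick counts
#'   for go and no-go responses (must be >= 0).
#' @param seed integer seed.
#' @param backgrounds background odour labels (use `"blank"` for
#'   single-target trials).
#' @param target target odour label.
#' @param pRewarded probability a trial is rewarded (a third, as in the
#'   task design).
#' @param threshold anticipatory-lick threshold (licks >= threshold = go).
#' @return data.frame with columns `trial`, `backgroundId`, `rewarded`,
#'   `stimulus`, `anticipatoryLicks`.
#' @export
simulateBehaviour <- function(nTrials, pCorrect = 1, lickRateRewarded = 6,
                              lickRateUnrewarded = 0.5, seed = 1L,
                              backgrounds = c("MB", "ET", "MV", "BB", "MT",
                                              "blank"),
                              target = "EB", pRewarded = 1 / 3,
                              threshold = 2L) {
    if (lickRateRewarded < 0 || lickRateUnrewarded < 0)
        stop("lick rates must be nonnegative")
    if (any(pCorrect < 0 | pCorrect > 1))
        stop("'pCorrect' must lie in [0, 1]")
    if (length(pCorrect) == 1L)
        pCorrect <- stats::setNames(rep(pCorrect, length(backgrounds)),
                                    backgrounds)
    stopifnot(all(backgrounds %in% names(pCorrect)))
    withSeed(seed, {
        bg <- sample(backgrounds, nTrials, replace = TRUE)
        rewarded <- stats::rbinom(nTrials, 1L, pRewarded) == 1L
        correct <- stats::rbinom(nTrials, 1L, pCorrect[bg]) == 1L
        go <- (rewarded & correct) | (!rewarded & !correct)
        licks <- integer(nTrials)
        nGo <- sum(go)
        licks[go] <- threshold +
            stats::rpois(nGo, max(0, lickRateRewarded - threshold))
        licks[!go] <- pmin(stats::rpois(nTrials - nGo, lickRateUnrewarded),
                           threshold - 1L)
        stim <- ifelse(rewarded,
                       ifelse(bg == "blank", target, paste0(target, "+", bg)),
                       ifelse(bg == "blank", "blank", bg))
        data.frame(trial = seq_len(nTrials), backgroundId = bg,
                   rewarded = rewarded, stimulus = stim,
                   anticipatoryLicks = licks)
    })
}
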