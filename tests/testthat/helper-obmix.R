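## Shared fixture builders (all fixtures are generated in code).

## A trial whose amplitude over any post-onset window is exactly `amp` per
## ROI: baseline 0, step to `amp` at onset.
stepTrial <- function(amps, stimulus = "EB", nFrames = 400L,
                      onsetFrame = 200L, rate = 30, fovId = "fov1") {
    f <- matrix(0, length(amps), nFrames)
    f[, (onsetFrame + 1L):nFrames] <- amps
    TrialRecording(f, frameRateHz = rate, onsetFrame = onsetFrame,
                   stimulus = stimulus, fovId = fovId, isDff = TRUE)
}

## Response matrix with exact per-ROI amplitudes per trial type.
## ampList: named list stimulus -> list of per-trial amplitude vectors.
exactResponseMatrix <- function(ampList, target = "EB", masker = "MB") {
    trials <- list()
    for (stim in names(ampList)) {
        comps <- strsplit(stim, "+", fixed = TRUE)[[1]]
        for (a in ampList[[stim]])
            trials[[length(trials) + 1L]] <- stepTrial(a, stimulus = comps)
    }
    buildResponseMatrix(trials, target = target, masker = masker)
}

## Small synthetic session under a preset, noiseless frames by default.
quickSession <- function(state = "anaesthetised", nRois = 60L, nOdours = 4L,
                         overlaps = c(0.7, 0.4, 0.2)[seq_len(nOdours - 1L)],
                         nBlocks = 2L, seed = 1L, frameNoiseSd = 0.05,
                         stateProfile = NULL) {
    p <- makePanel(nRois, nOdours, overlaps, seed = seed)
    cfg <- syntheticConfig(makeTrialList(p, nBlocks, seed = seed + 1L),
                           seed = seed + 2L, frameNoiseSd = frameNoiseSd)
    st <- if (is.null(stateProfile)) statePreset(state) else stateProfile
    list(panel = p, cfg = cfg,
         trials = simulateSession(p, st, cfg))
}
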