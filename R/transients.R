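## delta-F/F conversion and window-averaged response amplitudes.
##
## Conventions: frames are 0-based; time is in seconds relative to the
## final-valve opening; windows are half-open [start, end).

## 1-based column indices for a half-open window in seconds.
.windowCols <- function(trial, window) {
    if (length(window) != 2L || !all(is.finite(window)) ||
        window[2] <= window[1])
        stop("invalid window: need finite (start, end) with end > start")
    rate <- frameRate(trial)
    from <- onsetFrame(trial) + round(window[1] * rate)
    to <- onsetFrame(trial) + round(window[2] * rate)  # exclusive
    if (from < 0 || to > ncol(fluorescence(trial)))
        stop("window [", window[1], ", ", window[2],
             ") falls outside the recording")
    if (to <= from) stop("empty window: no frames in [",
                         window[1], ", ", window[2], ")")
    seq.int(from + 1L, to)
}

#' Convert raw fluorescence to delta-F/F
#'
#' The baseline F0 of each ROI is its mean fluorescence over the
#' `baselineS` seconds immediately preceding the final-valve opening
#' (frames `[onset - baselineS * rate, onset)`), and the trace becomes
#' `(F - F0) / F0`.  Trials already flagged as delta-F/F are returned
#' unchanged rather than re-normalised.
#'
#' @param trial a [TrialRecording-class].
#' @param baselineS baseline duration in seconds (default 2, i.e. 60 frames
#'   at 30 Hz).
#' @return a [TrialRecording-class] with `isDff = TRUE`; the baseline-window
#'   mean of each ROI is 0 by construction.
#' @examples
#' f <- matrix(100, 2, 400)
#' f[, 201:400] <- 110
#' tr <- TrialRecording(f, stimulus = "EB")
#' max(abs(responseAmplitude(computeDff(tr)) - 0.1))
#' @export
computeDff <- function(trial, baselineS = 2) {
    stopifnot(is(trial, "TrialRecording"))
    if (isDff(trial)) return(trial)
    rate <- frameRate(trial)
    nBase <- round(baselineS * rate)
    if (nBase < 1L) stop("baseline window contains no frames")
    if (onsetFrame(trial) < nBase)
        stop("baseline of ", baselineS,
             " s does not fit before the onset frame")
    f <- fluorescence(trial)
    cols <- seq.int(onsetFrame(trial) - nBase + 1L, onsetFrame(trial))
    f0 <- rowMeans(f[, cols, drop = FALSE])
    bad <- which(f0 <= 0)
    if (length(bad))
        stop("degenerate baseline (F0 <= 0) for ROI(s): ",
             paste(if (is.null(rownames(f))) bad else rownames(f)[bad],
                   collapse = ", "))
    out <- trial
    out@fluorescence <- sweep(sweep(f, 1, f0, "-"), 1, f0, "/")
    out@isDff <- TRUE
    out
}

#' Window-averaged response amplitude per ROI
#'
#' Mean delta-F/F over the frames in the half-open window
#' `[onset + round(start * rate), onset + round(end * rate))`.  The default
#' window (0, 1) is the standard 1-s (30-frame) odour response period
#' starting at final-valve opening.
#'
#' @param trial a [TrialRecording-class] (delta-F/F).
#' @param window numeric `c(start, end)` in seconds relative to onset;
#'   negative starts reach into the baseline.
#' @return named numeric vector, one amplitude per ROI.
#' @export
responseAmplitude <- function(trial, window = c(0, 1)) {
    stopifnot(is(trial, "TrialRecording"))
    cols <- .windowCols(trial, window)
    rowMeans(fluorescence(trial)[, cols, drop = FALSE])
}

#' Assemble a trial x ROI response matrix
#'
#' Computes [responseAmplitude()] for every trial and stacks the results
#' into a [ResponseMatrix-class], preserving trial order.  Labels are
#' derived from the stimulus metadata: `targetPresent` is `TRUE` when the
#' target odour is among the components, `maskerPresent` likewise for the
#' masker.
#'
#' @param trials list of [TrialRecording-class] sharing ROI count and
#'   field of view.
#' @param window response window in seconds, as in [responseAmplitude()].
#' @param target target odour label (default `"EB"`).
#' @param masker masker odour label (default `"MB"`).
#' @param timePoint optional time tag (s) stored in metadata, used by the
#'   time-resolved analyses.
#' @return a [ResponseMatrix-class].
#' @export
buildResponseMatrix <- function(trials, window = c(0, 1), target = "EB",
                                masker = "MB", timePoint = NA_real_) {
    stopifnot(length(trials) >= 1L,
              all(vapply(trials, is, logical(1), "TrialRecording")))
    ns <- vapply(trials, nRois, integer(1))
    if (length(unique(ns)) != 1L)
        stop("shape mismatch: trials have differing ROI counts (",
             paste(unique(ns), collapse = ", "), ")")
    fovs <- unique(vapply(trials, fovId, character(1)))
    if (length(fovs) != 1L)
        stop("trials come from multiple fields of view: ",
             paste(fovs, collapse = ", "))
    amp <- vapply(trials, responseAmplitude, numeric(ns[1]), window = window)
    amp <- matrix(amp, nrow = ns[1])  # ROI x trial
    rn <- rownames(fluorescence(trials[[1]]))
    rownames(amp) <- if (is.null(rn)) sprintf("roi%03d", seq_len(ns[1])) else rn
    colnames(amp) <- sprintf("trial%03d", seq_along(trials))
    stim <- vapply(trials, function(tr) paste(stimulus(tr), collapse = "+"),
                   character(1))
    cd <- S4Vectors::DataFrame(
        stimulus = stim,
        nComponents = vapply(trials, function(tr) length(stimulus(tr)),
                             integer(1)),
        targetPresent = vapply(trials, function(tr) target %in% stimulus(tr),
                               logical(1)),
        maskerPresent = vapply(trials, function(tr) masker %in% stimulus(tr),
                               logical(1)),
        state = vapply(trials, function(tr) tr@state, character(1)),
        rewarded = vapply(trials, function(tr) tr@rewarded, logical(1)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(amplitude = amp), colData = cd)
    metadata(se) <- list(window = window, fovId = fovs, target = target,
                         masker = masker, timePoint = timePoint)
    new("ResponseMatrix", se)
}

#' Time-resolved response matrices over sliding windows
#'
#' Builds one [ResponseMatrix-class] per time point using a causal sliding
#' window of `windowS` seconds ending at each time point (signals are
#' averaged over ~1 s, i.e. 30 frames, per time point).  A matrix labelled
#' `t` therefore summarises `(t - windowS, t]`.
#'
#' @param trials list of [TrialRecording-class].
#' @param timePoints numeric vector of window-end times (s relative to
#'   onset).
#' @param windowS window length in seconds (default 1).
#' @inheritParams buildResponseMatrix
#' @return named list of [ResponseMatrix-class], one per time point.
#' @export
slidingResponseMatrices <- function(trials, timePoints = seq(0.5, 3, by = 0.5),
                                    windowS = 1, target = "EB",
                                    masker = "MB") {
    out <- lapply(timePoints, function(tp)
        buildResponseMatrix(trials, window = c(tp - windowS, tp),
                            target = target, masker = masker,
                            timePoint = tp))
    names(out) <- sprintf("t%+.2f", timePoints)
    out
}
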