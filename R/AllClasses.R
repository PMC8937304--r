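## S4 class definitions for obmix.

#' Saturating normalisation parameters
#'
#' Parameters of the saturating (normalising) transform applied to summed
#' response amplitudes, \eqn{R^* = R_{max}\,(2/(1+e^{-sR}) - 1)}.  \code{Rmax}
#' is the saturation ceiling in delta-F/F units; \code{s} (1/delta-F/F) sets
#' how quickly responses approach it.  The transform is odd, strictly
#' increasing and bounded in \eqn{(-R_{max}, R_{max})}; its slope at the
#' origin is \eqn{R_{max}\,s/2}.
#'
#' @slot Rmax numeric(1), saturation ceiling (> 0).
#' @slot s numeric(1), slope parameter (> 0).
#' @seealso [normaliseResponse()], [fitNormalisation()]
#' @export
setClass("NormalisationParams",
         representation(Rmax = "numeric", s = "numeric"),
         prototype(Rmax = 6, s = 0.2))

setValidity("NormalisationParams", function(object) {
    if (length(object@Rmax) != 1L || !is.finite(object@Rmax) || object@Rmax <= 0)
        return("'Rmax' must be a single finite positive number")
    if (length(object@s) != 1L || !is.finite(object@s) || object@s <= 0)
        return("'s' must be a single finite positive number")
    TRUE
})

#' @describeIn NormalisationParams-class constructor.
#' @param Rmax,s see slots.
#' @export
NormalisationParams <- function(Rmax = 6, s = 0.2)
    new("NormalisationParams", Rmax = Rmax, s = s)

#' Trial-noise model for simulated mixture responses
#'
#' Standard deviation of the uncorrelated Gaussian noise added to simulated
#' mixture responses: \code{sigma0 + slope * |amplitude|}.  \code{sigma0} is
#' the fixed baseline SD (delta-F/F); \code{slope} is the dimensionless
#' increment of SD per unit response amplitude, typically estimated from the
#' observed trial-to-trial dispersion.
#'
#' @slot sigma0 numeric(1), baseline SD (>= 0).
#' @slot slope numeric(1), SD per unit |amplitude| (>= 0).
#' @seealso [fitNoiseSlope()], [simulateMixtureTest()]
#' @export
setClass("NoiseModel",
         representation(sigma0 = "numeric", slope = "numeric"),
         prototype(sigma0 = 0.2, slope = 0))

setValidity("NoiseModel", function(object) {
    if (length(object@sigma0) != 1L || !is.finite(object@sigma0) ||
        object@sigma0 < 0)
        return("'sigma0' must be a single finite nonnegative number")
    if (length(object@slope) != 1L || !is.finite(object@slope) ||
        object@slope < 0)
        return("'slope' must be a single finite nonnegative number")
    TRUE
})

#' @describeIn NoiseModel-class constructor.
#' @param sigma0,slope see slots.
#' @export
NoiseModel <- function(sigma0 = 0.2, slope = 0)
    new("NoiseModel", sigma0 = sigma0, slope = slope)

#' Brain-state profile for synthetic sessions
#'
#' Describes how a behavioural/brain state shapes simulated responses: a
#' multiplicative gain on mean amplitudes, trial-to-trial amplitude noise,
#' how binary-mixture components are summed ("linear", or a
#' [NormalisationParams-class] object applied to the component sum), and the
#' transient kinetics (onset lag and decay time constant).
#'
#' @slot name character(1); one of "anaesthetised", "behaving",
#'   "naive_engaged", "naive_disengaged" (free-form names are allowed).
#' @slot gain numeric(1) > 0, multiplier on tuning means.
#' @slot trialNoiseSd numeric(1) >= 0, SD of per-trial amplitude noise
#'   (delta-F/F).
#' @slot summation either the character "linear" or a
#'   [NormalisationParams-class] object.
#' @slot onsetLagS numeric(1), seconds from final-valve opening to transient
#'   onset.
#' @slot decayTauS numeric(1), decay time constant of the transient (s).
#' @seealso [statePreset()], [simulateSession()]
#' @export
setClass("StateProfile",
         representation(name = "character", gain = "numeric",
                        trialNoiseSd = "numeric", summation = "ANY",
                        onsetLagS = "numeric", decayTauS = "numeric"))

setValidity("StateProfile", function(object) {
    if (length(object@gain) != 1L || !is.finite(object@gain) || object@gain <= 0)
        return("'gain' must be a single positive number")
    if (length(object@trialNoiseSd) != 1L || !is.finite(object@trialNoiseSd) ||
        object@trialNoiseSd < 0)
        return("'trialNoiseSd' must be a single nonnegative number")
    ok <- (is.character(object@summation) &&
           identical(object@summation, "linear")) ||
          is(object@summation, "NormalisationParams")
    if (!ok)
        return("'summation' must be \"linear\" or a NormalisationParams object")
    if (object@onsetLagS < 0 || object@decayTauS <= 0)
        return("'onsetLagS' must be >= 0 and 'decayTauS' > 0")
    TRUE
})

#' @describeIn StateProfile-class constructor.
#' @param name,gain,trialNoiseSd,summation,onsetLagS,decayTauS see slots.
#' @export
StateProfile <- function(name, gain = 1, trialNoiseSd = 0.2,
                         summation = "linear", onsetLagS = 0.1,
                         decayTauS = 4) {
    new("StateProfile", name = name, gain = gain,
        trialNoiseSd = trialNoiseSd, summation = summation,
        onsetLagS = onsetLagS, decayTauS = decayTauS)
}

#' Odour panel with graded tuning overlap
#'
#' A panel of odours together with the mean response amplitude (tuning) of
#' every ROI to every odour, and the requested correlation of each non-target
#' odour's tuning vector with the target's.  Emulates a panel of esters and
#' non-esters whose glomerular patterns overlap the target to graded degrees.
#'
#' @slot odourIds character vector of short odour labels.
#' @slot targetId character(1), label of the target odour; must be in
#'   \code{odourIds}.
#' @slot tuning numeric matrix, ROI x odour, mean amplitudes (delta-F/F).
#' @slot overlapSpectrum named numeric in \[0, 1\], one entry per non-target
#'   odour: requested Pearson correlation of that odour's tuning vector with
#'   the target's.
#' @seealso [makePanel()]
#' @export
setClass("OdourPanel",
         representation(odourIds = "character", targetId = "character",
                        tuning = "matrix", overlapSpectrum = "numeric"))

setValidity("OdourPanel", function(object) {
    if (!(object@targetId %in% object@odourIds))
        return("'targetId' must be one of 'odourIds'")
    if (!all(is.finite(object@tuning)))
        return("'tuning' must be finite")
    if (ncol(object@tuning) != length(object@odourIds))
        return("tuning must have one column per odour")
    if (!identical(colnames(object@tuning), object@odourIds))
        return("tuning column names must equal 'odourIds'")
    nt <- setdiff(object@odourIds, object@targetId)
    if (!all(nt %in% names(object@overlapSpectrum)))
        return("'overlapSpectrum' must name every non-target odour")
    if (any(!is.finite(object@overlapSpectrum)))
        return("'overlapSpectrum' must be finite")
    TRUE
})

#' One imaging trial: ROI x frame fluorescence plus stimulus metadata
#'
#' Holds a single trial's fluorescence matrix (ROIs in rows, frames in
#' columns; raw fluorescence or delta-F/F as indicated by \code{isDff})
#' together with acquisition and stimulus metadata.  Frames are 0-based and
#' \code{onsetFrame} indexes the frame at which the final valve opened; with
#' the default acquisition there are 400 frames at 30 Hz with 200 baseline
#' frames.
#'
#' @slot fluorescence numeric matrix, ROI x frame.
#' @slot frameRateHz numeric(1), acquisition rate (Hz).
#' @slot onsetFrame integer(1), 0-based frame index of stimulus onset.
#' @slot stimulus character vector of odour components (length 1 for single
#'   odours, 2 for binary mixtures).
#' @slot rewarded logical(1), NA when not a task trial.
#' @slot state character(1), brain-state label.
#' @slot fovId character(1), field-of-view label.
#' @slot isDff logical(1), TRUE when the traces are already delta-F/F.
#' @seealso [computeDff()], [responseAmplitude()], [simulateSession()]
#' @export
setClass("TrialRecording",
         representation(fluorescence = "matrix", frameRateHz = "numeric",
                        onsetFrame = "integer", stimulus = "character",
                        rewarded = "logical", state = "character",
                        fovId = "character", isDff = "logical"))

setValidity("TrialRecording", function(object) {
    if (!is.numeric(object@fluorescence))
        return("'fluorescence' must be a numeric matrix")
    if (object@onsetFrame < 0L || object@onsetFrame >= ncol(object@fluorescence))
        return("'onsetFrame' must lie within the recording")
    if (length(object@stimulus) < 1L)
        return("'stimulus' must list at least one odour component")
    if (object@frameRateHz <= 0)
        return("'frameRateHz' must be positive")
    TRUE
})

#' @describeIn TrialRecording-class constructor.
#' @param fluorescence,frameRateHz,onsetFrame,stimulus,rewarded,state,fovId,isDff
#'   see slots.
#' @export
TrialRecording <- function(fluorescence, frameRateHz = 30, onsetFrame = 200L,
                           stimulus, rewarded = NA, state = "anaesthetised",
                           fovId = "fov1", isDff = FALSE) {
    new("TrialRecording", fluorescence = fluorescence,
        frameRateHz = frameRateHz, onsetFrame = as.integer(onsetFrame),
        stimulus = stimulus, rewarded = as.logical(rewarded), state = state,
        fovId = fovId, isDff = isDff)
}

#' Trial x ROI response-amplitude matrix
#'
#' A \linkS4class{SummarizedExperiment}-derived container of window-averaged
#' response amplitudes.  The assay \code{"amplitude"} is stored ROI x trial
#' (rows are features as usual for SummarizedExperiment); the accessor
#' [amplitudes()] returns the trial x ROI orientation used by the analysis
#' functions.  Per-trial stimulus labels (stimulus string, target-present
#' and masker-present flags, state, reward) live in \code{colData}; the
#' response window (seconds relative to odour onset), field-of-view id,
#' target/masker identity and (for time-resolved matrices) the time point
#' live in \code{metadata}.
#'
#' @seealso [buildResponseMatrix()], [slidingResponseMatrices()]
#' @export
setClass("ResponseMatrix", contains = "SummarizedExperiment")

setValidity("ResponseMatrix", function(object) {
    if (!("amplitude" %in% SummarizedExperiment::assayNames(object)))
        return("ResponseMatrix requires an 'amplitude' assay")
    need <- c("stimulus", "targetPresent", "maskerPresent")
    miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
    if (length(miss))
        return(paste("missing colData columns:", paste(miss, collapse = ", ")))
    TRUE
})

#' Trial-by-trial population-correlation analysis
#'
#' Pearson correlation between population response vectors of every pair of
#' trials, with S+/S- class labels (S+ = target-containing stimulus).
#'
#' @slot corr numeric trial x trial correlation matrix (symmetric, unit
#'   diagonal).
#' @slot classLabels logical per trial; TRUE for S+ trials.
#' @slot timePoint numeric(1), seconds relative to odour onset (NA when not
#'   time-resolved).
#' @seealso [trialCorrelationMatrix()], [discriminabilityIndex()]
#' @export
setClass("CorrelationAnalysis",
         representation(corr = "matrix", classLabels = "logical",
                        timePoint = "numeric"))

setValidity("CorrelationAnalysis", function(object) {
    m <- object@corr
    if (nrow(m) != ncol(m)) return("'corr' must be square")
    if (length(object@classLabels) != nrow(m))
        return("one class label per trial required")
    if (nrow(m) > 0L) {
        if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
            return("'corr' must be symmetric")
        if (max(abs(diag(m) - 1), na.rm = TRUE) > 1e-8)
            return("'corr' must have unit diagonal")
        if (any(m > 1 + 1e-8 | m < -1 - 1e-8, na.rm = TRUE))
            return("correlations must lie in [-1, 1]")
    }
    TRUE
})

#' Time-resolved decoding accuracies
#'
#' Accuracy of a linear decoder over random splits (rows) and time points
#' (columns), with the split design recorded in \code{splitSpec}
#' ("random_80_20" or "train_single_test_mixture").
#'
#' @slot timePoints numeric, seconds relative to odour onset (window end).
#' @slot accuracy numeric matrix, split x time, values in \[0, 1\].
#' @slot splitSpec character(1).
#' @slot nSplits integer(1).
#' @slot seed integer(1), seed used for the split randomisation.
#' @slot fovId character(1).
#' @seealso [randomSplitAccuracy()], [crossGeneralizationAccuracy()]
#' @export
setClass("DecodingResult",
         representation(timePoints = "numeric", accuracy = "matrix",
                        splitSpec = "character", nSplits = "integer",
                        seed = "integer", fovId = "character"))

setValidity("DecodingResult", function(object) {
    if (ncol(object@accuracy) != length(object@timePoints))
        return("one accuracy column per time point required")
    a <- object@accuracy
    if (any(a < -1e-9 | a > 1 + 1e-9, na.rm = TRUE))
        return("accuracies must lie in [0, 1]")
    TRUE
})
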