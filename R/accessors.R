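## Generics, accessors and show methods.

#' @name obmix-accessors
#' @title Accessors for obmix classes
#' @description Accessor functions for the S4 containers; user code should
#'   use these rather than reaching into slots.
#' @param x an obmix object.
#' @param object an obmix object (for `show`).
NULL

#' @describeIn obmix-accessors trial x ROI amplitude matrix of a
#'   [ResponseMatrix-class] (transposed from the internal ROI x trial assay).
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname obmix-accessors
#' @export
setMethod("amplitudes", "ResponseMatrix", function(x)
    t(SummarizedExperiment::assay(x, "amplitude")))

#' @describeIn obmix-accessors per-trial label data.frame (stimulus,
#'   targetPresent, maskerPresent, state, rewarded).
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname obmix-accessors
#' @export
setMethod("trialLabels", "ResponseMatrix", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @describeIn obmix-accessors response window in seconds relative to odour
#'   onset, `c(start, end)`.
#' @export
setGeneric("responseWindow", function(x) standardGeneric("responseWindow"))

#' @rdname obmix-accessors
#' @export
setMethod("responseWindow", "ResponseMatrix", function(x)
    metadata(x)$window)

#' @describeIn obmix-accessors field-of-view label.
#' @export
setGeneric("fovId", function(x) standardGeneric("fovId"))

#' @rdname obmix-accessors
#' @export
setMethod("fovId", "ResponseMatrix", function(x) metadata(x)$fovId)

#' @rdname obmix-accessors
#' @export
setMethod("fovId", "TrialRecording", function(x) x@fovId)

#' @rdname obmix-accessors
#' @export
setMethod("fovId", "DecodingResult", function(x) x@fovId)

#' @describeIn obmix-accessors number of ROIs.
#' @export
setGeneric("nRois", function(x) standardGeneric("nRois"))

#' @rdname obmix-accessors
#' @export
setMethod("nRois", "ResponseMatrix", function(x) nrow(x))

#' @rdname obmix-accessors
#' @export
setMethod("nRois", "TrialRecording", function(x) nrow(x@fluorescence))

#' @rdname obmix-accessors
#' @export
setMethod("nRois", "OdourPanel", function(x) nrow(x@tuning))

#' @describeIn obmix-accessors fluorescence matrix (ROI x frame) of a
#'   [TrialRecording-class].
#' @export
setGeneric("fluorescence", function(x) standardGeneric("fluorescence"))

#' @rdname obmix-accessors
#' @export
setMethod("fluorescence", "TrialRecording", function(x) x@fluorescence)

#' @describeIn obmix-accessors stimulus components of a trial.
#' @export
setGeneric("stimulus", function(x) standardGeneric("stimulus"))

#' @rdname obmix-accessors
#' @export
setMethod("stimulus", "TrialRecording", function(x) x@stimulus)

#' @describeIn obmix-accessors 0-based frame index of stimulus onset.
#' @export
setGeneric("onsetFrame", function(x) standardGeneric("onsetFrame"))

#' @rdname obmix-accessors
#' @export
setMethod("onsetFrame", "TrialRecording", function(x) x@onsetFrame)

#' @describeIn obmix-accessors acquisition frame rate (Hz).
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname obmix-accessors
#' @export
setMethod("frameRate", "TrialRecording", function(x) x@frameRateHz)

#' @describeIn obmix-accessors whether traces are already delta-F/F.
#' @export
setGeneric("isDff", function(x) standardGeneric("isDff"))

#' @rdname obmix-accessors
#' @export
setMethod("isDff", "TrialRecording", function(x) x@isDff)

#' @describeIn obmix-accessors odour labels of an [OdourPanel-class].
#' @export
setGeneric("odourIds", function(x) standardGeneric("odourIds"))

#' @rdname obmix-accessors
#' @export
setMethod("odourIds", "OdourPanel", function(x) x@odourIds)

#' @describeIn obmix-accessors target-odour label.
#' @export
setGeneric("targetId", function(x) standardGeneric("targetId"))

#' @rdname obmix-accessors
#' @export
setMethod("targetId", "OdourPanel", function(x) x@targetId)

#' @describeIn obmix-accessors ROI x odour tuning matrix.
#' @export
setGeneric("tuningMatrix", function(x) standardGeneric("tuningMatrix"))

#' @rdname obmix-accessors
#' @export
setMethod("tuningMatrix", "OdourPanel", function(x) x@tuning)

#' @describeIn obmix-accessors requested tuning overlap per non-target odour.
#' @export
setGeneric("overlapSpectrum", function(x) standardGeneric("overlapSpectrum"))

#' @rdname obmix-accessors
#' @export
setMethod("overlapSpectrum", "OdourPanel", function(x) x@overlapSpectrum)

#' @describeIn obmix-accessors split x time accuracy matrix of a
#'   [DecodingResult-class].
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))

#' @rdname obmix-accessors
#' @export
setMethod("accuracies", "DecodingResult", function(x) x@accuracy)

#' @describeIn obmix-accessors time points (s, window end) of a
#'   [DecodingResult-class].
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname obmix-accessors
#' @export
setMethod("timePoints", "DecodingResult", function(x) x@timePoints)

#' @rdname obmix-accessors
#' @export
setMethod("timePoints", "CorrelationAnalysis", function(x) x@timePoint)

#' @rdname obmix-accessors
#' @export
setMethod("timePoints", "ResponseMatrix", function(x) {
    tp <- metadata(x)$timePoint
    if (is.null(tp)) NA_real_ else tp
})

#' @describeIn obmix-accessors split design label of a
#'   [DecodingResult-class].
#' @export
setGeneric("splitSpec", function(x) standardGeneric("splitSpec"))

#' @rdname obmix-accessors
#' @export
setMethod("splitSpec", "DecodingResult", function(x) x@splitSpec)

#' @describeIn obmix-accessors trial x trial correlation matrix.
#' @export
setGeneric("corrMatrix", function(x) standardGeneric("corrMatrix"))

#' @rdname obmix-accessors
#' @export
setMethod("corrMatrix", "CorrelationAnalysis", function(x) x@corr)

#' @describeIn obmix-accessors logical S+ flags per trial.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname obmix-accessors
#' @export
setMethod("classLabels", "CorrelationAnalysis", function(x) x@classLabels)

#' @describeIn obmix-accessors Rmax of a [NormalisationParams-class].
#' @export
setGeneric("Rmax", function(x) standardGeneric("Rmax"))

#' @rdname obmix-accessors
#' @export
setMethod("Rmax", "NormalisationParams", function(x) x@Rmax)

#' @describeIn obmix-accessors slope parameter s of a
#'   [NormalisationParams-class].
#' @export
setGeneric("slopeParam", function(x) standardGeneric("slopeParam"))

#' @rdname obmix-accessors
#' @export
setMethod("slopeParam", "NormalisationParams", function(x) x@s)

## show methods -------------------------------------------------------------

#' @rdname obmix-accessors
#' @export
setMethod("show", "NormalisationParams", function(object) {
    cat(sprintf("NormalisationParams: Rmax = %.4g, s = %.4g (slope at 0 = %.4g)\n",
                object@Rmax, object@s, object@Rmax * object@s / 2))
})

#' @rdname obmix-accessors
#' @export
setMethod("show", "NoiseModel", function(object) {
    cat(sprintf("NoiseModel: sd = %.4g + %.4g * |amplitude|\n",
                object@sigma0, object@slope))
})

#' @rdname obmix-accessors
#' @export
setMethod("show", "StateProfile", function(object) {
    summ <- if (is.character(object@summation)) "linear"
            else sprintf("saturating (Rmax = %.3g, s = %.3g)",
                         object@summation@Rmax, object@summation@s)
    cat(sprintf(paste0("StateProfile '%s': gain %.3g, trial noise SD %.3g, ",
                       "%s summation, lag %.3gs, tau %.3gs\n"),
                object@name, object@gain, object@trialNoiseSd, summ,
                object@onsetLagS, object@decayTauS))
})

#' @rdname obmix-accessors
#' @export
setMethod("show", "OdourPanel", function(object) {
    cat(sprintf("OdourPanel: %d odours x %d ROIs, target '%s'\n",
                length(object@odourIds), nrow(object@tuning), object@targetId))
    ov <- sort(object@overlapSpectrum, decreasing = TRUE)
    cat("  overlap spectrum:",
        paste(sprintf("%s=%.2f", names(ov), ov), collapse = ", "), "\n")
})

#' @rdname obmix-accessors
#' @export
setMethod("show", "TrialRecording", function(object) {
    cat(sprintf(paste0("TrialRecording [%s]: %d ROIs x %d frames @ %g Hz, ",
                       "onset frame %d, stimulus %s%s\n"),
                object@fovId, nrow(object@fluorescence),
                ncol(object@fluorescence), object@frameRateHz,
                object@onsetFrame, paste(object@stimulus, collapse = "+"),
                if (object@isDff) " (dF/F)" else " (raw F)"))
})

#' @rdname obmix-accessors
#' @export
setMethod("show", "CorrelationAnalysis", function(object) {
    cat(sprintf(paste0("CorrelationAnalysis: %d trials (%d S+, %d S-)",
                       "%s\n"),
                nrow(object@corr), sum(object@classLabels),
                sum(!object@classLabels),
                if (is.na(object@timePoint)) ""
                else sprintf(", t = %.2f s", object@timePoint)))
})

#' @rdname obmix-accessors
#' @export
setMethod("show", "DecodingResult", function(object) {
    cat(sprintf(paste0("DecodingResult [%s, %s]: %d splits x %d time points",
                       " (%.2f-%.2f s)\n"),
                object@fovId, object@splitSpec, nrow(object@accuracy),
                length(object@timePoints), min(object@timePoints),
                max(object@timePoints)))
})
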