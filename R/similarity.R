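## Trial-by-trial population-vector similarity and discriminability.

#' Trial-by-trial population correlation matrix
#'
#' Pearson correlation between the population (across-ROI) response vectors
#' of every pair of trials.  Trials are partitioned into S+ (stimulus
#' containing the target odour, whether as a single odour or in a binary
#' mixture) and S-.  Trials with zero-variance population vectors cannot be
#' correlated and are excluded with a warning.
#'
#' @param rm a [ResponseMatrix-class] (needs >= 2 ROIs).
#' @return a [CorrelationAnalysis-class].
#' @export
trialCorrelationMatrix <- function(rm) {
    stopifnot(is(rm, "ResponseMatrix"))
    amp <- amplitudes(rm)                       # trial x ROI
    if (ncol(amp) < 2L) stop("need at least 2 ROIs")
    v <- apply(amp, 1, stats::var)
    flat <- v == 0 | !is.finite(v)
    if (any(flat)) {
        warning("excluding ", sum(flat),
                " trial(s) with zero-variance population vectors: ",
                paste(rownames(amp)[flat], collapse = ", "))
        amp <- amp[!flat, , drop = FALSE]
    }
    if (nrow(amp) < 2L) stop("fewer than 2 usable trials")
    cc <- stats::cor(t(amp))
    labels <- trialLabels(rm)$targetPresent[!flat]
    tp <- metadata(rm)$timePoint
    new("CorrelationAnalysis", corr = cc, classLabels = labels,
        timePoint = if (is.null(tp)) NA_real_ else tp)
}

#' Within- and across-class correlation means
#'
#' Mean pairwise correlation within S+ trials, within S- trials, and across
#' the two classes.  Only off-diagonal pairs contribute and each unordered
#' pair is counted once.  A class with fewer than two trials has an
#' undefined within-class mean (`NA`).
#'
#' @param ca a [CorrelationAnalysis-class].
#' @return named numeric: `withinSplus`, `withinSminus`, `across`.
#' @export
classCorrelationSummary <- function(ca) {
    stopifnot(is(ca, "CorrelationAnalysis"))
    cc <- corrMatrix(ca)
    sp <- which(classLabels(ca))
    sm <- which(!classLabels(ca))
    if (!length(sp) || !length(sm))
        stop("both classes must be non-empty")
    offMean <- function(idx) {
        if (length(idx) < 2L) return(NA_real_)
        m <- cc[idx, idx]
        mean(m[upper.tri(m)])
    }
    c(withinSplus = offMean(sp), withinSminus = offMean(sm),
      across = mean(cc[sp, sm, drop = FALSE]))
}

#' Correlation-based discriminability index
#'
#' For each S+ trial, its mean correlation with the other S+ trials is
#' compared with its mean correlation with the S- trials; the index is the
#' proportion of S+ trials for which the within-class mean is strictly
#' higher (the distance measure is 1 - Pearson correlation, so "closer to
#' its own class" means more correlated).  Ties count as not discriminated.
#' An index of 0.5 is chance; 1 means every S+ trial sits nearer its own
#' class.
#'
#' @param ca a [CorrelationAnalysis-class]; needs >= 2 S+ and >= 1 S-
#'   trials.
#' @return scalar in \[0, 1\].
#' @export
discriminabilityIndex <- function(ca) {
    stopifnot(is(ca, "CorrelationAnalysis"))
    cc <- corrMatrix(ca)
    sp <- which(classLabels(ca))
    sm <- which(!classLabels(ca))
    if (length(sp) < 2L || length(sm) < 1L)
        stop("undefined index: need >= 2 S+ trials and >= 1 S- trial")
    hits <- vapply(sp, function(i) {
        within <- mean(cc[i, setdiff(sp, i)])
        across <- mean(cc[i, sm])
        within > across
    }, logical(1))
    mean(hits)
}

#' Time-resolved similarity summaries
#'
#' Applies [trialCorrelationMatrix()] to each time point's response matrix
#' and collects class-correlation means and the discriminability index into
#' a tidy table.
#'
#' @param rmList named list of [ResponseMatrix-class] from
#'   [slidingResponseMatrices()].
#' @return data.frame: `timePoint`, `withinSplus`, `withinSminus`,
#'   `across`, `discriminability`, `fovId`.
#' @export
similarityTimecourse <- function(rmList) {
    do.call(rbind, lapply(rmList, function(rm) {
        ca <- trialCorrelationMatrix(rm)
        s <- classCorrelationSummary(ca)
        data.frame(timePoint = timePoints(ca), withinSplus = s[["withinSplus"]],
                   withinSminus = s[["withinSminus"]], across = s[["across"]],
                   discriminability = discriminabilityIndex(ca),
                   fovId = fovId(rm), row.names = NULL)
    }))
}
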