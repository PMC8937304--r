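## Mixture-summation statistics: observed vs. linear-sum comparisons.

.stimString <- function(comps) paste(comps, collapse = "+")

## sem with n = 1 treated as 0 dispersion (single-trial estimate).
.sem <- function(x) if (length(x) < 2L) 0 else stats::sd(x) / sqrt(length(x))

#' Per-ROI observed-mixture vs. linear-sum pairs
#'
#' For a binary mixture `a + b`, computes per ROI the trial-averaged
#' observed mixture amplitude and the linear sum of the trial-averaged
#' component amplitudes, along with their s.e.m.s.  The linear-sum s.e.m.
#' is the sum of the component s.e.m.s (the joint dispersion used by
#' [deviationFromLinearity()]).
#'
#' @param rm a [ResponseMatrix-class].
#' @param componentA,componentB component odour labels.
#' @return a data.frame of class `"SummationPairs"` with columns `roiId`,
#'   `rObserved`, `rLinear`, `semObserved`, `semLinear`,
#'   `nTrialsMixture`, `nTrialsComponents`, `fovId`.
#' @examples
#' p <- makePanel(50, 3, c(0.7, 0.2), seed = 1)
#' cfg <- syntheticConfig(makeTrialList(p, 2, seed = 2), seed = 3)
#' rm <- buildResponseMatrix(simulateSession(p, statePreset("behaving"), cfg))
#' head(linearSumPairs(rm, "EB", "MB"))
#' @export
linearSumPairs <- function(rm, componentA = "EB", componentB = "MB") {
    stopifnot(is(rm, "ResponseMatrix"))
    amp <- amplitudes(rm)                       # trial x ROI
    stim <- trialLabels(rm)$stimulus
    ia <- stim == componentA
    ib <- stim == componentB
    imix <- stim %in% c(.stimString(c(componentA, componentB)),
                        .stimString(c(componentB, componentA)))
    if (!sum(ia)) stop("insufficient trials: no '", componentA, "' trials")
    if (!sum(ib)) stop("insufficient trials: no '", componentB, "' trials")
    if (!sum(imix)) stop("insufficient trials: no '",
                         .stimString(c(componentA, componentB)), "' trials")
    mA <- colMeans(amp[ia, , drop = FALSE])
    mB <- colMeans(amp[ib, , drop = FALSE])
    sA <- apply(amp[ia, , drop = FALSE], 2, .sem)
    sB <- apply(amp[ib, , drop = FALSE], 2, .sem)
    mM <- colMeans(amp[imix, , drop = FALSE])
    sM <- apply(amp[imix, , drop = FALSE], 2, .sem)
    out <- data.frame(roiId = colnames(amp), rObserved = mM,
                      rLinear = mA + mB, semObserved = sM,
                      semLinear = sA + sB, nTrialsMixture = sum(imix),
                      nTrialsComponents = sum(ia) + sum(ib),
                      fovId = fovId(rm), row.names = NULL)
    class(out) <- c("SummationPairs", "data.frame")
    out
}

.pairsArgs <- function(rObserved, rLinear) {
    if (is.data.frame(rObserved)) {
        list(obs = rObserved$rObserved, lin = rObserved$rLinear,
             semObs = rObserved$semObserved, semLin = rObserved$semLinear)
    } else {
        list(obs = rObserved, lin = rLinear, semObs = NULL, semLin = NULL)
    }
}

#' Fractional deviation from linearity
#'
#' `(rObserved - rLinear) / |rLinear|`.  Negative values indicate sublinear
#' (suppressive) summation.  ROIs whose `|rLinear|` falls below the
#' exclusion floor are returned as `NA` (the ratio is unstable near zero);
#' the excluded mask is attached as attribute `"excluded"`.
#'
#' @param rObserved a `"SummationPairs"` data.frame, or a numeric vector of
#'   observed mixture amplitudes.
#' @param rLinear numeric vector of linear sums (ignored when `rObserved`
#'   is a data.frame).
#' @param floor exclusion floor on `|rLinear|` in delta-F/F (default 0.05).
#' @return numeric vector of fractional deviations (`NA` = excluded).
#' @examples
#' fractionalDeviation(0.61, 1)   # -0.39
#' fractionalDeviation(2, -1)     #  3
#' @export
fractionalDeviation <- function(rObserved, rLinear = NULL, floor = 0.05) {
    a <- .pairsArgs(rObserved, rLinear)
    stopifnot(length(a$obs) == length(a$lin), floor >= 0)
    excluded <- abs(a$lin) < floor
    fd <- ifelse(excluded, NA_real_, (a$obs - a$lin) / abs(a$lin))
    attr(fd, "excluded") <- excluded
    fd
}

#' Deviation from linearity in joint-s.e.m. units
#'
#' `(rObserved - rLinear) / (semObserved + semLinear)`: the difference
#' between the observed mixture response and the linear sum, normalised by
#' the joint dispersion (sum of the two s.e.m.s).  Values beyond +/-2 are
#' conventionally classified as nonlinear, below -2 as sublinear.  A zero
#' joint s.e.m. yields `NA` (undefined deviation).
#'
#' @param rObserved a `"SummationPairs"` data.frame, or numeric vector.
#' @param rLinear,semObserved,semLinear numeric vectors (ignored for a
#'   data.frame input).
#' @return numeric vector of deviations (`NA` where undefined).
#' @export
deviationFromLinearity <- function(rObserved, rLinear = NULL,
                                   semObserved = NULL, semLinear = NULL) {
    a <- .pairsArgs(rObserved, rLinear)
    if (is.null(a$semObs)) {
        a$semObs <- semObserved
        a$semLin <- semLinear
    }
    stopifnot(length(a$obs) == length(a$lin),
              length(a$semObs) == length(a$obs))
    denom <- a$semObs + a$semLin
    bad <- denom <= 0
    if (any(bad))
        warning(sum(bad), " ROI(s) with zero joint s.e.m.: deviation undefined")
    ifelse(bad, NA_real_, (a$obs - a$lin) / denom)
}

#' Classify summation linearity from joint-s.e.m. deviations
#'
#' @param dev numeric deviations from [deviationFromLinearity()].
#' @param threshold classification threshold (default 2).
#' @return factor with levels `"sublinear"`, `"linear"`, `"supralinear"`.
#' @export
classifyLinearity <- function(dev, threshold = 2) {
    cut(dev, breaks = c(-Inf, -threshold, threshold, Inf),
        labels = c("sublinear", "linear", "supralinear"))
}

#' Per-field medians of the fractional deviation
#'
#' Computes the median fractional deviation over included ROIs within each
#' field of view, then summarises across fields by the median of the field
#' medians with 25th/75th percentiles (the boxplot convention used for
#' time-course summaries).
#'
#' @param pairs a `"SummationPairs"` data.frame (possibly row-bound across
#'   fields; must carry a `fovId` column).
#' @param floor exclusion floor passed to [fractionalDeviation()].
#' @return list with `perField` (data.frame: `fovId`, `median`,
#'   `nIncluded`) and `pooled` (list: `median`, `q25`, `q75`, `nFields`).
#' @export
medianFractionalDeviation <- function(pairs, floor = 0.05) {
    stopifnot(is.data.frame(pairs), "fovId" %in% names(pairs))
    fd <- fractionalDeviation(pairs, floor = floor)
    byField <- split(fd, pairs$fovId)
    med <- vapply(byField, function(x) {
        x <- x[!is.na(x)]
        if (!length(x))
            stop("empty field: all ROIs excluded in at least one field")
        stats::median(x)
    }, numeric(1))
    perField <- data.frame(fovId = names(med), median = unname(med),
                           nIncluded = vapply(byField,
                                              function(x) sum(!is.na(x)),
                                              integer(1)),
                           row.names = NULL)
    pooled <- list(median = stats::median(med),
                   q25 = unname(stats::quantile(med, 0.25)),
                   q75 = unname(stats::quantile(med, 0.75)),
                   nFields = length(med))
    list(perField = perField, pooled = pooled)
}

#' Robustness of the fractional-deviation distribution to trial noise
#'
#' Adds zero-mean Gaussian noise of each requested SD to trial amplitudes
#' \emph{before} trial averaging, recomputes the per-ROI fractional
#' deviation, and repeats.  Increasing noise broadens the deviation
#' distribution while leaving its median approximately unchanged.  With
#' `applyTo = "all"` (the default) noise lands on every trial, so the
#' linear-sum denominator is perturbed too; because the deviation is a
#' ratio, this induces small second-order median drifts and, at small SDs,
#' occasional mild IQR shrinkage.  `applyTo = "mixture"` perturbs only the
#' observed-mixture trials, which isolates the numerator: there the
#' broadening is exact and the median is unbiased.
#'
#' @param rm a [ResponseMatrix-class] containing component and mixture
#'   trials.
#' @param noiseSds numeric vector of noise SDs (delta-F/F, >= 0); include 0
#'   for the unperturbed distribution.
#' @param componentA,componentB component odour labels.
#' @param nReps Monte-Carlo repeats per SD (default 200).
#' @param seed integer seed.
#' @param floor exclusion floor passed to [fractionalDeviation()].
#' @param applyTo `"all"` (noise on every trial) or `"mixture"` (noise on
#'   observed-mixture trials only).
#' @return list of class `"NoiseRobustness"`: `deviations` (data.frame:
#'   `noiseSd`, `rep`, `roiId`, `deviation`) and `summary` (data.frame per
#'   SD: mean and Monte-Carlo SD of the per-repeat median — the yardstick
#'   for "median unaffected" is that its shift stays within the
#'   noise-induced jitter of the median itself — plus the mean per-repeat
#'   IQR).
#' @export
noiseRobustness <- function(rm, noiseSds, componentA = "EB",
                            componentB = "MB", nReps = 200L, seed = 1L,
                            floor = 0.05, applyTo = c("all", "mixture")) {
    if (any(noiseSds < 0)) stop("noise SDs must be nonnegative")
    applyTo <- match.arg(applyTo)
    stopifnot(is(rm, "ResponseMatrix"))
    amp <- amplitudes(rm)
    stim <- trialLabels(rm)$stimulus
    ia <- stim == componentA
    ib <- stim == componentB
    imix <- stim %in% c(.stimString(c(componentA, componentB)),
                        .stimString(c(componentB, componentA)))
    if (!sum(ia) || !sum(ib) || !sum(imix))
        stop("insufficient trials for components and/or mixture")
    oneDraw <- function(sdNoise) {
        noisy <- amp
        if (sdNoise > 0) {
            pert <- if (applyTo == "all") seq_len(nrow(amp)) else which(imix)
            noisy[pert, ] <- noisy[pert, ] +
                matrix(stats::rnorm(length(pert) * ncol(amp), 0, sdNoise),
                       length(pert))
        }
        rObs <- colMeans(noisy[imix, , drop = FALSE])
        rLin <- colMeans(noisy[ia, , drop = FALSE]) +
            colMeans(noisy[ib, , drop = FALSE])
        fractionalDeviation(rObs, rLin, floor = floor)
    }
    withSeed(seed, {
        rows <- list()
        for (sdNoise in noiseSds) {
            reps <- if (sdNoise == 0) 1L else as.integer(nReps)
            for (r in seq_len(reps)) {
                fd <- oneDraw(sdNoise)
                rows[[length(rows) + 1L]] <-
                    data.frame(noiseSd = sdNoise, rep = r,
                               roiId = colnames(amp), deviation = fd,
                               row.names = NULL)
            }
        }
        dev <- do.call(rbind, rows)
        summ <- do.call(rbind, lapply(split(dev, dev$noiseSd), function(d) {
            med <- vapply(split(d$deviation, d$rep),
                          function(x) stats::median(x, na.rm = TRUE),
                          numeric(1))
            iqr <- vapply(split(d$deviation, d$rep), function(x)
                diff(stats::quantile(x, c(0.25, 0.75), na.rm = TRUE)),
                numeric(1))
            data.frame(noiseSd = d$noiseSd[1], medianMean = mean(med),
                       medianSd = if (length(med) > 1) stats::sd(med) else 0,
                       iqrMean = mean(iqr), nReps = length(med),
                       row.names = NULL)
        }))
        structure(list(deviations = dev, summary = summ),
                  class = "NoiseRobustness")
    })
}

#' Masking index of background odours against a target pattern
#'
#' Works at the glomerular level on single-odour responses averaged over
#' three or more trials.  Trial-averaged target responses are z-scored
#' across glomeruli within the field of view; glomeruli with z above
#' `zThreshold` form the target-responsive set.  For each odour, the
#' per-glomerulus overlap is the background/target amplitude ratio clipped
#' to \[0, 1\] (negative responses clip to 0, so the maximum contribution
#' of a glomerulus is 1), and the masking index is the mean overlap over
#' the target-responsive set.
#'
#' @param rm a [ResponseMatrix-class] of glomerular single-odour responses.
#' @param target target odour label; defaults to the matrix's target.
#' @param zThreshold z-score threshold for target-responsive glomeruli
#'   (default 2).
#' @param overlap `"ratio"` (clipped ratio, default) or `"min"`
#'   (`min(Rbg, Rtgt)/Rtgt` with negatives clipped) — identical for
#'   positive target responses; both retained to make the interpretation
#'   explicit.
#' @param minTrials minimum trials per odour (default 3).
#' @return data.frame with `odourId`, `maskingIndex`, `nTargetGlomeruli`,
#'   one row per single odour (the target's own index is 1 by definition).
#' @export
maskingIndex <- function(rm, target = NULL, zThreshold = 2,
                         overlap = c("ratio", "min"), minTrials = 3L) {
    overlap <- match.arg(overlap)
    stopifnot(is(rm, "ResponseMatrix"))
    if (is.null(target)) target <- metadata(rm)$target
    lab <- trialLabels(rm)
    single <- lab$nComponents == 1L
    amp <- amplitudes(rm)[single, , drop = FALSE]
    stim <- lab$stimulus[single]
    odours <- unique(stim)
    if (!(target %in% odours))
        stop("no single-odour trials of the target '", target, "'")
    nPer <- table(stim)
    short <- names(nPer)[nPer < minTrials]
    if (length(short))
        stop("fewer than ", minTrials, " trials for odour(s): ",
             paste(short, collapse = ", "))
    meanResp <- vapply(odours, function(o)
        colMeans(amp[stim == o, , drop = FALSE]), numeric(ncol(amp)))
    if (stats::sd(meanResp[, target]) == 0)
        stop("no target-responsive glomeruli at z > ", zThreshold,
             ": target responses are constant across glomeruli")
    z <- as.numeric(scale(meanResp[, target]))
    responsive <- z > zThreshold
    if (!any(responsive))
        stop("no target-responsive glomeruli at z > ", zThreshold)
    rT <- meanResp[responsive, target]
    idx <- vapply(odours, function(o) {
        rB <- pmax(meanResp[responsive, o], 0)
        ov <- switch(overlap,
                     ratio = pmin(rB / rT, 1),
                     min = pmin(rB, rT) / rT)
        mean(ov)
    }, numeric(1))
    data.frame(odourId = odours, maskingIndex = unname(idx),
               nTargetGlomeruli = sum(responsive), row.names = NULL)
}

#' Load Dryad-style linear-sum/observed amplitude pairs
#'
#' Reads a two-column table per field of view — linear sum of component
#' responses and observed mixture response at the 300-1000 ms window — into
#' a `"SummationPairs"` data.frame (s.e.m. columns are `NA`: the deposited
#' pairs carry no trial dispersion).
#'
#' @param path CSV/TSV file with columns interpretable as linear sum and
#'   observed amplitude (first two numeric columns are used; common header
#'   spellings such as `linear_sum`/`observed` are recognised).
#' @param fovId field label recorded in the output.
#' @return a `"SummationPairs"` data.frame.
#' @export
readSummationPairs <- function(path, fovId = basename(path)) {
    if (!file.exists(path)) stop("file not found: ", path)
    d <- data.table::fread(path, data.table = FALSE)
    nm <- tolower(names(d))
    linCol <- which(grepl("lin", nm))[1]
    obsCol <- which(grepl("obs|mix", nm))[1]
    if (is.na(linCol) || is.na(obsCol)) {
        num <- which(vapply(d, is.numeric, logical(1)))
        if (length(num) < 2L)
            stop("need two numeric columns (linear sum, observed) in ", path)
        linCol <- num[1]; obsCol <- num[2]
    }
    out <- data.frame(roiId = sprintf("roi%03d", seq_len(nrow(d))),
                      rObserved = as.numeric(d[[obsCol]]),
                      rLinear = as.numeric(d[[linCol]]),
                      semObserved = NA_real_, semLinear = NA_real_,
                      nTrialsMixture = NA_integer_,
                      nTrialsComponents = NA_integer_, fovId = fovId,
                      row.names = NULL)
    if (any(!is.finite(out$rObserved)) || any(!is.finite(out$rLinear)))
        stop("non-finite amplitudes in ", path)
    class(out) <- c("SummationPairs", "data.frame")
    out
}
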