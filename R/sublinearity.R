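## The in-silico sublinearity experiment: linear-sum mixtures + noise,
## optional saturating normalisation, decoders trained on single odours.

#' Saturating (normalising) transform of response amplitudes
#'
#' \eqn{R^* = R_{max}\,(2/(1+e^{-sR}) - 1)}: odd, strictly increasing,
#' bounded in \eqn{(-R_{max}, R_{max})}, with slope \eqn{R_{max}s/2} at the
#' origin.  Small amplitudes pass nearly linearly; large amplitudes are
#' compressed towards the ceiling, which is what makes the transform
#' "normalising" — the sublinearity it adds grows with amplitude.
#'
#' @param R numeric amplitude(s), delta-F/F.
#' @param params a [NormalisationParams-class] (defaults Rmax = 6,
#'   s = 0.2).
#' @return transformed amplitude(s).
#' @examples
#' normaliseResponse(0)                 # 0
#' normaliseResponse(5, NormalisationParams(6, 0.2))
#' normaliseResponse(1e6)               # ~ Rmax
#' @export
normaliseResponse <- function(R, params = NormalisationParams()) {
    stopifnot(is(params, "NormalisationParams"))
    params@Rmax * (2 / (1 + exp(-params@s * R)) - 1)
}

#' Fit the saturating transform to observed mixture responses
#'
#' Unweighted least-squares fit of
#' `rObserved ~ Rmax * (2 / (1 + exp(-s * rLinear)) - 1)` over pooled ROI
#' pairs (Levenberg-Marquardt).  When the data never reach the bend of the
#' sigmoid only the product `Rmax * s / 2` (the initial slope) is
#' constrained, so the fit is flagged unidentifiable when
#' `max |s * rLinear|` stays below 1.
#'
#' @param pairs a `"SummationPairs"` data.frame (or anything with
#'   `rLinear` and `rObserved` columns) with >= 10 rows.
#' @param start optional list with starting `Rmax` and `s`.
#' @return list: `params` ([NormalisationParams-class]), `residualSd`,
#'   `identifiable`, `fit` (the `nls` object).
#' @export
fitNormalisation <- function(pairs, start = NULL) {
    stopifnot(is.data.frame(pairs),
              all(c("rLinear", "rObserved") %in% names(pairs)))
    d <- pairs[is.finite(pairs$rLinear) & is.finite(pairs$rObserved), ]
    if (nrow(d) < 10L)
        stop("need at least 10 (linear sum, observed) pairs")
    if (is.null(start)) {
        b0 <- sum(d$rLinear * d$rObserved) / sum(d$rLinear^2)
        Rmax0 <- max(1.2 * max(abs(d$rObserved)), 1e-2)
        s0 <- max(2 * b0 / Rmax0, 1e-3)
        start <- list(Rmax = Rmax0, s = s0)
    }
    fit <- tryCatch(
        minpack.lm::nlsLM(
            rObserved ~ Rmax * (2 / (1 + exp(-s * rLinear)) - 1),
            data = d, start = start,
            lower = c(Rmax = 1e-6, s = 1e-6),
            upper = c(Rmax = 1e4, s = 1e3),
            control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e)
            stop("fit failure: ", conditionMessage(e),
                 " (n = ", nrow(d), ", start Rmax = ",
                 signif(start$Rmax, 3), ", s = ", signif(start$s, 3), ")"))
    cf <- stats::coef(fit)
    identifiable <- max(abs(cf[["s"]] * d$rLinear)) >= 1
    if (!identifiable)
        warning("saturation not identifiable: data stay in the linear ",
                "range of the fitted transform (only Rmax*s/2 is ",
                "constrained)")
    list(params = NormalisationParams(Rmax = cf[["Rmax"]], s = cf[["s"]]),
         residualSd = stats::sd(stats::resid(fit)),
         identifiable = identifiable, fit = fit)
}

#' Estimate the amplitude scaling of trial noise
#'
#' For every ROI x stimulus combination with repeated trials, computes the
#' across-trial mean and SD of the response amplitude, then regresses SD on
#' |mean| (ordinary least squares, pooled over ROIs and stimuli).  The
#' regression slope is the amplitude-scaled component of the noise model;
#' the baseline SD `sigma0` is supplied by the state (0.2 anaesthetised, 2
#' awake/behaving).  A negative fitted slope is clipped to 0 with a
#' warning.
#'
#' @param rm a [ResponseMatrix-class] with trial-level amplitudes.
#' @param sigma0 baseline SD for the returned model.
#' @return a [NoiseModel-class]; the regression is attached as attribute
#'   `"fit"`.
#' @export
fitNoiseSlope <- function(rm, sigma0 = 0.2) {
    stopifnot(is(rm, "ResponseMatrix"))
    amp <- amplitudes(rm)
    if (ncol(amp) < 5L) stop("insufficient data: need >= 5 ROIs")
    stim <- trialLabels(rm)$stimulus
    keep <- names(which(table(stim) >= 2L))
    if (!length(keep)) stop("no stimulus with repeated trials")
    mu <- NULL; sdv <- NULL
    for (s in keep) {
        a <- amp[stim == s, , drop = FALSE]
        mu <- c(mu, colMeans(a))
        sdv <- c(sdv, apply(a, 2, stats::sd))
    }
    fit <- stats::lm(sdv ~ abs(mu))
    slope <- unname(stats::coef(fit)[2])
    if (slope < 0) {
        warning("negative fitted noise slope (", signif(slope, 3),
                ") clipped to 0")
        slope <- 0
    }
    out <- NoiseModel(sigma0 = sigma0, slope = slope)
    attr(out, "fit") <- fit
    out
}

## Trial-averaged single-odour responses and all two-odour linear sums.
.simulatedMixtures <- function(rm, target) {
    lab <- trialLabels(rm)
    single <- lab$nComponents == 1L
    amp <- amplitudes(rm)
    odours <- unique(lab$stimulus[single])
    if (length(odours) < 2L)
        stop("need single-odour trials of at least 2 odours")
    means <- vapply(odours, function(o)
        colMeans(amp[single & lab$stimulus == o, , drop = FALSE]),
        numeric(ncol(amp)))
    combos <- utils::combn(odours, 2L)
    sums <- vapply(seq_len(ncol(combos)), function(k)
        means[, combos[1, k]] + means[, combos[2, k]],
        numeric(nrow(means)))
    list(linearSums = t(sums),                     # mixture x ROI
         labels = apply(combos, 2, function(p) target %in% p),
         combos = combos)
}

#' Decoder accuracy on simulated mixture responses
#'
#' The in-silico experiment: per time point, a zero-intercept linear
#' decoder is trained on the session's single-odour responses (target vs.
#' other single odours); simulated mixtures are built by summing the
#' trial-averaged responses of every odour pair, adding fresh uncorrelated
#' Gaussian noise per ROI (SD = `sigma0 + slope * |amplitude|`), and —
#' optionally — applying the saturating transform.  Accuracy over the
#' simulated mixture set is recorded per noise draw.
#'
#' @param rmList list of [ResponseMatrix-class] over time points (or a
#'   single matrix).
#' @param params a [NormalisationParams-class] for the sublinear condition,
#'   or `NULL` for the linear-sum condition.
#' @param noise a [NoiseModel-class].
#' @param nReps independent noise draws per time point (default 20).
#' @param seed integer seed.
#' @param lambda ridge strength for the decoder.
#' @return a [DecodingResult-class] (`splitSpec` records the condition;
#'   rows are noise draws).
#' @export
simulateMixtureTest <- function(rmList, params = NULL, noise = NoiseModel(),
                                nReps = 20L, seed = 1L, lambda = 1) {
    rmList <- .ampStack(rmList)
    stopifnot(is.null(params) || is(params, "NormalisationParams"),
              is(noise, "NoiseModel"))
    target <- metadata(rmList[[1]])$target
    tps <- vapply(rmList, .timeOf, numeric(1))
    withSeed(seed, {
        acc <- matrix(NA_real_, nReps, length(rmList))
        for (t in seq_along(rmList)) {
            rm <- rmList[[t]]
            lab <- trialLabels(rm)
            single <- lab$nComponents == 1L
            dec <- trainLinearDecoder(amplitudes(rm)[single, , drop = FALSE],
                                      lab$targetPresent[single],
                                      lambda = lambda)
            sim <- .simulatedMixtures(rm, target)
            for (r in seq_len(nReps)) {
                sdMat <- noise@sigma0 + noise@slope * abs(sim$linearSums)
                x <- sim$linearSums +
                    matrix(stats::rnorm(length(sdMat), 0, sdMat),
                           nrow(sdMat))
                if (!is.null(params)) x <- normaliseResponse(x, params)
                acc[r, t] <- .decoderAccuracy(dec, x, sim$labels)
            }
        }
        new("DecodingResult", timePoints = tps, accuracy = acc,
            splitSpec = if (is.null(params)) "simulated_mixture_linear"
                        else "simulated_mixture_sublinear",
            nSplits = as.integer(nReps), seed = as.integer(seed),
            fovId = fovId(rmList[[1]]))
    })
}

#' Accuracy ratio of sublinear vs. linear simulated mixtures
#'
#' Expresses decoder accuracy with sublinearity as a fraction of the
#' accuracy obtained with the plain linear sum, per time bin, and averages
#' the ratio over the early (0-1.5 s) and late (1.5-3 s) phases.  Bins
#' with zero baseline accuracy are excluded with a warning.
#'
#' @param withSublinearity,linearBaseline matched [DecodingResult-class]
#'   objects from [simulateMixtureTest()].
#' @param earlyPhase,latePhase phase bounds in seconds, half-open
#'   `(lo, hi]`.
#' @return list: `timecourse` (data.frame `timePoint`, `ratio`), `early`,
#'   `late` (phase-mean ratios), `fovId`.
#' @export
accuracyRatio <- function(withSublinearity, linearBaseline,
                          earlyPhase = c(0, 1.5), latePhase = c(1.5, 3)) {
    stopifnot(is(withSublinearity, "DecodingResult"),
              is(linearBaseline, "DecodingResult"),
              all(timePoints(withSublinearity) ==
                  timePoints(linearBaseline)))
    tps <- timePoints(withSublinearity)
    aSub <- colMeans(accuracies(withSublinearity))
    aLin <- colMeans(accuracies(linearBaseline))
    zero <- aLin == 0
    if (any(zero))
        warning("excluding ", sum(zero), " bin(s) with zero baseline accuracy")
    ratio <- ifelse(zero, NA_real_, aSub / aLin)
    phaseMean <- function(ph) {
        sel <- tps > ph[1] & tps <= ph[2]
        if (!any(sel)) NA_real_ else mean(ratio[sel], na.rm = TRUE)
    }
    list(timecourse = data.frame(timePoint = tps, ratio = ratio,
                                 row.names = NULL),
         early = phaseMean(earlyPhase), late = phaseMean(latePhase),
         fovId = fovId(withSublinearity))
}

#' Compare accuracy ratios between two state groups
#'
#' Pairs the per-field phase-mean ratios of two conditions (fields matched
#' by position) and runs paired t-tests per phase, alongside one-sample
#' t-tests of each group's late-phase ratio against 1.
#'
#' @param ratiosA,ratiosB lists of [accuracyRatio()] outputs, one per
#'   field; equal length.
#' @return data.frame with one row per phase: group means, paired-t p
#'   value, and each group's p value for ratio < 1.
#' @export
compareRatioPhases <- function(ratiosA, ratiosB) {
    stopifnot(length(ratiosA) == length(ratiosB), length(ratiosA) >= 2L)
    getPhase <- function(rs, ph) vapply(rs, `[[`, numeric(1), ph)
    do.call(rbind, lapply(c("early", "late"), function(ph) {
        a <- getPhase(ratiosA, ph)
        b <- getPhase(ratiosB, ph)
        data.frame(phase = ph, meanA = mean(a), meanB = mean(b),
                   pPaired = stats::t.test(a, b, paired = TRUE)$p.value,
                   pAbelow1 = stats::t.test(a, mu = 1,
                                            alternative = "less")$p.value,
                   pBbelow1 = stats::t.test(b, mu = 1,
                                            alternative = "less")$p.value,
                   row.names = NULL)
    }))
}
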