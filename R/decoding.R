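## Time-resolved linear decoding of target-odour presence.
##
## The decoder is a linear max-margin classifier with the intercept
## constrained to zero: L2-regularised squared-hinge loss
##   f(w) = lambda/2 * ||w||^2 + mean_i max(0, 1 - y_i w.x_i)^2
## minimised by BFGS (smooth objective, analytic gradient).  The decision
## is the sign of w.x, so classification is invariant to uniform scaling.

.decoderInputs <- function(x, y) {
    if (is(x, "ResponseMatrix")) {
        y <- trialLabels(x)$targetPresent
        x <- amplitudes(x)
    }
    stopifnot(is.matrix(x), length(y) == nrow(x))
    if (is.logical(y)) y <- ifelse(y, 1, -1)
    if (!all(y %in% c(-1, 1))) stop("labels must be logical or in {-1, +1}")
    list(x = x, y = y)
}

#' Train a zero-intercept linear max-margin decoder
#'
#' @param x a [ResponseMatrix-class] (labels taken from `targetPresent`),
#'   or a trial x feature numeric matrix.
#' @param y labels (logical, or -1/+1) when `x` is a matrix.
#' @param lambda ridge penalty strength (default 1).
#' @return object of class `"linearDecoder"` with components `weights`
#'   (one per feature) and `lambda`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 2), 10), matrix(rnorm(40, -2), 10))
#' d <- trainLinearDecoder(x, rep(c(TRUE, FALSE), each = 10))
#' mean(predict(d, x) == rep(c(TRUE, FALSE), each = 10))
#' @export
trainLinearDecoder <- function(x, y = NULL, lambda = 1) {
    inp <- .decoderInputs(x, y)
    X <- inp$x; yy <- inp$y
    if (length(unique(yy)) < 2L)
        stop("invalid training set: both classes must be present")
    n <- nrow(X)
    fn <- function(w) {
        m <- 1 - yy * drop(X %*% w)
        0.5 * lambda * sum(w^2) + mean(pmax(m, 0)^2)
    }
    gr <- function(w) {
        m <- 1 - yy * drop(X %*% w)
        act <- pmax(m, 0)
        lambda * w - (2 / n) * drop(crossprod(X, yy * act))
    }
    fit <- stats::optim(rep(0, ncol(X)), fn, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-10))
    structure(list(weights = stats::setNames(fit$par, colnames(X)),
                   lambda = lambda, value = fit$value,
                   converged = fit$convergence == 0),
              class = "linearDecoder")
}

#' @describeIn trainLinearDecoder predict target presence; decision values
#'   are `x %*% weights` and class is `decision >= 0` (exact zeros classify
#'   as positive).
#' @param object a `"linearDecoder"`.
#' @param newdata trial x feature matrix or [ResponseMatrix-class].
#' @param type `"class"` (logical) or `"decision"` (numeric margin).
#' @param ... unused.
#' @export
predict.linearDecoder <- function(object, newdata,
                                  type = c("class", "decision"), ...) {
    type <- match.arg(type)
    if (is(newdata, "ResponseMatrix")) newdata <- amplitudes(newdata)
    d <- drop(newdata %*% object$weights)
    if (type == "decision") d else d >= 0
}

.decoderAccuracy <- function(decoder, x, y)
    mean(predict(decoder, x) == y)

## Draw a train/test partition with both classes on both sides, resampling
## (capped) when a side is single-class.
.classedSplit <- function(y, testFraction, cap = 20L) {
    n <- length(y)
    nTest <- max(1L, round(n * testFraction))
    for (k in seq_len(cap)) {
        test <- sample.int(n, nTest)
        if (length(unique(y[test])) == 2L &&
            length(unique(y[-test])) == 2L)
            return(list(test = test, retries = k - 1L))
    }
    stop("could not draw a split with both classes on both sides (",
         cap, " attempts)")
}

.ampStack <- function(rmList) {
    if (is(rmList, "ResponseMatrix")) rmList <- list(rmList)
    stopifnot(length(rmList) >= 1L,
              all(vapply(rmList, is, logical(1), "ResponseMatrix")))
    rmList
}

.timeOf <- function(rm) {
    tp <- metadata(rm)$timePoint
    if (is.null(tp) || is.na(tp)) responseWindow(rm)[2] else tp
}

#' Random-split decoding accuracy over time
#'
#' Trains the zero-intercept linear decoder on a random `1 - testFraction`
#' share of trials and tests on the remainder, for each time point's
#' response matrix; both training and test sets contain a random mix of
#' single-odour and mixture trials.  The partition is stratification-free;
#' draws leaving a side single-class are redrawn (logged, capped).  By
#' default the same partitions are reused across time points so the time
#' course reflects coding dynamics rather than split noise.
#'
#' @param rmList list of [ResponseMatrix-class] over time points (all built
#'   from the same trials), e.g. from [slidingResponseMatrices()]; a single
#'   matrix is accepted.
#' @param testFraction held-out fraction (default 0.2).
#' @param nSplits number of random splits (default 50).
#' @param seed integer seed.
#' @param lambda ridge strength for [trainLinearDecoder()].
#' @param fixedSplits reuse the same partitions at every time point
#'   (default `TRUE`).
#' @param shuffleLabels permute class labels independently for every split
#'   (chance-level control; default `FALSE`).
#' @return a [DecodingResult-class] with `splitSpec = "random_80_20"`.
#' @export
randomSplitAccuracy <- function(rmList, testFraction = 0.2, nSplits = 50L,
                                seed = 1L, lambda = 1, fixedSplits = TRUE,
                                shuffleLabels = FALSE) {
    rmList <- .ampStack(rmList)
    amps <- lapply(rmList, amplitudes)
    y <- trialLabels(rmList[[1]])$targetPresent
    tps <- vapply(rmList, .timeOf, numeric(1))
    withSeed(seed, {
        acc <- matrix(NA_real_, nSplits, length(rmList))
        for (s in seq_len(nSplits)) {
            ys <- if (shuffleLabels) sample(y) else y
            spFixed <- if (fixedSplits) .classedSplit(ys, testFraction)
            for (t in seq_along(amps)) {
                sp <- if (fixedSplits) spFixed
                      else .classedSplit(ys, testFraction)
                test <- sp$test
                dec <- trainLinearDecoder(amps[[t]][-test, , drop = FALSE],
                                          ys[-test], lambda = lambda)
                acc[s, t] <- .decoderAccuracy(dec,
                                              amps[[t]][test, , drop = FALSE],
                                              ys[test])
            }
        }
        new("DecodingResult", timePoints = tps, accuracy = acc,
            splitSpec = "random_80_20", nSplits = as.integer(nSplits),
            seed = as.integer(seed), fovId = fovId(rmList[[1]]))
    })
}

#' Single-odour to mixture cross-generalization accuracy
#'
#' Trains the decoder on single-odour trials only (target vs. other single
#' odours) and tests on binary-mixture trials labelled by target presence.
#' Each split subsamples a random `trainFraction` of the single-odour
#' trials (both classes enforced); all mixture trials are used for
#' testing.
#'
#' @inheritParams randomSplitAccuracy
#' @param trainFraction fraction of single-odour trials used per split
#'   (default 0.8).
#' @return a [DecodingResult-class] with
#'   `splitSpec = "train_single_test_mixture"`.
#' @export
crossGeneralizationAccuracy <- function(rmList, nSplits = 50L, seed = 1L,
                                        lambda = 1, trainFraction = 0.8) {
    rmList <- .ampStack(rmList)
    lab <- trialLabels(rmList[[1]])
    single <- lab$nComponents == 1L
    mix <- lab$nComponents == 2L
    if (!any(mix)) stop("invalid design: no mixture trials to test on")
    if (length(unique(lab$targetPresent[single])) < 2L)
        stop("invalid design: single-odour trials must include target and ",
             "non-target odours")
    y <- lab$targetPresent
    tps <- vapply(rmList, .timeOf, numeric(1))
    amps <- lapply(rmList, amplitudes)
    withSeed(seed, {
        acc <- matrix(NA_real_, nSplits, length(rmList))
        singleIdx <- which(single)
        mixIdx <- which(mix)
        nTrain <- max(2L, round(length(singleIdx) * trainFraction))
        for (s in seq_len(nSplits)) {
            for (k in seq_len(20L)) {
                tr <- sample(singleIdx, nTrain)
                if (length(unique(y[tr])) == 2L) break
                if (k == 20L) stop("could not draw a two-class training set")
            }
            for (t in seq_along(amps)) {
                dec <- trainLinearDecoder(amps[[t]][tr, , drop = FALSE],
                                          y[tr], lambda = lambda)
                acc[s, t] <- .decoderAccuracy(dec,
                                              amps[[t]][mixIdx, , drop = FALSE],
                                              y[mixIdx])
            }
        }
        new("DecodingResult", timePoints = tps, accuracy = acc,
            splitSpec = "train_single_test_mixture",
            nSplits = as.integer(nSplits), seed = as.integer(seed),
            fovId = fovId(rmList[[1]]))
    })
}

## fields x time matrix of split-averaged accuracies.
.fieldMeans <- function(results) {
    if (is.matrix(results)) {
        if (is.null(attr(results, "timePoints")))
            attr(results, "timePoints") <-
                if (!is.null(colnames(results)))
                    suppressWarnings(as.numeric(colnames(results)))
                else seq_len(ncol(results))
        return(results)
    }
    stopifnot(all(vapply(results, is, logical(1), "DecodingResult")))
    tps <- timePoints(results[[1]])
    m <- t(vapply(results, function(r) colMeans(accuracies(r)),
                  numeric(length(tps))))
    colnames(m) <- sprintf("%g", tps)
    attr(m, "timePoints") <- tps
    m
}

#' Earliest time of above-chance decoding
#'
#' Per time point, a one-sample, one-sided t-test of the field-level mean
#' accuracies against chance; the earliest significant time is the first
#' flagged window.  No multiple-comparison correction is applied (each
#' window is tested at `alpha`).  Degenerate cases with zero variance
#' across fields are flagged significant only if the common value exceeds
#' chance.
#'
#' @param results list of [DecodingResult-class], one per field (>= 3), or
#'   a fields x time accuracy matrix.
#' @param chance chance level (default 0.5).
#' @param alpha significance level (default 0.05).
#' @return data.frame (`timePoint`, `meanAccuracy`, `p`, `significant`)
#'   with the earliest significant time in attribute `"earliest"` (`NA` if
#'   never significant).
#' @export
accuracySignificance <- function(results, chance = 0.5, alpha = 0.05) {
    m <- .fieldMeans(results)
    if (nrow(m) < 3L)
        stop("insufficient replicates: need >= 3 fields")
    tps <- attr(m, "timePoints")
    if (is.null(tps)) tps <- as.numeric(colnames(m))
    p <- vapply(seq_len(ncol(m)), function(j) {
        x <- m[, j]
        if (stats::sd(x) == 0)
            return(if (mean(x) > chance) 0 else 1)
        stats::t.test(x, mu = chance, alternative = "greater")$p.value
    }, numeric(1))
    out <- data.frame(timePoint = tps, meanAccuracy = colMeans(m), p = p,
                      significant = p < alpha, row.names = NULL)
    attr(out, "earliest") <- if (any(out$significant))
        out$timePoint[which(out$significant)[1]] else NA_real_
    out
}

#' Tie-corrected rank-sum z statistic
#'
#' Normal approximation to the two-sample Wilcoxon rank-sum statistic with
#' tie correction and no continuity correction; positive z means the first
#' sample ranks higher.  All-tied samples give z = 0 with a warning.
#'
#' @param x,y numeric samples.
#' @return scalar z.
#' @export
ranksumZ <- function(x, y) {
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    r <- rank(c(x, y))
    W <- sum(r[seq_len(n1)])
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    tieTerm <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    if (sigma2 <= 0) {
        warning("all observations tied: z = 0")
        return(0)
    }
    (W - mu) / sqrt(sigma2)
}

#' Rank-sum z time course between two groups of decoding results
#'
#' Per time point, compares the field-level mean accuracies of two groups
#' with [ranksumZ()] (the approximate z of the rank-sum test).
#'
#' @param resultsA,resultsB lists of [DecodingResult-class] (or fields x
#'   time matrices); each group needs >= 3 fields.
#' @return data.frame: `timePoint`, `z`, `nA`, `nB`.
#' @export
ranksumZTimecourse <- function(resultsA, resultsB) {
    a <- .fieldMeans(resultsA)
    b <- .fieldMeans(resultsB)
    if (nrow(a) < 3L || nrow(b) < 3L)
        stop("need >= 3 fields per group")
    stopifnot(ncol(a) == ncol(b))
    tps <- attr(a, "timePoints")
    z <- vapply(seq_len(ncol(a)), function(j) ranksumZ(a[, j], b[, j]),
                numeric(1))
    data.frame(timePoint = tps, z = z, nA = nrow(a), nB = nrow(b),
               row.names = NULL)
}
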