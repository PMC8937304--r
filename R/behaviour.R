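## Go/No-Go behavioural metrics.

#' Classify a trial's behavioural response
#'
#' Anticipatory licks within the 3-s response window are compared against
#' the lick threshold (default 2): on rewarded trials two or more licks is
#' a hit and fewer a miss; on unrewarded trials one lick or less is a
#' correct rejection and anything at or above threshold a false alarm.
#'
#' @param licks integer lick count(s).
#' @param rewarded logical flag(s).
#' @param threshold anticipatory-lick threshold (default 2).
#' @return factor with levels `"hit"`, `"miss"`, `"false_alarm"`,
#'   `"correct_rejection"`.
#' @examples
#' classifyResponse(c(2, 1, 5, 0), c(TRUE, FALSE, FALSE, TRUE))
#' @export
classifyResponse <- function(licks, rewarded, threshold = 2L) {
    stopifnot(length(licks) == length(rewarded), all(licks >= 0))
    out <- ifelse(rewarded,
                  ifelse(licks >= threshold, "hit", "miss"),
                  ifelse(licks <= threshold - 1L, "correct_rejection",
                         "false_alarm"))
    factor(out, levels = c("hit", "miss", "false_alarm",
                           "correct_rejection"))
}

.isCorrect <- function(licks, rewarded, threshold = 2L)
    classifyResponse(licks, rewarded, threshold) %in%
        c("hit", "correct_rejection")

#' Blockwise learning curve and trials to criterion
#'
#' Accuracy — (hits + correct rejections) / block — over non-overlapping
#' consecutive blocks of `block` trials, in presentation order.  A trailing
#' partial block is reported separately and does not enter the criterion
#' scan.  Trials-to-criterion is the end index of the first full block
#' whose accuracy reaches `criterion`.
#'
#' @param trials data.frame with columns `anticipatoryLicks` and
#'   `rewarded` (e.g. from [simulateBehaviour()]), in trial order.
#' @param block block size (default 50).
#' @param criterion accuracy criterion (default 0.8).
#' @param threshold lick threshold for [classifyResponse()].
#' @return list: `blocks` (data.frame `block`, `trials`, `accuracy`),
#'   `partial` (accuracy of the trailing partial block, or `NA`),
#'   `trialsToCriterion` (`NA` if never reached).
#' @export
learningCurve <- function(trials, block = 50L, criterion = 0.8,
                          threshold = 2L) {
    stopifnot(is.data.frame(trials), nrow(trials) >= block)
    ok <- .isCorrect(trials$anticipatoryLicks, trials$rewarded, threshold)
    nFull <- nrow(trials) %/% block
    acc <- vapply(seq_len(nFull), function(b)
        mean(ok[((b - 1L) * block + 1L):(b * block)]), numeric(1))
    rest <- if (nrow(trials) > nFull * block)
        mean(ok[(nFull * block + 1L):nrow(trials)]) else NA_real_
    reached <- which(acc >= criterion)
    list(blocks = data.frame(block = seq_len(nFull),
                             trials = seq_len(nFull) * block,
                             accuracy = acc, row.names = NULL),
         partial = rest,
         trialsToCriterion = if (length(reached)) reached[1] * block
                             else NA_integer_)
}

#' Lick preference index per background odour
#'
#' `(lickRewarded - lickUnrewarded) / (lickRewarded + lickUnrewarded)`,
#' where the two terms are the mean anticipatory-lick counts on rewarded
#' and unrewarded trials sharing the background odour.  The index lies in
#' \[-1, 1\]; 1 means all anticipatory licks occurred on rewarded trials
#' only.  Backgrounds with licks on neither trial type give `NA`
#' (undefined), and backgrounds lacking one trial type raise an error.
#'
#' @param trials data.frame with columns `backgroundId`, `rewarded`,
#'   `anticipatoryLicks`.
#' @return data.frame: `backgroundId`, `index`, `meanLicksRewarded`,
#'   `meanLicksUnrewarded`, `nTrials`.
#' @export
lickPreferenceIndex <- function(trials) {
    stopifnot(is.data.frame(trials),
              all(c("backgroundId", "rewarded", "anticipatoryLicks") %in%
                  names(trials)))
    do.call(rbind, lapply(split(trials, trials$backgroundId), function(d) {
        if (!any(d$rewarded) || !any(!d$rewarded))
            stop("background '", d$backgroundId[1],
                 "' lacks rewarded and/or unrewarded trials")
        lr <- mean(d$anticipatoryLicks[d$rewarded])
        lu <- mean(d$anticipatoryLicks[!d$rewarded])
        idx <- if (lr + lu == 0) NA_real_ else (lr - lu) / (lr + lu)
        data.frame(backgroundId = d$backgroundId[1], index = idx,
                   meanLicksRewarded = lr, meanLicksUnrewarded = lu,
                   nTrials = nrow(d), row.names = NULL)
    }))
}

#' Per-background accuracy table
#'
#' Accuracy split by background odour and reward type — the per-odour
#' accuracy heat-map data for a session.
#'
#' @inheritParams lickPreferenceIndex
#' @param threshold lick threshold.
#' @return data.frame: `backgroundId`, `rewarded`, `accuracy`, `nTrials`.
#' @export
backgroundAccuracy <- function(trials, threshold = 2L) {
    ok <- .isCorrect(trials$anticipatoryLicks, trials$rewarded, threshold)
    agg <- stats::aggregate(ok,
                            by = list(backgroundId = trials$backgroundId,
                                      rewarded = trials$rewarded),
                            FUN = function(x) c(mean(x), length(x)))
    data.frame(backgroundId = agg$backgroundId, rewarded = agg$rewarded,
               accuracy = agg$x[, 1], nTrials = as.integer(agg$x[, 2]),
               row.names = NULL)
}
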