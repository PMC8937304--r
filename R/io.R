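## Session I/O and the reproducible pipeline runner.
##
## On-disk layout of a session: a directory with `manifest.csv` (one row
## per trial: stimulus and acquisition metadata plus the trial's file name)
## and one CSV array per trial (ROI x frame, ROI ids in the first column).
## Doubles are serialised with "%.17g", which round-trips exactly.

.manifestCols <- c("trial", "file", "stimulus", "frameRateHz", "onsetFrame",
                   "rewarded", "state", "fovId", "isDff", "nRois", "nFrames")

#' Write a session to a directory
#'
#' @param trials list of [TrialRecording-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [loadSession()]
#' @export
writeSession <- function(trials, dir) {
    stopifnot(length(trials) >= 1L,
              all(vapply(trials, is, logical(1), "TrialRecording")))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- do.call(rbind, lapply(seq_along(trials), function(i) {
        tr <- trials[[i]]
        data.frame(trial = i, file = sprintf("trial%03d.csv", i),
                   stimulus = paste(stimulus(tr), collapse = "+"),
                   frameRateHz = frameRate(tr), onsetFrame = onsetFrame(tr),
                   rewarded = tr@rewarded, state = tr@state,
                   fovId = fovId(tr), isDff = isDff(tr),
                   nRois = nRois(tr), nFrames = ncol(fluorescence(tr)),
                   row.names = NULL)
    }))
    for (i in seq_along(trials)) {
        f <- fluorescence(trials[[i]])
        d <- data.frame(roiId = if (is.null(rownames(f)))
                            sprintf("roi%d", seq_len(nrow(f)))
                        else rownames(f),
                        matrix(sprintf("%.17g", f), nrow = nrow(f)))
        names(d) <- c("roiId", sprintf("f%d", seq_len(ncol(f)) - 1L))
        data.table::fwrite(d, file.path(dir, manifest$file[i]))
    }
    data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
    invisible(dir)
}

#' Load a session from a directory
#'
#' Validates the manifest against the stored arrays (frame counts, onset
#' index, ROI counts) and reconstructs the trial list.
#'
#' @param dir directory written by [writeSession()].
#' @return list of [TrialRecording-class].
#' @export
loadSession <- function(dir) {
    mf <- file.path(dir, "manifest.csv")
    if (!file.exists(mf)) stop("no manifest.csv in ", dir)
    manifest <- data.table::fread(mf, data.table = FALSE)
    miss <- setdiff(.manifestCols, names(manifest))
    if (length(miss))
        stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
    lapply(seq_len(nrow(manifest)), function(i) {
        row <- manifest[i, ]
        if (is.na(row$onsetFrame))
            stop("trial ", row$trial, ": missing onset frame")
        path <- file.path(dir, row$file)
        if (!file.exists(path))
            stop("trial ", row$trial, ": array file not found: ", row$file)
        d <- data.table::fread(path, data.table = FALSE,
                               colClasses = list(character = "roiId"))
        f <- as.matrix(d[, -1, drop = FALSE])
        storage.mode(f) <- "double"
        dimnames(f) <- list(d$roiId, NULL)
        if (nrow(f) != row$nRois || ncol(f) != row$nFrames)
            stop("trial ", row$trial, ": array shape ", nrow(f), "x",
                 ncol(f), " does not match manifest (", row$nRois, "x",
                 row$nFrames, ")")
        TrialRecording(f, frameRateHz = row$frameRateHz,
                       onsetFrame = row$onsetFrame,
                       stimulus = strsplit(row$stimulus, "+",
                                           fixed = TRUE)[[1]],
                       rewarded = row$rewarded, state = row$state,
                       fovId = row$fovId, isDff = row$isDff)
    })
}

#' Export a response matrix as labelled CSV
#'
#' Trials as rows (with stimulus labels), ROIs as columns.
#'
#' @param rm a [ResponseMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportResponseMatrix <- function(rm, path) {
    d <- cbind(trialLabels(rm), as.data.frame(amplitudes(rm)))
    data.table::fwrite(d, path, row.names = FALSE)
    invisible(path)
}

.logLine <- function(log, ...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log, append = TRUE, sep = "")
}

#' Run the standard analysis pipeline on synthetic sessions
#'
#' A reproducible end-to-end run: simulate one session per requested state,
#' build response matrices, compute summation pairs with per-field medians,
#' similarity/discriminability time courses and decoding accuracies, and
#' write tidy outputs, a log, and a resolved-config snapshot into a run
#' directory.  Outputs are deterministic given the config's seed.
#'
#' @param config a named list (or path to a YAML file) with any of:
#'   `seed` (mandatory), `states`, `nRois`, `nOdours`, `targetOverlaps`,
#'   `nBlocks`, `timePoints`, `nSplits`, `window`.  Unset fields fall back
#'   to defaults.
#' @param outDir run directory (created; must not exist unless
#'   `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with the computed objects per state.
#' @export
runPipeline <- function(config, outDir, overwrite = FALSE) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    if (is.null(config$seed))
        stop("config must set a seed: stochastic stages require one")
    defaults <- list(states = c("anaesthetised", "behaving"), nRois = 100L,
                     nOdours = 6L,
                     targetOverlaps = c(0.8, 0.6, 0.4, 0.3, 0.2),
                     nBlocks = 4L, timePoints = seq(0.5, 3, 0.5),
                     nSplits = 20L, window = c(0, 1))
    cfg <- utils::modifyList(defaults, config)
    if (dir.exists(outDir) && !overwrite)
        stop("output directory exists: ", outDir)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(outDir, "run.log")
    cat("", file = log)
    .logLine(log, "obmix ", as.character(utils::packageVersion("obmix")),
             " pipeline run, seed ", cfg$seed)
    yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))

    results <- list()
    for (si in seq_along(cfg$states)) {
        state <- cfg$states[si]
        .logLine(log, "simulating state ", state)
        panel <- makePanel(cfg$nRois, cfg$nOdours, cfg$targetOverlaps,
                           seed = cfg$seed + 101L * si)
        sc <- syntheticConfig(makeTrialList(panel, cfg$nBlocks,
                                            seed = cfg$seed + 7L * si),
                              seed = cfg$seed + 13L * si)
        trials <- simulateSession(panel, statePreset(state), sc,
                                  fovId = paste0(state, "_fov1"))
        rm <- buildResponseMatrix(trials, window = cfg$window)
        exportResponseMatrix(rm, file.path(outDir,
                                           paste0(state, "_amplitudes.csv")))

        pairs <- linearSumPairs(rm)
        fd <- fractionalDeviation(pairs)
        nExcl <- sum(attr(fd, "excluded"))
        if (nExcl)
            .logLine(log, state, ": ", nExcl,
                     " ROI(s) below the |linear sum| floor excluded")
        pairs$fractionalDeviation <- as.numeric(fd)
        pairs$deviationFromLinearity <- deviationFromLinearity(pairs)
        data.table::fwrite(pairs, file.path(outDir,
                                            paste0(state, "_pairs.csv")))

        rmT <- slidingResponseMatrices(trials, cfg$timePoints)
        simil <- similarityTimecourse(rmT)
        data.table::fwrite(simil,
                           file.path(outDir,
                                     paste0(state, "_similarity.csv")))
        dec <- randomSplitAccuracy(rmT, nSplits = cfg$nSplits,
                                   seed = cfg$seed + 23L * si)
        decTidy <- data.frame(
            timePoint = rep(timePoints(dec), each = nrow(accuracies(dec))),
            split = rep(seq_len(nrow(accuracies(dec))),
                        times = length(timePoints(dec))),
            accuracy = as.numeric(accuracies(dec)),
            design = splitSpec(dec), fovId = fovId(dec))
        data.table::fwrite(decTidy,
                           file.path(outDir,
                                     paste0(state, "_decoding.csv")))
        results[[state]] <- list(panel = panel, responseMatrix = rm,
                                 pairs = pairs, similarity = simil,
                                 decoding = dec)
        .logLine(log, state, ": done")
    }
    meds <- lapply(results, function(r)
        medianFractionalDeviation(r$pairs)$pooled$median)
    jsonlite::write_json(
        list(package = as.character(utils::packageVersion("obmix")),
             seed = cfg$seed, medianFractionalDeviation = meds),
        file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
    .logLine(log, "pipeline complete")
    invisible(results)
}
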