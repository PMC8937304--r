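test_that("the zero-intercept decoder solves origin-separable problems", {
    set.seed(11)
    x <- rbind(matrix(rnorm(200, 3), 20), matrix(rnorm(200, -3), 20))
    y <- rep(c(TRUE, FALSE), each = 20)
    dec <- trainLinearDecoder(x, y)
    expect_true(dec$converged)
    expect_equal(mean(predict(dec, x) == y), 1)
    ## class swap flips the weight vector (up to optimiser tolerance)
    dec2 <- trainLinearDecoder(x, !y)
    expect_equal(dec2$weights, -dec$weights, tolerance = 1e-4)
    ## all-zero features carry no signal: prediction is constant
    z <- matrix(0, 40, 10)
    decZ <- trainLinearDecoder(z, y)
    expect_equal(sum(abs(decZ$weights)), 0)
    expect_equal(mean(predict(decZ, z) == y), 0.5)  # balanced base rate
    expect_error(trainLinearDecoder(x, rep(TRUE, 40)), "both classes")
})

test_that("the decoder agrees with an independent SVM on separable data", {
    skip_if_not_installed("e1071")
    set.seed(12)
    x <- rbind(matrix(rnorm(300, 2), 30), matrix(rnorm(300, -2), 30))
    y <- rep(c(TRUE, FALSE), each = 30)
    dec <- trainLinearDecoder(x, y)
    sv <- e1071::svm(x, factor(y), kernel = "linear", scale = FALSE)
    xt <- matrix(rnorm(200, rep(c(2, -2), each = 10)), 20)
    expect_equal(unname(predict(dec, xt)),
                 as.logical(as.character(predict(sv, xt))))
})

test_that("decoder output is invariant to consistent ROI permutation", {
    set.seed(13)
    x <- rbind(matrix(rnorm(150, 1), 15), matrix(rnorm(150, -1), 15))
    y <- rep(c(TRUE, FALSE), each = 15)
    xt <- matrix(rnorm(100), 10)
    perm <- sample(ncol(x))
    p1 <- predict(trainLinearDecoder(x, y), xt, type = "decision")
    p2 <- predict(trainLinearDecoder(x[, perm], y), xt[, perm],
                  type = "decision")
    expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("random-split accuracy separates post-onset and not pre-onset", {
    s <- quickSession("anaesthetised", nRois = 60, nBlocks = 3, seed = 131)
    rmT <- slidingResponseMatrices(s$trials, timePoints = c(-0.5, 1, 2))
    res <- randomSplitAccuracy(rmT, nSplits = 15, seed = 132)
    acc <- colMeans(accuracies(res))
    expect_true(all(accuracies(res) >= 0 & accuracies(res) <= 1))
    expect_equal(acc[[1]], 0.5, tolerance = 0.12)     # pre-onset: chance
    expect_gt(acc[[2]], 0.9)                          # separable post-onset
    ## reproducible given the seed
    res2 <- randomSplitAccuracy(rmT, nSplits = 15, seed = 132)
    expect_identical(accuracies(res), accuracies(res2))
    ## label-shuffled control sits at chance
    sh <- randomSplitAccuracy(rmT[2], nSplits = 40, seed = 133,
                              shuffleLabels = TRUE)
    expect_equal(mean(accuracies(sh)), 0.5, tolerance = 0.1)
})

test_that("ridge strength barely moves separable accuracies over a decade", {
    s <- quickSession("anaesthetised", nRois = 60, nBlocks = 3, seed = 141)
    rm <- buildResponseMatrix(s$trials)
    accs <- vapply(c(0.3, 1, 3), function(l)
        mean(accuracies(randomSplitAccuracy(rm, nSplits = 10, seed = 142,
                                            lambda = l))), numeric(1))
    expect_lt(diff(range(accs)), 0.1)
})

test_that("cross-generalization trains on singles and tests on mixtures", {
    s <- quickSession("anaesthetised", nRois = 80, nBlocks = 4, seed = 151)
    rm <- buildResponseMatrix(s$trials)
    res <- crossGeneralizationAccuracy(rm, nSplits = 10, seed = 152)
    expect_identical(splitSpec(res), "train_single_test_mixture")
    expect_gt(mean(accuracies(res)), 0.5)
    ## sessions without mixtures cannot run this design
    singlesOnly <- Filter(function(tr) length(stimulus(tr)) == 1L, s$trials)
    expect_error(crossGeneralizationAccuracy(
        buildResponseMatrix(singlesOnly), nSplits = 2, seed = 1),
        "invalid design")
    ## a perfect decoder tested on target-absent mixtures only measures
    ## specificity: all-correct on that set
    v <- c(5, 0, 0, 0); w <- c(0, 5, 0, 0); u <- c(0, 0, 5, 0)
    rmSpec <- exactResponseMatrix(list(
        "EB" = list(v, v), "MV" = list(w, w), "ET" = list(u, u),
        "MV+ET" = list(w + u, w + u)))
    resSpec <- crossGeneralizationAccuracy(rmSpec, nSplits = 5, seed = 3,
                                           trainFraction = 1)
    expect_equal(mean(accuracies(resSpec)), 1)
})

test_that("significance scan flags the earliest above-chance window", {
    ## all fields exactly at chance: never significant
    m <- matrix(0.5, 4, 5); colnames(m) <- 1:5
    out <- accuracySignificance(m)
    expect_false(any(out$significant))
    expect_true(is.na(attr(out, "earliest")))
    ## all fields at 1 from the second window on
    m2 <- cbind(`0` = rep(0.5, 4), `1` = rep(1, 4), `2` = rep(1, 4))
    out2 <- accuracySignificance(m2)
    expect_equal(attr(out2, "earliest"), 1)
    expect_error(accuracySignificance(m[1:2, ]), "insufficient")
    ## null calibration: false-positive rate per window is about alpha
    set.seed(14)
    fp <- mean(replicate(400, {
        x <- matrix(rnorm(8, 0.5, 0.05), 8, 1, dimnames = list(NULL, "1"))
        accuracySignificance(x)$significant
    }))
    expect_equal(fp, 0.05, tolerance = 0.5)
})

test_that("rank-sum z matches closed forms and flips with group order", {
    expect_warning(z0 <- ranksumZ(rep(1, 5), rep(1, 5)), "tied")
    expect_equal(z0, 0)
    ## completely separated groups of sizes (5, 5): |z| at the maximum
    ## rank-sum W = 40, mu = 27.5, sigma = sqrt(5 * 5 * 11 / 12)
    zMax <- (40 - 27.5) / sqrt(5 * 5 * 11 / 12)
    expect_equal(ranksumZ(6:10, 1:5), zMax)
    expect_equal(ranksumZ(1:5, 6:10), -zMax)
    ## antisymmetry on arbitrary data
    set.seed(15)
    a <- rnorm(7); b <- rnorm(9, 0.5)
    expect_equal(ranksumZ(a, b), -ranksumZ(b, a))
    ## the implied two-sided p agrees with wilcox.test's normal approximation
    p <- 2 * pnorm(-abs(ranksumZ(a, b)))
    pw <- wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
    expect_equal(p, pw, tolerance = 1e-8)
    ## time-course wrapper
    ma <- matrix(rnorm(12, 0.7, 0.01), 4, 3, dimnames = list(NULL, 1:3))
    mb <- matrix(rnorm(12, 0.5, 0.01), 4, 3, dimnames = list(NULL, 1:3))
    tc <- ranksumZTimecourse(ma, mb)
    expect_true(all(tc$z > 0))
    expect_equal(nrow(tc), 3L)
})
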