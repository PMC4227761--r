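test_that("EM recovers mixture structure and is deterministic given a seed", {
    set.seed(101)
    sizes <- c(rnorm(300, 49, 2), rnorm(200, 13, 2))
    m1 <- estimatePairSizeModel(sizes, C = 2L, seed = 5L)
    m2 <- estimatePairSizeModel(sizes, C = 2L, seed = 5L)
    expect_identical(m1@mean, m2@mean)
    expect_identical(mixtureLogLik(m1), mixtureLogLik(m2))
    # dominant component is the 60% mode near 49
    expect_gt(expectedPairSize(m1), 47)
    expect_lt(expectedPairSize(m1), 51)
    expect_true(m1@converged)
    # log-likelihood nondecreasing at every iteration
    expect_true(all(diff(mixtureLogLik(m1)) >= -1e-8))
})

test_that("EM agrees with an independent mixture fit (mclust)", {
    skip_if_not_installed("mclust")
    suppressPackageStartupMessages(library(mclust))  # Mclust needs attach
    set.seed(55)
    sizes <- c(rnorm(250, 49, 2), rnorm(150, 13, 2))
    ours <- estimatePairSizeModel(sizes, C = 2L, seed = 2L)
    ref <- mclust::Mclust(sizes, G = 2, modelNames = "V", verbose = FALSE)
    refMeans <- sort(as.numeric(ref$parameters$mean))
    expect_equal(sort(ours@mean), refMeans, tolerance = 0.05)
    refDom <- refMeans[which.max(tapply(ref$parameters$pro,
                                        order(ref$parameters$mean), sum))]
    expect_equal(expectedPairSize(ours), refDom, tolerance = 0.05)
})

test_that("degenerate and closed-form size fits behave as documented", {
    # all sizes identical: point mass, muT exact, dominant weight ~ 1
    expect_warning(m <- estimatePairSizeModel(rep(49, 30), C = 2L),
                   "degenerate")
    expect_equal(expectedPairSize(m), 49)
    expect_gt(kernelWidth(m), 0)
    # C = 1: closed form, sample mean / sd
    sizes <- c(rnorm(50, 30, 4))
    m1 <- estimatePairSizeModel(sizes, C = 1L)
    expect_equal(expectedPairSize(m1), mean(sizes))
    expect_equal(m1@sigmaT, sd(sizes))
    # too few sizes: actionable error
    expect_error(estimatePairSizeModel(rnorm(10, 49, 2)), "manually")
    # manual fallback
    mm <- pairSizeModel(25)
    expect_equal(expectedPairSize(mm), 25)
    expect_equal(kernelWidth(mm), 4)
})

test_that("pair-score kernel is exact, symmetric and decreasing from muT", {
    expect_equal(weightPairScore(10, 49, muT = 49, K = 6), 10)
    expect_equal(weightPairScore(10, 55, muT = 49, K = 6), 10 * exp(-1))
    expect_equal(weightPairScore(10, 55, muT = 49, K = 6), 3.679,
                 tolerance = 1e-4)
    # symmetry about muT and strict monotone decay in |d - muT|
    d <- 0:100
    w <- weightPairScore(1, d, muT = 50, K = 8)
    expect_equal(w, rev(w))
    expect_true(all(diff(w[d >= 50]) < 0))
    model <- pairSizeModel(49, sigmaT = 3)
    expect_equal(weightPairScore(7, 49, model), 7)
})

test_that("Fisher combination matches the chi-squared(4 df) tail exactly", {
    grid <- expand.grid(p1 = c(1e-6, 1e-3, 0.01, 0.05, 0.2, 0.5, 0.9, 1),
                        p2 = c(1e-6, 1e-3, 0.01, 0.05, 0.2, 0.5, 0.9, 1))
    got <- fisherCombine(grid$p1, grid$p2)
    oracle <- pchisq(-2 * log(grid$p1 * grid$p2), df = 4, lower.tail = FALSE)
    expect_lt(max(abs(got - oracle)), 1e-10)
    expect_equal(fisherCombine(1, 1), 1)
    expect_equal(fisherCombine(0.05, 0.05), 0.0025 * (1 - log(0.0025)))
    # monotone in each argument; bounded between q and 1
    p <- seq(0.01, 1, by = 0.01)
    expect_true(all(diff(fisherCombine(p, 0.3)) > 0))
    expect_true(all(got >= grid$p1 * grid$p2 - 1e-15 & got <= 1 + 1e-15))
    expect_error(fisherCombine(0, 0.5), "0, 1")
    expect_error(fisherCombine(0.5, 1.2), "0, 1")
})

test_that("trivial matchings: singleton pair, inadmissible geometry", {
    model <- pairSizeModel(49, sigmaT = 2)
    f <- makePeaks(100, "+", 50, 0.01)
    r <- makePeaks(148, "-", 40, 0.01)
    m <- stableMatch(f, r, model)
    expect_equal(nrow(m), 1L)
    expect_equal(m$dObs, 49)
    expect_equal(m$sObs, 90)
    # reverse borders upstream of the forward border: nothing admissible
    rUp <- makePeaks(50, "-", 40, 0.01)
    expect_equal(nrow(stableMatch(f, rUp, model)), 0L)
    # empty side
    expect_equal(nrow(stableMatch(f[0], r, model)), 0L)
})

test_that("random instances never contain a blocking pair (oracle check)", {
    set.seed(202)
    model <- pairSizeModel(49, sigmaT = 6, K = 12)
    maxSpan <- 200
    for (i in 1:200) {
        nf <- sample(1:5, 1); nr <- sample(1:5, 1)
        f <- makePeaks(sort(sample(1000:1400, nf)), rep("+", nf),
                       runif(nf, 5, 100), runif(nf, 1e-4, 0.05))
        r <- makePeaks(sort(sample(1000:1400, nr)), rep("-", nr),
                       runif(nr, 5, 100), runif(nr, 1e-4, 0.05))
        m <- stableMatch(f, r, model, maxSpan = maxSpan)
        d <- outer(start(f), start(r), function(a, b) b - a + 1)
        admissible <- d >= 1 & d <= maxSpan
        sw <- weightPairScore(outer(f$signal, r$signal, "+"), d, model)
        dev <- abs(d - expectedPairSize(model))
        expect_null(findBlockingPair(m, sw, dev, admissible,
                                     start(f), start(r)))
        # matched pairs are admissible and each border used at most once
        expect_true(all(admissible[cbind(m$f, m$r)]))
        expect_false(any(duplicated(m$f)) || any(duplicated(m$r)))
    }
})

test_that("double-stop geometry pairs outer with outer, inner with inner", {
    # F1 < F2 < R2 < R1 around one site: outer pair F1-R1 spans 49 bp,
    # inner pair F2-R2 spans 13 bp; crossing pairs span 31 bp
    model <- pairSizeModel(49, sigmaT = 2, K = 6)
    f <- makePeaks(c(100, 118), c("+", "+"), c(80, 60), c(0.01, 0.02))
    r <- makePeaks(c(130, 148), c("-", "-"), c(55, 75), c(0.02, 0.01))
    m <- stableMatch(f, r, model, maxSpan = 100)
    m <- m[order(m$f), ]
    expect_equal(m$f, c(1L, 2L))
    expect_equal(m$r, c(2L, 1L))        # F1-R1, F2-R2
    expect_equal(sort(m$dObs), c(13, 49))
    # enumeration oracle: F1-R1/F2-R2 beats both crossing alternatives for
    # every participant with muT = 49
    swF1R1 <- weightPairScore(80 + 75, 49, model)
    swF1R2 <- weightPairScore(80 + 55, 31, model)
    expect_gt(swF1R1, swF1R2)
})

test_that("pair calling filters by combined p-value and keeps invariants", {
    model <- pairSizeModel(49, sigmaT = 2, K = 6)
    peaks <- c(
        makePeaks(c(100, 148), c("+", "-"), c(50, 60), c(0.01, 0.02),
                  region = 1L),
        makePeaks(c(300, 348), c("+", "-"), c(10, 12), c(0.9, 0.9),
                  region = 2L))
    pairs <- callBorderPairs(peaks, model, alphaPair = 0.05)
    expect_length(pairs, 1L)   # weak region fails fisherCombine(0.9, 0.9)
    expect_equal(start(pairs), 100L)
    expect_equal(end(pairs), 148L)
    expect_equal(pairs$dObs, 49)
    expect_equal(pairs$pPair, fisherCombine(0.01, 0.02))
    expect_gte(pairs$pPair, pairs$pForward * pairs$pReverse)
    expect_lte(pairs$sWeighted, pairs$sObs)
    # no reverse border in a region -> no pairs
    solo <- makePeaks(500, "+", 50, 0.01, region = 3L)
    expect_length(callBorderPairs(solo, model), 0L)
})

test_that("high-confidence sizes come only from unambiguous regions", {
    peaks <- c(
        makePeaks(c(100, 148), c("+", "-"), c(5, 5), c(0.01, 0.01),
                  region = 1L),                     # one F, one R: size 49
        makePeaks(c(200, 210, 260), c("+", "+", "-"), rep(5, 3),
                  rep(0.01, 3), region = 2L),       # two F: ambiguous
        makePeaks(c(400, 350), c("+", "-"), c(5, 5), c(0.01, 0.01),
                  region = 3L))                     # R upstream of F
    expect_equal(highConfidenceSizes(peaks), 49)
})

test_that("border pairs export as BED6+4", {
    model <- pairSizeModel(49, sigmaT = 2, K = 6)
    peaks <- makePeaks(c(100, 148), c("+", "-"), c(50, 60), c(0.01, 0.02))
    pairs <- callBorderPairs(peaks, model)
    f <- tempfile(fileext = ".bed")
    writeBorderPairs(pairs, f)
    tab <- read.table(f, sep = "\t")
    expect_equal(tab$V2, 99)       # 0-based forward border
    expect_equal(tab$V3, 148)      # exclusive end = reverse border + 1
    expect_equal(tab$V6, ".")
    expect_equal(tab$V9, signif(fisherCombine(0.01, 0.02), 6))
})
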