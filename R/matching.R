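.restoreRNG <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        function() assign(".Random.seed", old, envir = globalenv())
    } else {
        function() suppressWarnings(
            rm(".Random.seed", envir = globalenv()))
    }
}

#' Fit a Gaussian mixture to high-confidence border-pair sizes
#'
#' Border-pair size distributions are often multimodal (e.g. outer and inner
#' exonuclease stops flanking the same factor), so the expected size
#' \eqn{\mu_T} is taken as the mean of the dominant component of a
#' C-component univariate Gaussian mixture fitted by expectation
#' maximization.  The EM log-likelihood is recorded every iteration and is
#' nondecreasing; the fit stops when the improvement drops below \code{tol}.
#'
#' @param sizes numeric vector of sizes (in bp) from unambiguous
#'   one-forward/one-reverse regions; at least 20 required.
#' @param C number of mixture components (default 2).
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param maxIter iteration cap (default 500).
#' @param seed integer seed for the initialization draw; the fit is
#'   deterministic given \code{seed}.
#' @param sdFloor lower bound on component standard deviations; a component
#'   collapsing below it is floored with a warning (degenerate fit guard).
#' @return a [PairSizeModel-class]; its kernel width is
#'   \code{K = max(2 * sigmaT, 1)}.
#' @seealso [pairSizeModel()] to set \eqn{\mu_T} manually,
#'   [highConfidenceSizes()]
#' @export
estimatePairSizeModel <- function(sizes, C = 2L, tol = 1e-8, maxIter = 500L,
                                  seed = 1L, sdFloor = 1e-2) {
    sizes <- as.numeric(sizes)
    if (length(sizes) < 20L)
        stop("need at least 20 high-confidence border-pair sizes to fit a ",
             "mixture; supply the expected size manually (pairSizeModel)")
    if (C < 1L)
        stop("C must be >= 1")
    n <- length(sizes)
    if (C == 1L) {
        mu <- mean(sizes)
        sg <- max(stats::sd(sizes), sdFloor)
        ll <- sum(stats::dnorm(sizes, mu, sg, log = TRUE))
        return(new("PairSizeModel", mean = mu, sd = sg, weight = 1,
                   muT = mu, sigmaT = sg, K = max(2 * sg, 1),
                   logLik = ll, converged = TRUE))
    }
    restore <- .restoreRNG()
    on.exit(restore())
    set.seed(as.integer(seed))
    mu <- sample(sizes, C)
    if (anyDuplicated(mu))
        mu <- mu + seq_len(C) * 1e-3
    sg <- rep(max(stats::sd(sizes), sdFloor), C)
    pi <- rep(1 / C, C)
    llTrace <- numeric(0L)
    converged <- FALSE
    floored <- FALSE
    for (iter in seq_len(maxIter)) {
        dens <- vapply(seq_len(C),
                       function(c) pi[c] * stats::dnorm(sizes, mu[c], sg[c]),
                       numeric(n))
        rowTot <- rowSums(dens)
        rowTot[rowTot == 0] <- .Machine$double.xmin
        ll <- sum(log(rowTot))
        llTrace <- c(llTrace, ll)
        if (iter > 1L && abs(ll - llTrace[iter - 1L]) < tol) {
            converged <- TRUE
            break
        }
        resp <- dens / rowTot
        nk <- colSums(resp)
        nk[nk == 0] <- .Machine$double.xmin
        pi <- nk / n
        mu <- colSums(resp * sizes) / nk
        sg <- sqrt(vapply(seq_len(C), function(c)
            sum(resp[, c] * (sizes - mu[c])^2) / nk[c], numeric(1L)))
        if (any(sg < sdFloor)) {
            sg <- pmax(sg, sdFloor)
            floored <- TRUE
        }
    }
    if (floored)
        warning("degenerate mixture component: sd floored at ", sdFloor)
    dom <- which.max(pi)
    new("PairSizeModel", mean = mu, sd = sg, weight = pi / sum(pi),
        muT = mu[dom], sigmaT = sg[dom], K = max(2 * sg[dom], 1),
        logLik = llTrace, converged = converged)
}

#' Construct a border-pair size model manually
#'
#' For runs without enough unambiguous regions to fit a mixture, the
#' expected pair size can be supplied directly (e.g. from the known motif
#' footprint of the factor).
#'
#' @param muT expected border-pair size in bp.
#' @param sigmaT its spread (default 2 bp).
#' @param K kernel width (default \code{max(2 * sigmaT, 1)}).
#' @return a single-component [PairSizeModel-class].
#' @export
pairSizeModel <- function(muT, sigmaT = 2, K = max(2 * sigmaT, 1)) {
    new("PairSizeModel", mean = muT, sd = sigmaT, weight = 1,
        muT = muT, sigmaT = sigmaT, K = K,
        logLik = numeric(0L), converged = TRUE)
}

#' Distance-weighted pair score
#'
#' \deqn{S_{weighted} = S_{obs} \times \exp(-(d_{obs} - \mu_T)^2 / K^2)}
#' Down-weights candidate border pairs whose size departs from the expected
#' size \eqn{\mu_T}; larger kernel widths K soften the penalty.
#'
#' @param sObs observed pair coverage score (sum of the two border signals).
#' @param dObs observed pair size in bp (inclusive of both border bases).
#' @param model a [PairSizeModel-class]; alternatively give \code{muT} and
#'   \code{K} directly.
#' @param muT,K explicit kernel parameters (override \code{model}).
#' @return the weighted score(s), vectorized.
#' @examples
#' weightPairScore(10, 49, muT = 49, K = 6)  # 10: at the expectation
#' weightPairScore(10, 55, muT = 49, K = 6)  # 10 * exp(-1) = 3.68
#' @export
weightPairScore <- function(sObs, dObs, model = NULL, muT = NULL, K = NULL) {
    if (is.null(muT) || is.null(K)) {
        stopifnot(is(model, "PairSizeModel"))
        if (is.null(muT)) muT <- model@muT
        if (is.null(K)) K <- model@K
    }
    stopifnot(all(sObs >= 0), K > 0)
    sObs * exp(-((dObs - muT)^2) / K^2)
}

#' Fisher-combined border-pair p-value
#'
#' The two exonuclease digestions demarcating a site are independent events,
#' so the two border pseudo p-values are combined with Fisher's method; for
#' two tests the chi-squared (4 df) tail has the closed form
#' \deqn{P_{pair} = q (1 - \ln q), \quad q = P_{fwd} P_{rev}.}
#'
#' @param pForward,pReverse border pseudo p-values in (0, 1], vectorized.
#' @return combined p-value(s) in (0, 1]; always at least
#'   \code{pForward * pReverse}.
#' @examples
#' fisherCombine(0.05, 0.05)  # 0.0175
#' fisherCombine(1, 1)        # 1
#' @export
fisherCombine <- function(pForward, pReverse) {
    if (any(pForward <= 0) || any(pReverse <= 0) ||
        any(pForward > 1) || any(pReverse > 1))
        stop("border p-values must lie in (0, 1]")
    q <- pForward * pReverse
    q * (1 - log(q))
}

# default admissibility cap on pair sizes: muT + 4 sd, with the sd floored
# at 2 bp so a near-degenerate fit (all high-confidence sizes identical)
# still admits slightly jittered pairs
.defaultMaxSpan <- function(model) {
    model@muT + 4 * max(model@sigmaT, 2)
}

# preference order of partners `js` for one proposer: descending weighted
# score, then size closest to muT, then smaller partner coordinate
.prefOrder <- function(js, sw, dev, coord) {
    js[order(-sw, dev, coord)]
}

#' Gale-Shapley stable matching of forward and reverse borders
#'
#' Within one candidate region, forward borders propose to downstream
#' reverse borders.  Both sides rank candidate partners by descending
#' distance-weighted pair score (ties: size closer to the expectation, then
#' smaller partner coordinate).  The returned matching is stable: no
#' forward/reverse pair prefer each other over their assigned partners.
#' Admissible pairs have the forward border at or upstream of the reverse
#' border and a size of at most \code{maxSpan}.
#'
#' @param fwd,rev \code{GRanges} of width-1 border peaks on the forward and
#'   reverse strand (metadata columns \code{signal}, \code{pseudoP}).
#' @param model a [PairSizeModel-class].
#' @param maxSpan maximum admissible pair size in bp (default
#'   \code{muT + 4 max(sigmaT, 2)}).
#' @return \code{data.frame} with one row per matched pair: indices
#'   \code{f}, \code{r} into the inputs, \code{dObs}, \code{sObs},
#'   \code{sWeighted}.
#' @export
stableMatch <- function(fwd, rev, model,
                        maxSpan = .defaultMaxSpan(model)) {
    stopifnot(is(model, "PairSizeModel"))
    nf <- length(fwd)
    nr <- length(rev)
    empty <- data.frame(f = integer(), r = integer(), dObs = numeric(),
                        sObs = numeric(), sWeighted = numeric())
    if (nf == 0L || nr == 0L)
        return(empty)
    fpos <- start(fwd)
    rpos <- start(rev)
    d <- outer(fpos, rpos, function(f, r) r - f + 1)   # inclusive span
    admissible <- d >= 1 & d <= maxSpan
    if (!any(admissible))
        return(empty)
    sObs <- outer(fwd$signal, rev$signal, "+")
    sw <- weightPairScore(sObs, d, model)
    dev <- abs(d - model@muT)

    prefF <- lapply(seq_len(nf), function(i) {
        js <- which(admissible[i, ])
        .prefOrder(js, sw[i, js], dev[i, js], rpos[js])
    })
    rankR <- lapply(seq_len(nr), function(j) {
        is <- which(admissible[, j])
        ord <- .prefOrder(is, sw[is, j], dev[is, j], fpos[is])
        rk <- rep(NA_integer_, nf)
        rk[ord] <- seq_along(ord)
        rk
    })

    nextProp <- rep(1L, nf)          # next partner index to propose to
    engagedTo <- rep(NA_integer_, nr)  # r -> f
    free <- which(lengths(prefF) > 0L)
    while (length(free) > 0L) {
        f <- free[[1L]]
        if (nextProp[f] > length(prefF[[f]])) {
            free <- free[-1L]        # exhausted all admissible partners
            next
        }
        r <- prefF[[f]][nextProp[f]]
        nextProp[f] <- nextProp[f] + 1L
        cur <- engagedTo[r]
        if (is.na(cur)) {
            engagedTo[r] <- f
            free <- free[-1L]
        } else if (rankR[[r]][f] < rankR[[r]][cur]) {
            engagedTo[r] <- f
            free <- c(free[-1L], cur)
        }
    }
    r <- which(!is.na(engagedTo))
    f <- engagedTo[r]
    data.frame(f = f, r = r,
               dObs = d[cbind(f, r)],
               sObs = sObs[cbind(f, r)],
               sWeighted = sw[cbind(f, r)])
}

#' Border-pair sizes from unambiguous regions
#'
#' The sizes of pairs from candidate regions containing exactly one
#' significant forward and one significant reverse border (the forward one
#' upstream), used as the high-confidence subset for fitting the pair-size
#' mixture.
#'
#' @param peaks \code{GRanges} from [callBorderPeaks()] (with \code{region}
#'   column).
#' @param maxSpan discard sizes beyond this pre-fit cap (default 500 bp).
#' @return numeric vector of sizes in bp.
#' @export
highConfidenceSizes <- function(peaks, maxSpan = 500) {
    sizes <- numeric(0L)
    for (reg in unique(peaks$region)) {
        p <- peaks[peaks$region == reg]
        f <- p[strand(p) == "+"]
        r <- p[strand(p) == "-"]
        if (length(f) == 1L && length(r) == 1L &&
            start(f) <= start(r)) {
            d <- start(r) - start(f) + 1
            if (d <= maxSpan)
                sizes <- c(sizes, d)
        }
    }
    sizes
}

#' Match border peaks into scored border pairs
#'
#' Runs [stableMatch()] within each candidate region, scores each matched
#' pair (\code{sObs} = sum of the two border signals, distance-weighted via
#' the size model) and combines the two border pseudo p-values with
#' [fisherCombine()].  Pairs with combined p-value above \code{alphaPair}
#' are dropped.
#'
#' @param peaks \code{GRanges} from [callBorderPeaks()].
#' @param model a [PairSizeModel-class].
#' @param alphaPair combined p-value cutoff (default 0.05).
#' @param maxSpan maximum pair size (default
#'   \code{muT + 4 max(sigmaT, 2)}).
#' @return \code{GRanges} of border pairs (start = forward border, end =
#'   reverse border, strand \code{*}), sorted, with metadata columns
#'   \code{dObs}, \code{sObs}, \code{sWeighted}, \code{pForward},
#'   \code{pReverse}, \code{pPair}, \code{region}.
#' @export
callBorderPairs <- function(peaks, model, alphaPair = 0.05,
                            maxSpan = expectedPairSize(model) +
                                4 * model@sigmaT) {
    res <- list()
    for (reg in unique(peaks$region)) {
        p <- peaks[peaks$region == reg]
        f <- p[strand(p) == "+"]
        r <- p[strand(p) == "-"]
        m <- stableMatch(f, r, model, maxSpan = maxSpan)
        if (nrow(m) == 0L)
            next
        pPair <- fisherCombine(f$pseudoP[m$f], r$pseudoP[m$r])
        keep <- pPair <= alphaPair
        if (!any(keep))
            next
        m <- m[keep, , drop = FALSE]
        res[[length(res) + 1L]] <- GRanges(
            seqnames(f)[m$f],
            IRanges(start(f)[m$f], start(r)[m$r]),
            strand = "*",
            dObs = m$dObs, sObs = m$sObs, sWeighted = m$sWeighted,
            pForward = f$pseudoP[m$f], pReverse = r$pseudoP[m$r],
            pPair = pPair[keep], region = reg,
            seqinfo = seqinfo(peaks))
    }
    if (length(res) == 0L) {
        gr <- GRanges(seqinfo = seqinfo(peaks))
        mcols(gr) <- DataFrame(dObs = numeric(), sObs = numeric(),
                               sWeighted = numeric(), pForward = numeric(),
                               pReverse = numeric(), pPair = numeric(),
                               region = integer())
        return(gr)
    }
    sort(do.call(c, res), ignore.strand = TRUE)
}

#' Write border pairs as BED6+4
#'
#' Columns: chrom, start (forward border, 0-based), end (reverse border,
#' exclusive), name, score = round(-10 log10 pPair), strand \code{.}, then
#' pForward, pReverse, pPair, sWeighted.
#'
#' @param pairs \code{GRanges} from [callBorderPairs()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBorderPairs <- function(pairs, path) {
    df <- data.frame(
        chrom = as.character(seqnames(pairs)),
        start = start(pairs) - 1L,
        end = end(pairs),
        name = sprintf("borderpair_%d", seq_along(pairs)),
        score = round(-10 * log10(pmax(pairs$pPair, 1e-30))),
        strand = ".",
        pForward = signif(pairs$pForward, 6L),
        pReverse = signif(pairs$pReverse, 6L),
        pPair = signif(pairs$pPair, 6L),
        sWeighted = signif(pairs$sWeighted, 6L))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write the fitted pair-size model as a text sidecar
#'
#' @param model a [PairSizeModel-class].
#' @param path output file.
#' @param sizes optional vector of the high-confidence sizes the model was
#'   fitted on, appended for audit.
#' @return \code{path}, invisibly.
#' @export
writePairSizeModel <- function(model, path, sizes = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("muT\t%.6g", model@muT), con)
    writeLines(sprintf("sigmaT\t%.6g", model@sigmaT), con)
    writeLines(sprintf("K\t%.6g", model@K), con)
    for (c in seq_along(model@mean))
        writeLines(sprintf("component_%d\tmean=%.6g\tsd=%.6g\tweight=%.6g",
                           c, model@mean[c], model@sd[c], model@weight[c]), con)
    writeLines(sprintf("converged\t%s", model@converged), con)
    writeLines(sprintf("iterations\t%d", length(model@logLik)), con)
    if (!is.null(sizes))
        writeLines(paste0("sizes\t", paste(sizes, collapse = ",")), con)
    invisible(path)
}
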