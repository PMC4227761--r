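#' Shannon entropy of a proportion vector
#'
#' \eqn{H(p) = -\sum_j p_j \ln p_j} in nats, with the convention
#' \eqn{0 \ln 0 = 0}.  For n replicates contributing equally,
#' \eqn{H = \ln n}: 1.386 for four equal replicates, dropping to 1.099 when
#' one of the four contributes nothing -- the drop is what penalizes
#' irreproducible positions during consolidation.
#'
#' @param p nonnegative proportions summing to 1 (tolerance 1e-9).
#' @return entropy in nats.
#' @examples
#' shannonEntropy(rep(0.25, 4))        # log(4) = 1.386
#' shannonEntropy(c(1/3, 1/3, 1/3, 0)) # log(3) = 1.099
#' @export
shannonEntropy <- function(p) {
    if (any(p < 0))
        stop("proportions must be nonnegative")
    if (abs(sum(p) - 1) > 1e-9)
        stop("proportions must sum to 1 (got ", format(sum(p)), ")")
    nz <- p > 0
    -sum(p[nz] * log(p[nz]))
}

# elementwise x*log(x) on an Rle with 0*log(0) := 0
.xlogxRle <- function(x) {
    v <- runValue(x)
    out <- ifelse(v > 0, v * log(pmax(v, .Machine$double.xmin)), 0)
    runValue(x) <- out
    x
}

# 0/0 := 0 division for proportion Rles
.safeDivRle <- function(num, den) {
    q <- num / den
    rv <- runValue(q)
    rv[!is.finite(rv)] <- 0
    runValue(q) <- rv
    q
}

.consolidateRleSet <- function(vlist, method, pool = c("position", "track"),
                               poolMass = NULL, snrCap = 1e3) {
    pool <- match.arg(pool)
    n <- length(vlist)
    tot <- Reduce(`+`, vlist)
    am <- tot / n
    if (method == "am")
        return(am)
    if (method == "gm") {
        prod <- Reduce(`*`, vlist)
        return(prod^(1 / n))
    }
    if (method == "snr") {
        if (n < 2L)
            stop("SNR consolidation needs at least 2 replicates")
        ssq <- Reduce(`+`, lapply(vlist, function(v) v * v))
        varr <- (ssq - n * am * am) / (n - 1)
        rv <- runValue(varr)
        rv[rv < 0] <- 0  # numerical negatives
        runValue(varr) <- rv
        sdr <- sqrt(varr)
        snr <- .safeDivRle(am, sdr)
        # sd = 0 with mean > 0: formula diverges; cap at mean * snrCap
        capped <- (sdr == 0) & (am > 0)
        return(snr * (!capped) + (am * snrCap) * capped)
    }
    # entropy
    if (n == 1L)
        return(am)
    if (pool == "position") {
        H <- 0
        for (v in vlist)
            H <- H - .xlogxRle(.safeDivRle(v, tot))
    } else {
        # pooled reading: p_j from each replicate's total mass over the locus
        if (is.null(poolMass))
            poolMass <- vapply(vlist, sum, numeric(1L))
        if (sum(poolMass) == 0)
            return(am * 0)
        pj <- poolMass / sum(poolMass)
        H <- shannonEntropy(pj)
    }
    am * (H / log(n))
}

#' Consolidate replicate signal tracks
#'
#' Combines n normalized replicate tracks position by position.  The default
#' entropy method computes, at each position, the proportions
#' \eqn{p_j = v_{ij} / \sum_j v_{ij}} of the normalized signal contributed by
#' each replicate and weights the across-replicate average by the relative
#' entropy \eqn{H(p)/\ln n \in [0,1]}:
#' \deqn{S_i = \frac{1}{n}\sum_j v_{ij} \times \frac{H(p)}{\ln n}.}
#' Perfectly reproducible positions keep their full average; positions where
#' one replicate carries all the signal are zeroed.  Arithmetic mean
#' (\code{"am"}), geometric mean (\code{"gm"}) and signal-to-noise ratio
#' (\code{"snr"}, mean/sd) are provided as benchmarking comparators.
#'
#' @param tracks list of normalized [StrandedCoverage-class] objects sharing
#'   one assembly (replicate values \eqn{v_{ij} = C_{ij} F_j W_i}).
#' @param method \code{"entropy"} (default), \code{"am"}, \code{"gm"} or
#'   \code{"snr"}.
#' @param pool how the entropy proportions are formed: \code{"position"}
#'   (default; per genomic position) or \code{"track"} (a single proportion
#'   vector from each replicate's total strand mass, applied to every
#'   position).
#' @param snrCap for \code{method = "snr"}: positions with zero
#'   across-replicate sd but positive mean report \code{mean * snrCap}
#'   instead of the divergent ratio.
#' @return a [StrandedCoverage-class] with \code{replicate = "consolidated"}
#'   and \code{method} set to the tag used.
#' @examples
#' asm <- Seqinfo("chr1", 300)
#' r1 <- fivePrimeCoverage(GRanges("chr1", IRanges(101, 136), "+"), asm)
#' r2 <- fivePrimeCoverage(GRanges("chr1", IRanges(101, 136), "+"), asm)
#' cons <- consolidate(list(r1, r2))
#' forwardTrack(cons)$chr1[101]  # 1: perfectly reproducible
#' @export
consolidate <- function(tracks, method = c("entropy", "am", "gm", "snr"),
                        pool = c("position", "track"), snrCap = 1e3) {
    method <- match.arg(method)
    pool <- match.arg(pool)
    stopifnot(length(tracks) >= 1L,
              all(vapply(tracks, is, logical(1L), "StrandedCoverage")))
    if (method == "entropy" && length(tracks) == 1L)
        warning("single replicate: entropy weight fixed at 1 (pass-through)")
    si <- seqinfo(tracks[[1L]])
    for (t in tracks[-1L])
        if (!identical(seqlengths(seqinfo(t)), seqlengths(si)))
            stop("replicate tracks disagree on the assembly")
    combineStrand <- function(getter) {
        vlists <- lapply(tracks, getter)
        out <- lapply(names(seqlengths(si)), function(chr) {
            vlist <- lapply(vlists, `[[`, chr)
            mass <- if (pool == "track")
                vapply(vlists, function(v) sum(sum(v)), numeric(1L))
            else NULL
            .consolidateRleSet(vlist, method, pool, poolMass = mass,
                               snrCap = snrCap)
        })
        names(out) <- names(seqlengths(si))
        as(out, "RleList")
    }
    new("StrandedCoverage",
        forward = combineStrand(forwardTrack),
        reverse = combineStrand(reverseTrack),
        seqinfo = si,
        replicate = "consolidated",
        method = method)
}
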