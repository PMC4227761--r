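#' Chebyshev pseudo p-value for an outlier signal
#'
#' For a signal X against a local background with mean m and standard
#' deviation s, the Chebyshev inequality bounds the probability of seeing a
#' value at least \eqn{k = (X - m)/s} standard deviations above the mean by
#' \eqn{1/k^2}, with no distributional assumption.  The bound is vacuous for
#' \eqn{k \le 1} (returns 1); a signal 4.5 SDs up gets
#' \eqn{1/4.5^2 \approx 0.05}.  Because it is an upper bound, not a
#' calibrated tail probability, it is reported as a pseudo p-value.
#'
#' @param signal observed signal value(s) X.
#' @param m local background mean.
#' @param s local background standard deviation (\code{s = 0} yields 1: no
#'   dispersion, no outlier call).
#' @return pseudo p-value(s) in (0, 1], vectorized over \code{signal}.
#' @examples
#' chebyshevPValue(19, m = 10, s = 2)  # 4.5 SDs: 1/4.5^2 ~ 0.049
#' chebyshevPValue(12, m = 10, s = 2)  # k = 1: vacuous, 1
#' @export
chebyshevPValue <- function(signal, m, s) {
    stopifnot(length(m) == 1L, length(s) == 1L, s >= 0)
    if (s == 0)
        return(rep(1, length(signal)))
    k <- (signal - m) / s
    ifelse(k > 1, pmin(1, 1 / k^2), 1)
}

.viewStats <- function(values, sq, chr, start, end) {
    # population mean/sd of one strand's signal over [start, end], zeros
    # included
    v <- Views(values[[chr]], start = start, end = end)
    n <- end - start + 1
    m <- viewSums(v)[1L] / n
    ex2 <- viewSums(Views(sq[[chr]], start = start, end = end))[1L] / n
    s <- sqrt(max(ex2 - m^2, 0))
    c(m = m, s = s)
}

#' Segment consolidated signal into candidate regions
#'
#' Candidate regions are maximal runs of positions whose combined
#' forward+reverse consolidated signal reaches \code{minSignal}; runs
#' separated by fewer than \code{mergeGap} bases are merged.  For each region
#' a per-strand local background mean m and (population) standard deviation s
#' are computed over the region extended by \code{bgFlank} bases on each side
#' (clamped to the chromosome), zeros included -- the local-background
#' analogue of a peak caller's local lambda.
#'
#' @param track consolidated [StrandedCoverage-class].
#' @param minSignal minimum combined signal to seed a region (default 5
#'   normalized units).
#' @param mergeGap merge runs closer than this many bases (default 100).
#' @param bgFlank background flank in bases (default 500).
#' @return \code{GRanges} of regions with metadata columns \code{mFwd},
#'   \code{sFwd}, \code{mRev}, \code{sRev}.
#' @seealso [callBorderPeaks()]
#' @export
segmentCandidateRegions <- function(track, minSignal = 5, mergeGap = 100L,
                                    bgFlank = 500L) {
    stopifnot(is(track, "StrandedCoverage"))
    comb <- track@forward + track@reverse
    ir <- slice(comb, lower = minSignal, rangesOnly = TRUE)
    ir <- reduce(ir, min.gapwidth = mergeGap)
    gr <- GRanges(ir, seqinfo = track@seqinfo)
    if (length(gr) == 0L) {
        mcols(gr) <- DataFrame(mFwd = numeric(), sFwd = numeric(),
                               mRev = numeric(), sRev = numeric())
        return(gr)
    }
    sl <- seqlengths(track@seqinfo)
    bgStart <- pmax(1L, start(gr) - bgFlank)
    bgEnd <- pmin(unname(sl[as.character(seqnames(gr))]), end(gr) + bgFlank)
    sqF <- track@forward * track@forward
    sqR <- track@reverse * track@reverse
    statF <- t(vapply(seq_along(gr), function(i)
        .viewStats(track@forward, sqF, as.character(seqnames(gr))[i],
                   bgStart[i], bgEnd[i]), c(m = 0, s = 0)))
    statR <- t(vapply(seq_along(gr), function(i)
        .viewStats(track@reverse, sqR, as.character(seqnames(gr))[i],
                   bgStart[i], bgEnd[i]), c(m = 0, s = 0)))
    mcols(gr) <- DataFrame(mFwd = unname(statF[, "m"]),
                           sFwd = unname(statF[, "s"]),
                           mRev = unname(statR[, "m"]),
                           sRev = unname(statR[, "s"]))
    gr
}

# collapse significant positions within `dist` nt to the local maximum
# (leftmost on ties); pos must be sorted ascending
.collapseAdjacent <- function(pos, sig, dist = 2L) {
    if (length(pos) == 0L)
        return(integer(0L))
    grp <- cumsum(c(1L, as.integer(diff(pos) > dist)))
    vapply(split(seq_along(pos), grp), function(ii) {
        ii[which.max(sig[ii])]  # which.max is leftmost on ties
    }, integer(1L), USE.NAMES = FALSE)
}

#' Call single-nucleotide border peaks
#'
#' Within each candidate region, every position whose Chebyshev pseudo
#' p-value against the region's local background is at most \code{alpha} is
#' a candidate border; forward and reverse strands are processed
#' independently.  Significant positions within \code{collapseDist} nt on
#' the same strand are collapsed to the single strongest position (leftmost
#' on ties), yielding one border per exonuclease stop.
#'
#' @param track consolidated [StrandedCoverage-class].
#' @param regions \code{GRanges} from [segmentCandidateRegions()].
#' @param alpha pseudo p-value cutoff (default 0.05, i.e. k > ~4.47 SDs).
#' @param collapseDist adjacency collapsing distance in nt (default 2).
#' @return \code{GRanges} of width-1 peaks with strand and metadata columns
#'   \code{signal}, \code{kValue}, \code{pseudoP}, \code{region} (index into
#'   \code{regions}).
#' @export
callBorderPeaks <- function(track, regions, alpha = 0.05, collapseDist = 2L) {
    stopifnot(is(track, "StrandedCoverage"))
    res <- list()
    for (i in seq_along(regions)) {
        chr <- as.character(seqnames(regions))[i]
        st <- start(regions)[i]
        en <- end(regions)[i]
        for (sd in c("+", "-")) {
            values <- if (sd == "+") track@forward else track@reverse
            m <- if (sd == "+") regions$mFwd[i] else regions$mRev[i]
            s <- if (sd == "+") regions$sFwd[i] else regions$sRev[i]
            x <- as.numeric(values[[chr]][st:en])
            p <- chebyshevPValue(x, m, s)
            hit <- which(p <= alpha)
            if (length(hit) == 0L)
                next
            keep <- .collapseAdjacent(hit, x[hit], collapseDist)
            hit <- hit[keep]
            res[[length(res) + 1L]] <- GRanges(
                chr, IRanges(st + hit - 1L, width = 1L), strand = sd,
                signal = x[hit], kValue = (x[hit] - m) / s,
                pseudoP = p[hit], region = i,
                seqinfo = track@seqinfo)
        }
    }
    if (length(res) == 0L) {
        gr <- GRanges(seqinfo = track@seqinfo)
        mcols(gr) <- DataFrame(signal = numeric(), kValue = numeric(),
                               pseudoP = numeric(), region = integer())
        return(gr)
    }
    sort(do.call(c, res), ignore.strand = TRUE)
}

#' Write border peaks as BED6+2
#'
#' Columns: chrom, start, end (the single border base, 0-based half-open),
#' name, score = round(-10 log10 pseudoP), strand, then kValue and pseudoP.
#'
#' @param peaks \code{GRanges} from [callBorderPeaks()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBorderPeaks <- function(peaks, path) {
    df <- data.frame(
        chrom = as.character(seqnames(peaks)),
        start = start(peaks) - 1L,
        end = end(peaks),
        name = sprintf("border_%d", seq_along(peaks)),
        score = round(-10 * log10(pmax(peaks$pseudoP, 1e-30))),
        strand = as.character(strand(peaks)),
        kValue = signif(peaks$kValue, 6L),
        pseudoP = signif(peaks$pseudoP, 6L))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
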