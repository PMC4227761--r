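#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<- Rle
#'   runValue runValue<- isSorted queryHits subjectHits
#' @importFrom IRanges IRanges IRangesList RleList Views viewSums viewMeans
#'   slice reduce
#' @importFrom GenomicRanges GRanges GRangesList coverage resize strand
#'   strand<- seqnames start end width findOverlaps countOverlaps
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqinfo<- seqlengths seqnames
#'   seqlevels seqlevels<- keepSeqlevels
#' @importFrom BiocGenerics sort unlist
NULL

#' Strand-separated 5'-end signal tracks
#'
#' Holds one per-base signal value per genomic position, kept separately for
#' the forward and reverse strand, across the chromosomes of an assembly.
#' Values are run-length encoded (\code{RleList}, one \code{Rle} per
#' chromosome) so memory scales with the number of distinct runs, not genome
#' length.  A track may contain raw 5'-end read counts, depth-normalized
#' signal, or a consolidated multi-replicate signal; \code{replicate} and
#' \code{method} record which.
#'
#' @slot forward \code{RleList} of per-base signal on the forward strand.
#' @slot reverse \code{RleList} of per-base signal on the reverse strand.
#' @slot seqinfo \code{Seqinfo} describing the assembly.
#' @slot replicate single string: replicate identifier, or
#'   \code{"consolidated"}.
#' @slot method single string: \code{"raw"} for per-replicate tracks,
#'   otherwise the consolidation method tag (\code{"entropy"}, \code{"am"},
#'   \code{"gm"}, \code{"snr"}).
#'
#' @seealso [fivePrimeCoverage()], [consolidate()], [writeSignalTrack()]
#' @export
setClass("StrandedCoverage",
    slots = c(
        forward   = "RleList",
        reverse   = "RleList",
        seqinfo   = "Seqinfo",
        replicate = "character",
        method    = "character"
    ),
    prototype = prototype(replicate = NA_character_, method = "raw")
)

setValidity("StrandedCoverage", function(object) {
    msg <- character()
    sl <- seqlengths(object@seqinfo)
    for (slot in c("forward", "reverse")) {
        v <- slot(object, slot)
        if (!identical(names(v), names(sl)))
            msg <- c(msg, sprintf("%s track chromosomes must match seqinfo",
                                  slot))
        else if (!all(lengths(v) == unname(sl)))
            msg <- c(msg, sprintf("%s track lengths must match seqlengths",
                                  slot))
        if (any(vapply(v, function(x) any(runValue(x) < 0), logical(1L))))
            msg <- c(msg, sprintf("%s track has negative values", slot))
    }
    if (length(object@replicate) != 1L)
        msg <- c(msg, "replicate must be a single string")
    if (length(object@method) != 1L)
        msg <- c(msg, "method must be a single string")
    if (length(msg)) msg else TRUE
})

#' Positional k-mer composition bias model
#'
#' Frequencies of each k-mer at the first position of sequenced reads
#' (\code{p0}) versus the average over interior read offsets (\code{pnMean}),
#' estimated from singleton reads, together with the derived per-k-mer
#' correction weights \eqn{W(h) = \bar{P}_n(h) / \hat{P}_0(h)} used to
#' reweight each read by its starting k-mer.
#'
#' @slot k k-mer length (default 6).
#' @slot readLength read length L used for the interior offsets 1..L-k.
#' @slot nReads number of singleton reads the model was fitted on.
#' @slot table \code{DataFrame} with columns \code{kmer}, \code{p0},
#'   \code{pnMean}, \code{weight}, one row per k-mer observed anywhere.
#'
#' @seealso [estimateKmerBias()], [applyReadWeights()]
#' @export
setClass("KmerBiasModel",
    slots = c(
        k          = "integer",
        readLength = "integer",
        nReads     = "integer",
        table      = "DataFrame"
    )
)

setValidity("KmerBiasModel", function(object) {
    msg <- character()
    need <- c("kmer", "p0", "pnMean", "weight")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, paste("table must have columns",
                            paste(need, collapse = ", ")))
    if (length(object@k) != 1L || object@k < 1L)
        msg <- c(msg, "k must be a single positive integer")
    if (length(object@readLength) != 1L || object@readLength <= object@k)
        msg <- c(msg, "readLength must exceed k")
    if (length(msg)) msg else TRUE
})

#' Gaussian-mixture model of border-pair sizes
#'
#' Parameters of a C-component univariate Gaussian mixture fitted by EM to
#' high-confidence border-pair sizes.  The expected pair size \code{muT} is
#' the mean of the dominant (highest mixing weight) component; \code{K} is
#' the width of the Gaussian kernel used to down-weight candidate pairs whose
#' size departs from \code{muT}.
#'
#' @slot mean component means.
#' @slot sd component standard deviations.
#' @slot weight mixing proportions (sum to 1).
#' @slot muT expected border-pair size (mean of the dominant component).
#' @slot sigmaT standard deviation of the dominant component.
#' @slot K kernel width for pair-score weighting.
#' @slot logLik per-iteration log-likelihood trace of the EM fit (empty for
#'   manually constructed models).
#' @slot converged whether EM converged within the iteration budget.
#'
#' @seealso [estimatePairSizeModel()], [weightPairScore()], [stableMatch()]
#' @export
setClass("PairSizeModel",
    slots = c(
        mean      = "numeric",
        sd        = "numeric",
        weight    = "numeric",
        muT       = "numeric",
        sigmaT    = "numeric",
        K         = "numeric",
        logLik    = "numeric",
        converged = "logical"
    )
)

setValidity("PairSizeModel", function(object) {
    msg <- character()
    C <- length(object@mean)
    if (length(object@sd) != C || length(object@weight) != C)
        msg <- c(msg, "mean, sd and weight must have equal length")
    if (any(object@sd <= 0))
        msg <- c(msg, "component sds must be positive")
    if (any(object@weight <= 0) || abs(sum(object@weight) - 1) > 1e-6)
        msg <- c(msg, "mixing weights must be positive and sum to 1")
    if (length(object@muT) != 1L || object@muT <= 0)
        msg <- c(msg, "muT must be a single positive number")
    if (length(object@K) != 1L || object@K <= 0)
        msg <- c(msg, "K must be a single positive number")
    if (length(msg)) msg else TRUE
})

setMethod("show", "StrandedCoverage", function(object) {
    m <- trackMass(object)
    cat(sprintf(
        "StrandedCoverage [%s, %s] on %d chromosome(s)\n",
        object@replicate, object@method, length(seqlengths(object@seqinfo))))
    cat(sprintf("  mass: forward %.4g, reverse %.4g\n", m[["forward"]],
                m[["reverse"]]))
})

setMethod("show", "KmerBiasModel", function(object) {
    w <- object@table$weight
    cat(sprintf("KmerBiasModel: k=%d, readLength=%d, %d singleton reads\n",
                object@k, object@readLength, object@nReads))
    cat(sprintf("  %d k-mers; weight range [%.3g, %.3g]\n",
                nrow(object@table), min(w), max(w)))
})

setMethod("show", "PairSizeModel", function(object) {
    cat(sprintf("PairSizeModel with %d component(s)\n", length(object@mean)))
    for (c in seq_along(object@mean))
        cat(sprintf("  comp %d: mean=%.2f sd=%.2f weight=%.3f\n",
                    c, object@mean[c], object@sd[c], object@weight[c]))
    cat(sprintf("  muT=%.2f sigmaT=%.2f K=%.2f (EM %s, %d iterations)\n",
                object@muT, object@sigmaT, object@K,
                if (isTRUE(object@converged)) "converged" else "not converged",
                length(object@logLik)))
})
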