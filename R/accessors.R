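#' Accessors for StrandedCoverage objects
#'
#' @param x,object a [StrandedCoverage-class] object.
#' @return \code{forwardTrack} and \code{reverseTrack} return the per-base
#'   signal as an \code{RleList}; \code{trackMass} returns a named numeric
#'   vector with the total signal on each strand; \code{consolidationMethod}
#'   and \code{replicateId} return single strings.
#' @examples
#' asm <- Seqinfo("chr1", 200)
#' reads <- GRanges("chr1", IRanges(101, 136), strand = "+")
#' cov <- fivePrimeCoverage(reads, asm)
#' trackMass(cov)
#' @name StrandedCoverage-accessors
NULL

#' @rdname StrandedCoverage-accessors
#' @export
forwardTrack <- function(x) {
    stopifnot(is(x, "StrandedCoverage"))
    x@forward
}

#' @rdname StrandedCoverage-accessors
#' @export
reverseTrack <- function(x) {
    stopifnot(is(x, "StrandedCoverage"))
    x@reverse
}

#' @rdname StrandedCoverage-accessors
#' @export
trackMass <- function(x) {
    stopifnot(is(x, "StrandedCoverage"))
    c(forward = sum(vapply(x@forward, sum, numeric(1L))),
      reverse = sum(vapply(x@reverse, sum, numeric(1L))))
}

#' @rdname StrandedCoverage-accessors
#' @export
consolidationMethod <- function(x) {
    stopifnot(is(x, "StrandedCoverage"))
    x@method
}

#' @rdname StrandedCoverage-accessors
#' @export
replicateId <- function(x) {
    stopifnot(is(x, "StrandedCoverage"))
    x@replicate
}

#' @rdname StrandedCoverage-accessors
#' @export
setMethod("seqinfo", "StrandedCoverage", function(x) x@seqinfo)

#' Accessors for KmerBiasModel objects
#'
#' @param x a [KmerBiasModel-class] object.
#' @return \code{biasTable} returns the per-k-mer \code{DataFrame} (columns
#'   \code{kmer}, \code{p0}, \code{pnMean}, \code{weight}); \code{kmerSize}
#'   the k-mer length.
#' @name KmerBiasModel-accessors
NULL

#' @rdname KmerBiasModel-accessors
#' @export
biasTable <- function(x) {
    stopifnot(is(x, "KmerBiasModel"))
    x@table
}

#' @rdname KmerBiasModel-accessors
#' @export
kmerSize <- function(x) {
    stopifnot(is(x, "KmerBiasModel"))
    x@k
}

#' Accessors for PairSizeModel objects
#'
#' @param x a [PairSizeModel-class] object.
#' @return \code{expectedPairSize} returns \eqn{\mu_T}, the fitted expected
#'   border-pair size; \code{kernelWidth} the kernel width K;
#'   \code{mixtureLogLik} the per-iteration EM log-likelihood trace.
#' @name PairSizeModel-accessors
NULL

#' @rdname PairSizeModel-accessors
#' @export
expectedPairSize <- function(x) {
    stopifnot(is(x, "PairSizeModel"))
    x@muT
}

#' @rdname PairSizeModel-accessors
#' @export
kernelWidth <- function(x) {
    stopifnot(is(x, "PairSizeModel"))
    x@K
}

#' @rdname PairSizeModel-accessors
#' @export
mixtureLogLik <- function(x) {
    stopifnot(is(x, "PairSizeModel"))
    x@logLik
}
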