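#' Sequencing-depth size factor
#'
#' \eqn{F_j = \mathrm{commonScale} / T_j}, where \eqn{T_j} is the number of
#' uniquely mapped reads in replicate j.  Multiplying replicate j's raw 5'-end
#' coverage by \eqn{F_j} brings every replicate to the same total mass
#' (default 1e7, i.e. "per 10 million reads").
#'
#' @param totalReads unique-read count \eqn{T_j} (> 0).
#' @param commonScale the common scale (default \code{1e7}).
#' @return the size factor, a positive scalar.
#' @examples
#' computeSizeFactor(2e7)          # 0.5
#' computeSizeFactor(1e7)          # 1
#' @export
computeSizeFactor <- function(totalReads, commonScale = 1e7) {
    stopifnot(length(totalReads) == 1L, length(commonScale) == 1L,
              commonScale > 0)
    if (is.na(totalReads) || totalReads <= 0)
        stop("replicate has no mapped reads; cannot compute a size factor")
    commonScale / totalReads
}

#' Find singleton reads
#'
#' A singleton is a uniquely mapped read whose interval overlaps no other
#' read on either strand of the same chromosome.  Singletons sample the
#' genome free of immunoprecipitation, exonuclease and PCR selection, so
#' their starting k-mer composition estimates the background positional
#' sequence bias of the library.
#'
#' @param reads \code{GRanges} of one replicate's alignments.
#' @return the subset of \code{reads} that are singletons (original order).
#' @seealso [estimateKmerBias()]
#' @export
findSingletonReads <- function(reads) {
    if (length(reads) == 0L)
        return(reads)
    # strand-agnostic overlap; min.gapwidth = 0 so book-ended (touching but
    # non-overlapping) reads are not lumped together
    merged <- reduce(reads, ignore.strand = TRUE, min.gapwidth = 0L)
    nPerBlock <- countOverlaps(merged, reads, ignore.strand = TRUE)
    solo <- merged[nPerBlock == 1L]
    hits <- findOverlaps(reads, solo, ignore.strand = TRUE)
    reads[queryHits(hits)]
}

.allKmers <- function(k) {
    mkAllStrings <- Biostrings::mkAllStrings
    mkAllStrings(c("A", "C", "G", "T"), k)
}

.kmerProportions <- function(seqs, offset, k) {
    # counts of each ACGT k-mer starting at 1-based `offset`; k-mers with
    # ambiguous bases are not counted (oligonucleotideFrequency only tallies
    # unambiguous words)
    sub <- Biostrings::subseq(seqs, start = offset, width = k)
    counts <- Biostrings::oligonucleotideFrequency(sub, width = k,
                                                   simplify.as = "collapse")
    tot <- sum(counts)
    if (tot == 0) counts else counts / tot
}

#' Estimate positional k-mer composition bias from singleton reads
#'
#' Compares the frequency of each k-mer at the first read position
#' (\eqn{\hat{P}_0(h)}) with its average frequency over the interior offsets
#' \eqn{n = 1, \ldots, L-k} (\eqn{\bar{P}_n(h)}).  Without positional bias
#' the two agree and the weight \eqn{W(h) = \bar{P}_n(h)/\hat{P}_0(h)} is
#' close to 1; k-mers over-represented at read starts get \eqn{W(h) < 1} and
#' depleted ones \eqn{W(h) > 1}.  Weights are clamped to
#' \code{weightRange} so rare k-mers cannot explode the signal; a k-mer never
#' seen at offset 0 but seen internally takes the upper clamp.
#'
#' @param singletons \code{GRanges} from [findSingletonReads()] with a
#'   \code{readPrefix} metadata column holding the as-sequenced read
#'   (5' to 3', i.e. as in the FASTQ, not reverse-complemented).
#' @param k k-mer length, 4--8 (default 6, hexamer).
#' @param readLength read length L; default the shortest available prefix.
#' @param weightRange clamp interval for W(h) (default \code{c(0.1, 10)}).
#' @return a [KmerBiasModel-class].
#' @seealso [applyReadWeights()], [writeKmerBiasModel()]
#' @export
estimateKmerBias <- function(singletons, k = 6L, readLength = NULL,
                             weightRange = c(0.1, 10)) {
    k <- as.integer(k)
    stopifnot(k >= 4L, k <= 8L)
    prefix <- mcols(singletons)$readPrefix
    prefix <- prefix[.isDnaPrefix(prefix)]
    if (length(prefix) == 0L)
        stop("no singleton reads with sequence available; ",
             "disable bias correction (biasCorrection = FALSE)")
    if (is.null(readLength))
        readLength <- min(nchar(prefix))
    readLength <- as.integer(readLength)
    if (readLength <= k)
        stop("readLength (", readLength, ") must exceed k (", k, ")")
    prefix <- prefix[nchar(prefix) >= readLength]
    if (length(prefix) == 0L)
        stop("no singleton read prefixes of length >= ", readLength)
    seqs <- Biostrings::DNAStringSet(prefix)

    p0 <- .kmerProportions(seqs, 1L, k)
    inner <- lapply(seq_len(readLength - k),
                    function(n) .kmerProportions(seqs, n + 1L, k))
    pnMean <- Reduce(`+`, inner) / length(inner)

    keep <- p0 > 0 | pnMean > 0
    w <- ifelse(p0[keep] > 0, pnMean[keep] / p0[keep], weightRange[2L])
    w <- pmin(pmax(w, weightRange[1L]), weightRange[2L])
    tab <- DataFrame(kmer = names(p0)[keep],
                     p0 = unname(p0[keep]),
                     pnMean = unname(pnMean[keep]),
                     weight = unname(w))
    new("KmerBiasModel", k = k, readLength = readLength,
        nReads = length(seqs), table = tab)
}

#' Per-read weights from a fitted bias model
#'
#' Looks up \eqn{W(h)} for each read's first k-mer.  Reads without sequence,
#' with ambiguous bases in the first k-mer, or with a k-mer absent from the
#' model fall back to weight 1.  Passing \code{model = NULL} (bias correction
#' off, the default pipeline setting) returns all-1 weights.
#'
#' @param reads \code{GRanges} with a \code{readPrefix} metadata column.
#' @param model a [KmerBiasModel-class], or \code{NULL}.
#' @return numeric vector of weights, one per read.
#' @export
applyReadWeights <- function(reads, model = NULL) {
    if (is.null(model))
        return(rep(1, length(reads)))
    stopifnot(is(model, "KmerBiasModel"))
    prefix <- mcols(reads)$readPrefix
    w <- rep(1, length(reads))
    ok <- .isDnaPrefix(prefix) & nchar(prefix) >= model@k
    first <- substr(prefix[ok], 1L, model@k)
    idx <- match(first, model@table$kmer)
    wk <- model@table$weight[idx]
    wk[is.na(wk)] <- 1
    w[ok] <- wk
    w
}

#' Serialize / deserialize a k-mer bias model
#'
#' The model is stored as a tab-separated table (kmer, p0, pnMean, weight)
#' with a \code{#}-comment header carrying k, readLength and nReads, so it
#' can be inspected with any text tool.
#'
#' @param model a [KmerBiasModel-class].
#' @param path output (input) file.
#' @return \code{writeKmerBiasModel}: \code{path}, invisibly;
#'   \code{readKmerBiasModel}: the model.
#' @export
writeKmerBiasModel <- function(model, path) {
    stopifnot(is(model, "KmerBiasModel"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# k=%d readLength=%d nReads=%d",
                       model@k, model@readLength, model@nReads), con)
    utils::write.table(as.data.frame(model@table), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeKmerBiasModel
#' @export
readKmerBiasModel <- function(path) {
    hdr <- readLines(path, n = 1L)
    m <- regmatches(hdr, regexec(
        "k=([0-9]+) readLength=([0-9]+) nReads=([0-9]+)", hdr))[[1L]]
    if (length(m) != 4L)
        stop("not a k-mer bias model file: ", path)
    tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                             colClasses = c("character", rep("numeric", 3L)))
    new("KmerBiasModel", k = as.integer(m[2L]), readLength = as.integer(m[3L]),
        nReads = as.integer(m[4L]), table = as(tab, "DataFrame"))
}
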