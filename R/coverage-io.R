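#' Read a chromosome-sizes table
#'
#' Parses the standard two-column (name, length) chrom.sizes text format into
#' a \code{Seqinfo} describing the assembly.
#'
#' @param path path to a tab- or space-separated two-column file.
#' @param genome optional genome build label stored in the result.
#' @return a \code{Seqinfo}.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t1000", "chr2\t500"), f)
#' readChromSizes(f)
#' @export
readChromSizes <- function(path, genome = NA_character_) {
    tab <- utils::read.table(path, header = FALSE, col.names = c("name", "len"),
                             colClasses = c("character", "integer"))
    if (anyDuplicated(tab$name))
        stop("duplicated chromosome name in ", path)
    if (any(tab$len <= 0L) || anyNA(tab$len))
        stop("chromosome lengths must be positive integers in ", path)
    Seqinfo(seqnames = tab$name, seqlengths = tab$len, genome = genome)
}

.isDnaPrefix <- function(x) {
    !is.na(x) & nchar(x) >= 1L & grepl("^[ACGTNacgtn]+$", x)
}

#' Load uniquely mapped alignments
#'
#' Reads ChIP-exo alignments from BED6, SAM or BAM into a \code{GRanges}.
#' Clonal reads (identical coordinates) are all retained: in ChIP-exo many
#' reads legitimately share one 5' coordinate because lambda exonuclease stops
#' at the protein-bound base, so deduplication would destroy the signal.
#'
#' For SAM/BAM the \code{minMapq} threshold acts as the uniqueness filter
#' (upstream aligners encode uniqueness in MAPQ differently; 20 is a common
#' proxy).  BED6 carries no mapping quality and is assumed to contain unique
#' alignments already.  SAM text is converted to BAM on the fly.
#'
#' If read sequences are available (SAM/BAM \code{SEQ}, or a BED name column
#' that is a plain A/C/G/T/N string, the convention used by
#' [writeSimulation()]), the as-sequenced prefix is attached as
#' \code{mcols(reads)$readPrefix} for k-mer bias estimation.
#'
#' @param path alignment file (\code{.bed}, \code{.sam}, \code{.bam}).
#' @param assembly \code{Seqinfo} to validate records against.
#' @param minMapq minimum mapping quality for SAM/BAM records (default 20);
#'   records with missing MAPQ are kept.
#' @param replicate optional replicate identifier stored in
#'   \code{mcols(reads)$replicate}.
#' @return \code{GRanges} with strand, and metadata columns
#'   \code{readPrefix} (character or \code{NA}) and \code{replicate}.
#' @seealso [fivePrimeCoverage()], [findSingletonReads()]
#' @export
loadAlignments <- function(path, assembly, minMapq = 20L,
                           replicate = NA_character_) {
    if (!file.exists(path))
        stop("alignment file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    gr <- switch(ext,
        bed = .loadBed(path),
        sam = .loadBam(Rsamtools::asBam(path,
                  destination = tempfile(), overwrite = TRUE,
                  indexDestination = FALSE), minMapq),
        bam = .loadBam(path, minMapq),
        stop("unsupported alignment format '.", ext,
             "' (expected .bed, .sam or .bam): ", path)
    )
    .checkAgainstAssembly(gr, assembly, path)
    gr <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                  strand = strand(gr),
                  readPrefix = mcols(gr)$readPrefix,
                  replicate = rep(as.character(replicate), length(gr)),
                  seqinfo = assembly)
    gr
}

.loadBed <- function(path) {
    if (file.size(path) == 0L) {
        gr <- GRanges()
        mcols(gr)$readPrefix <- character(0L)
        return(gr)
    }
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e)
                       stop("malformed BED record in ", path, ": ",
                            conditionMessage(e), call. = FALSE))
    if (any(strand(gr) == "*"))
        stop("BED record without strand in ", path,
             " (record ", which(strand(gr) == "*")[1L], ")")
    nm <- mcols(gr)$name
    prefix <- rep(NA_character_, length(gr))
    if (!is.null(nm)) {
        ok <- .isDnaPrefix(nm)
        prefix[ok] <- toupper(nm[ok])
    }
    mcols(gr) <- DataFrame(readPrefix = prefix)
    gr
}

.loadBam <- function(path, minMapq) {
    param <- Rsamtools::ScanBamParam(
        what = c("mapq", "seq"),
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    aln <- GenomicAlignments::readGAlignments(path, param = param)
    mapq <- mcols(aln)$mapq
    keep <- is.na(mapq) | mapq >= minMapq
    aln <- aln[keep]
    gr <- GRanges(seqnames(aln),
                  IRanges(start(aln), end(aln)),
                  strand = strand(aln))
    seqs <- mcols(aln)$seq
    mcols(gr)$readPrefix <- if (length(seqs)) as.character(seqs)
                            else rep(NA_character_, length(gr))
    gr
}

.checkAgainstAssembly <- function(gr, assembly, path) {
    sl <- seqlengths(assembly)
    bad <- !(as.character(seqnames(gr)) %in% names(sl))
    if (any(bad)) {
        i <- which(bad)[1L]
        stop("record ", i, " in ", path, " maps to unknown chromosome '",
             as.character(seqnames(gr))[i], "'")
    }
    lens <- sl[as.character(seqnames(gr))]
    oob <- start(gr) < 1L | end(gr) > lens
    if (any(oob)) {
        i <- which(oob)[1L]
        stop("record ", i, " in ", path, " out of chromosome bounds: ",
             as.character(seqnames(gr))[i], ":", start(gr)[i], "-", end(gr)[i])
    }
    invisible(TRUE)
}

#' Build strand-separated 5'-end coverage
#'
#' Each forward-strand read contributes at its leftmost base, each
#' reverse-strand read at its rightmost base -- in both cases the 5' end of
#' the sequenced fragment, the position where lambda exonuclease digestion
#' stopped.  Contributions are +1 by default, or per-read weights when k-mer
#' bias correction is enabled.
#'
#' @param reads \code{GRanges} of alignments (strand \code{+} or \code{-}).
#' @param assembly \code{Seqinfo}.
#' @param weights optional numeric vector, one weight per read (from
#'   [applyReadWeights()]); default all 1.
#' @param replicate replicate identifier for the resulting track.
#' @return a [StrandedCoverage-class] with one \code{Rle} per chromosome and
#'   strand.  Total mass over both strands equals \code{sum(weights)}.
#' @examples
#' asm <- Seqinfo("chr1", 200)
#' reads <- GRanges("chr1", IRanges(c(101, 101, 51), c(136, 136, 86)),
#'                  strand = c("+", "+", "-"))
#' cov <- fivePrimeCoverage(reads, asm)
#' forwardTrack(cov)$chr1[101]  # 2 clonal 5' ends
#' reverseTrack(cov)$chr1[86]   # 5' end of the reverse read
#' @export
fivePrimeCoverage <- function(reads, assembly, weights = NULL,
                              replicate = NA_character_) {
    if (is.null(weights))
        weights <- rep(1, length(reads))
    if (length(weights) != length(reads))
        stop("need one weight per read")
    st <- as.character(strand(reads))
    if (any(st == "*"))
        stop("reads must be stranded (+/-) to locate their 5' ends")
    ends5 <- resize(reads, width = 1L, fix = "start")  # strand-aware 5' base
    covOne <- function(sel) {
        gr <- GRanges(seqnames(ends5)[sel],
                      IRanges(start(ends5)[sel], width = 1L),
                      seqinfo = assembly)
        .weightedCoverage(gr, weights[sel])
    }
    new("StrandedCoverage",
        forward = covOne(st == "+"),
        reverse = covOne(st == "-"),
        seqinfo = assembly,
        replicate = as.character(replicate),
        method = "raw")
}

#' Scale a coverage track by a constant
#'
#' Used to apply the per-replicate size factor \eqn{F_j} (see
#' [computeSizeFactor()]); after scaling, a raw unweighted track's total mass
#' equals the common scale.
#'
#' @param x a [StrandedCoverage-class].
#' @param factor positive scalar.
#' @return the scaled track.
#' @export
scaleTrack <- function(x, factor) {
    stopifnot(is(x, "StrandedCoverage"), length(factor) == 1L, factor > 0)
    x@forward <- x@forward * factor
    x@reverse <- x@reverse * factor
    x
}

.weightedCoverage <- function(gr, weights) {
    # gr must carry seqinfo; coverage() rejects zero-length weight vectors
    if (length(gr) == 0L)
        return(GenomicRanges::coverage(gr))
    cov <- GenomicRanges::coverage(gr, weight = weights)
    # weighted coverage is accumulated by running sums, which can leave
    # O(1e-17) residues at uncovered positions; snap those to exact zero
    as(lapply(cov, function(x) {
        rv <- runValue(x)
        rv[abs(rv) < 1e-10] <- 0
        runValue(x) <- rv
        x
    }), "RleList")
}

.rleToGRanges <- function(rlelist, seqinfo) {
    gr <- as(rlelist, "GRanges")
    gr <- gr[gr$score != 0]
    seqinfo(gr) <- seqinfo
    sort(gr)
}

#' Write one strand of a signal track to bedGraph or BigWig
#'
#' Runs of equal signal are merged into single intervals; zero-signal runs are
#' omitted.  bedGraph intervals are 0-based half-open, sorted and
#' non-overlapping.
#'
#' @param track a [StrandedCoverage-class].
#' @param path output file.
#' @param strand which strand to write: \code{"forward"} or \code{"reverse"}.
#' @param format \code{"bedgraph"} or \code{"bigwig"}.
#' @return \code{path}, invisibly.
#' @seealso [readSignalTrack()] for the inverse, [writeSignalTracks()] to
#'   write both strands with the \code{.fwd.}/\code{.rev.} suffix convention.
#' @export
writeSignalTrack <- function(track, path,
                             strand = c("forward", "reverse"),
                             format = c("bedgraph", "bigwig")) {
    stopifnot(is(track, "StrandedCoverage"))
    strand <- match.arg(strand)
    format <- match.arg(format)
    v <- if (strand == "forward") track@forward else track@reverse
    gr <- .rleToGRanges(v, track@seqinfo)
    fmt <- if (format == "bedgraph") "bedGraph" else "BigWig"
    if (format == "bigwig" && length(gr) == 0L)
        stop("cannot write an empty BigWig track: ", path)
    tryCatch(rtracklayer::export(gr, path, format = fmt),
             error = function(e)
                 stop("cannot write ", format, " track to ", path, ": ",
                      conditionMessage(e), call. = FALSE))
    invisible(path)
}

#' @rdname writeSignalTrack
#' @param prefix output path prefix; files are written as
#'   \code{<prefix>.fwd.<ext>} and \code{<prefix>.rev.<ext>}.
#' @return \code{writeSignalTracks} returns the two paths, invisibly.
#' @export
writeSignalTracks <- function(track, prefix, format = c("bedgraph", "bigwig")) {
    format <- match.arg(format)
    ext <- if (format == "bedgraph") "bedgraph" else "bw"
    paths <- c(forward = paste0(prefix, ".fwd.", ext),
               reverse = paste0(prefix, ".rev.", ext))
    writeSignalTrack(track, paths[["forward"]], "forward", format)
    writeSignalTrack(track, paths[["reverse"]], "reverse", format)
    invisible(paths)
}

#' Read a signal track written by [writeSignalTrack()]
#'
#' @param forwardPath,reversePath bedGraph/BigWig files for the two strands.
#' @param assembly \code{Seqinfo}.
#' @param format \code{"bedgraph"} or \code{"bigwig"}.
#' @param replicate,method labels for the reconstructed track.
#' @return a [StrandedCoverage-class].
#' @export
readSignalTrack <- function(forwardPath, reversePath, assembly,
                            format = c("bedgraph", "bigwig"),
                            replicate = NA_character_, method = "raw") {
    format <- match.arg(format)
    fmt <- if (format == "bedgraph") "bedGraph" else "BigWig"
    readOne <- function(p) {
        raw <- rtracklayer::import(p, format = fmt)
        gr <- GRanges(seqnames(raw), IRanges(start(raw), end(raw)),
                      seqinfo = assembly)
        w <- if (length(raw)) raw$score else numeric(0L)
        .weightedCoverage(gr, w)
    }
    new("StrandedCoverage",
        forward = readOne(forwardPath),
        reverse = readOne(reversePath),
        seqinfo = assembly,
        replicate = as.character(replicate),
        method = method)
}
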