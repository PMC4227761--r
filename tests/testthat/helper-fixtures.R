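suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
    library(GenomeInfoDb)
})

# one-chromosome StrandedCoverage from dense value vectors
makeTrack <- function(fwd, rev = numeric(length(fwd)),
                      replicate = "r1", method = "raw", chrom = "chr1") {
    stopifnot(length(fwd) == length(rev))
    new("StrandedCoverage",
        forward = RleList(setNames(list(Rle(as.numeric(fwd))), chrom)),
        reverse = RleList(setNames(list(Rle(as.numeric(rev))), chrom)),
        seqinfo = Seqinfo(chrom, length(fwd)),
        replicate = replicate, method = method)
}

denseFwd <- function(track, chrom = "chr1")
    as.numeric(forwardTrack(track)[[chrom]])
denseRev <- function(track, chrom = "chr1")
    as.numeric(reverseTrack(track)[[chrom]])

# write a GRanges of reads as a BED6 file; name column carries the read
# prefix when present
writeBed <- function(gr, path = tempfile(fileext = ".bed")) {
    prefix <- mcols(gr)$readPrefix
    name <- if (is.null(prefix)) paste0("read_", seq_along(gr))
            else ifelse(is.na(prefix), paste0("read_", seq_along(gr)), prefix)
    df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     name, 0L, as.character(strand(gr)))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    path
}

writeChromSizes <- function(assembly, path = tempfile()) {
    write.table(data.frame(seqnames(assembly), seqlengths(assembly)),
                path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    path
}

# width-1 border-peak GRanges as produced by callBorderPeaks
makePeaks <- function(pos, strand, signal, pseudoP, region = 1L,
                      chrom = "chr1", seqlen = 100000L) {
    GRanges(chrom, IRanges(pos, width = 1L), strand = strand,
            signal = signal, kValue = rep(NA_real_, length(pos)),
            pseudoP = pseudoP, region = region,
            seqinfo = Seqinfo(chrom, seqlen))
}

# --- independent stability oracle -------------------------------------------
# Preference comparison computed directly from the (weighted score,
# |d - muT|, partner coordinate) tuples, independent of the package's
# internal ranking code.
.oraclePrefers <- function(swA, devA, coordA, swB, devB, coordB) {
    if (swA != swB) return(swA > swB)
    if (devA != devB) return(devA < devB)
    coordA < coordB
}

# TRUE iff the matching (data.frame f, r) has a blocking pair under the
# given score matrices; fpos/rpos are partner coordinates for tie-breaks
findBlockingPair <- function(match, sw, dev, admissible, fpos, rpos) {
    nf <- nrow(sw); nr <- ncol(sw)
    partnerOfF <- rep(NA_integer_, nf); partnerOfF[match$f] <- match$r
    partnerOfR <- rep(NA_integer_, nr); partnerOfR[match$r] <- match$f
    for (f in seq_len(nf)) for (r in seq_len(nr)) {
        if (!admissible[f, r]) next
        if (!is.na(partnerOfF[f]) && partnerOfF[f] == r) next
        # does f strictly prefer r over its current situation?
        fBetter <- if (is.na(partnerOfF[f])) TRUE else
            .oraclePrefers(sw[f, r], dev[f, r], rpos[r],
                           sw[f, partnerOfF[f]], dev[f, partnerOfF[f]],
                           rpos[partnerOfF[f]])
        if (!fBetter) next
        rBetter <- if (is.na(partnerOfR[r])) TRUE else
            .oraclePrefers(sw[f, r], dev[f, r], fpos[f],
                           sw[partnerOfR[r], r], dev[partnerOfR[r], r],
                           fpos[partnerOfR[r]])
        if (rBetter) return(c(f = f, r = r))
    }
    NULL
}
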