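#' Configuration for the ChIP-exo read simulator
#'
#' Describes a synthetic experiment with planted binding sites whose
#' forward/reverse borders are known, so every pipeline stage can be
#' validated against truth.  Each planted site of width w has its forward
#' border at its leftmost base and its reverse border at its rightmost base;
#' border reads pile their 5' ends on those bases (clonal reads -- the
#' expected ChIP-exo signature, not an artifact), blurred by a small
#' exonuclease-stop jitter.  Replicates share the sites but draw independent
#' read counts, at different depths, over an independent uniform background.
#'
#' @param genome named integer vector of chromosome lengths (default one
#'   100 kb chromosome).
#' @param nSites number of planted sites (default 200).
#' @param siteWidth site width(s) in bp (default 49, a typical
#'   zinc-finger-factor outer footprint); give a vector plus
#'   \code{widthProbs} for a mixture (e.g. \code{c(49, 13)} to mimic
#'   outer/inner double stops).
#' @param widthProbs mixture proportions matching \code{siteWidth}.
#' @param borderDepth mean clonal reads per border per unit depth factor
#'   (default 50).
#' @param jitterSd exonuclease-stop jitter SD in nt (default 0.5: most stops
#'   on the exact border base, occasional one-base slips).
#' @param backgroundRate diffuse background reads per kb per replicate
#'   (default 0.5).
#' @param nReplicates number of biological replicates (default 3).
#' @param depthFactors per-replicate relative depths (default evenly spread
#'   over 0.8--1.2).
#' @param readLength sequenced read length (default 36 nt; reads may extend
#'   past the site, as digestion stops at the bound protein).
#' @param kmerBias optional named numeric vector of start k-mer enrichment
#'   multipliers (e.g. \code{c(ACGTAC = 5)}); when set, every read gets a
#'   simulated sequence whose first k-mer is drawn with these multipliers
#'   and the rest uniform, and the sequence is carried as
#'   \code{readPrefix}.
#' @param seed integer seed; the full output stream is a deterministic
#'   function of the config.
#' @return a \code{list} of class \code{"simConfig"}.
#' @seealso [simulateChipExo()]
#' @export
simConfig <- function(genome = c(sim = 100000L),
                      nSites = 200L,
                      siteWidth = 49L,
                      widthProbs = NULL,
                      borderDepth = 50,
                      jitterSd = 0.5,
                      backgroundRate = 0.5,
                      nReplicates = 3L,
                      depthFactors = NULL,
                      readLength = 36L,
                      kmerBias = NULL,
                      seed = 1L) {
    if (is.null(names(genome)) || any(genome <= 0))
        stop("genome must be a named vector of positive chromosome lengths")
    if (is.null(depthFactors))
        depthFactors <- if (nReplicates == 1L) 1
                        else seq(0.8, 1.2, length.out = nReplicates)
    if (length(depthFactors) != nReplicates)
        stop("need one depth factor per replicate")
    if (!is.null(widthProbs) && length(widthProbs) != length(siteWidth))
        stop("widthProbs must match siteWidth")
    if (is.null(widthProbs))
        widthProbs <- rep(1 / length(siteWidth), length(siteWidth))
    stopifnot(borderDepth >= 0, jitterSd >= 0, backgroundRate >= 0,
              readLength >= 1L, nSites >= 1L)
    structure(list(genome = genome, nSites = as.integer(nSites),
                   siteWidth = as.integer(siteWidth), widthProbs = widthProbs,
                   borderDepth = borderDepth, jitterSd = jitterSd,
                   backgroundRate = backgroundRate,
                   nReplicates = as.integer(nReplicates),
                   depthFactors = depthFactors,
                   readLength = as.integer(readLength),
                   kmerBias = kmerBias, seed = as.integer(seed)),
              class = "simConfig")
}

.simSequences <- function(nReads, readLength, kmerBias) {
    k <- unique(nchar(names(kmerBias)))
    if (length(k) != 1L)
        stop("kmerBias k-mers must share one length")
    kmers <- .allKmers(k)
    mult <- rep(1, length(kmers))
    names(mult) <- kmers
    idx <- match(toupper(names(kmerBias)), kmers)
    if (anyNA(idx))
        stop("kmerBias names must be ACGT k-mers")
    mult[idx] <- kmerBias
    starts <- sample(kmers, nReads, replace = TRUE, prob = mult / sum(mult))
    tailLen <- readLength - k
    tails <- matrix(sample(c("A", "C", "G", "T"), nReads * tailLen,
                           replace = TRUE), nrow = nReads)
    paste0(starts, do.call(paste0, as.data.frame(tails)))
}

#' Simulate ChIP-exo alignments with known border truth
#'
#' Plants non-overlapping sites (forward border at the left edge, reverse
#' border at the right edge), then draws, per replicate, Poisson numbers of
#' clonal border reads whose 5' ends sit on the border base plus a rounded
#' Normal jitter, and uniform background reads on random strands.  Identical
#' configs (including seed) produce identical output.
#'
#' @param config a [simConfig()] object.
#' @return list with elements \code{reads} (one \code{GRanges} per
#'   replicate, with \code{readPrefix} when \code{kmerBias} is set),
#'   \code{truth} (\code{data.frame}: chrom, fwd, rev, width -- 1-based
#'   border coordinates), \code{assembly} (\code{Seqinfo}) and
#'   \code{config}.
#' @seealso [writeSimulation()]
#' @export
simulateChipExo <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    restore <- .restoreRNG()
    on.exit(restore())
    set.seed(config$seed)
    L <- config$readLength
    margin <- L + 1000L  # room for reads and background flanks
    maxW <- max(config$siteWidth)
    usable <- pmax(config$genome - 2L * margin, 0L)
    if (sum(usable) < config$nSites * (maxW + 200L))
        stop("genome too small to place ", config$nSites,
             " non-overlapping sites of width ", maxW)
    # apportion sites to chromosomes by usable length, largest remainder last
    nPer <- floor(usable / sum(usable) * config$nSites)
    while (sum(nPer) < config$nSites)
        nPer[which.max(usable / (nPer + 1L))] <-
            nPer[which.max(usable / (nPer + 1L))] + 1L

    truth <- NULL
    for (chr in names(config$genome)) {
        ns <- nPer[[chr]]
        if (ns == 0L) next
        spacing <- floor(usable[[chr]] / ns)
        slack <- spacing - maxW - 100L
        if (slack < 1L)
            stop("chromosome ", chr, " too crowded for ", ns, " sites")
        offs <- sample.int(slack, ns, replace = TRUE)
        w <- config$siteWidth[sample.int(length(config$siteWidth), ns,
                                         replace = TRUE,
                                         prob = config$widthProbs)]
        fwd <- margin + (seq_len(ns) - 1L) * spacing + offs
        truth <- rbind(truth, data.frame(
            chrom = chr, fwd = fwd, rev = fwd + w - 1L, width = w))
    }
    assembly <- Seqinfo(names(config$genome),
                        unname(as.integer(config$genome)))

    mkReads <- function(chrom, pos5, strandChar) {
        st <- ifelse(strandChar == "+", pos5, pos5 - L + 1L)
        en <- st + L - 1L
        ok <- st >= 1L & en <= config$genome[chrom]
        GRanges(chrom[ok], IRanges(st[ok], en[ok]), strand = strandChar[ok])
    }

    reads <- vector("list", config$nReplicates)
    for (j in seq_len(config$nReplicates)) {
        dj <- config$depthFactors[j]
        nF <- stats::rpois(nrow(truth), config$borderDepth * dj)
        nR <- stats::rpois(nrow(truth), config$borderDepth * dj)
        fwdPos <- rep(truth$fwd, nF) +
            round(stats::rnorm(sum(nF), 0, config$jitterSd))
        revPos <- rep(truth$rev, nR) -
            round(stats::rnorm(sum(nR), 0, config$jitterSd))
        grF <- mkReads(rep(truth$chrom, nF), as.integer(fwdPos),
                       rep("+", sum(nF)))
        grR <- mkReads(rep(truth$chrom, nR), as.integer(revPos),
                       rep("-", sum(nR)))
        bg <- list()
        for (chr in names(config$genome)) {
            nB <- stats::rpois(1L, config$backgroundRate *
                                   config$genome[[chr]] / 1000 * dj)
            if (nB == 0L) next
            pos <- sample.int(config$genome[[chr]], nB, replace = TRUE)
            sdr <- sample(c("+", "-"), nB, replace = TRUE)
            bg[[chr]] <- mkReads(rep(chr, nB), pos, sdr)
        }
        gr <- suppressWarnings(c(grF, grR, do.call(c, c(list(GRanges()), bg))))
        seqlevels(gr) <- seqlevels(assembly)
        seqinfo(gr) <- assembly
        mcols(gr)$readPrefix <- if (is.null(config$kmerBias))
            rep(NA_character_, length(gr))
        else .simSequences(length(gr), L, config$kmerBias)
        mcols(gr)$replicate <- sprintf("rep%d", j)
        reads[[j]] <- gr
    }
    names(reads) <- sprintf("rep%d", seq_len(config$nReplicates))
    list(reads = reads, truth = truth, assembly = assembly, config = config)
}

#' Write a simulation to disk
#'
#' Emits one BED6 file per replicate (when the simulation carries read
#' sequences, the BED name column stores the as-sequenced prefix -- the
#' convention [loadAlignments()] understands), the truth table as TSV, and a
#' chrom.sizes file.
#'
#' @param sim result of [simulateChipExo()].
#' @param outdir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- c()
    for (nm in names(sim$reads)) {
        gr <- sim$reads[[nm]]
        prefix <- mcols(gr)$readPrefix
        name <- ifelse(is.na(prefix), paste0("read_", seq_along(gr)), prefix)
        df <- data.frame(chrom = as.character(seqnames(gr)),
                         start = start(gr) - 1L, end = end(gr),
                         name = name, score = 0L,
                         strand = as.character(strand(gr)))
        p <- file.path(outdir, paste0(nm, ".bed"))
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        paths[nm] <- p
    }
    tp <- file.path(outdir, "truth.tsv")
    utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["truth"] <- tp
    cp <- file.path(outdir, "chrom.sizes")
    utils::write.table(
        data.frame(names(seqlengths(sim$assembly)),
                   unname(seqlengths(sim$assembly))),
        cp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths["chromSizes"] <- cp
    invisible(paths)
}
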