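#' Pipeline run configuration
#'
#' Bundles every tunable of the four-stage workflow (normalize, consolidate,
#' call borders, pair borders) with the package defaults.  A config
#' round-trips unchanged through [writeExoConfig()] / [readExoConfig()].
#'
#' @param alignments character vector of per-replicate alignment files
#'   (BED6/SAM/BAM).
#' @param chromSizes chromosome-sizes file (name, length).
#' @param commonScale depth-normalization target mass (default 1e7).
#' @param biasCorrection estimate and apply k-mer start bias weights
#'   (default \code{FALSE}; correction is optional and typically changes
#'   results little).
#' @param kmerSize bias-model k-mer length (default 6).
#' @param minMapq SAM/BAM mapping-quality cutoff standing in for the
#'   uniqueness filter (default 20).
#' @param method consolidation method (default \code{"entropy"}).
#' @param pool entropy proportion pooling (default \code{"position"}).
#' @param minSignal,mergeGap,bgFlank candidate-region segmentation
#'   parameters (defaults 5 normalized units, 100 bp, 500 bp).
#' @param alpha border pseudo p-value cutoff (default 0.05).
#' @param collapseDist border adjacency collapsing distance (default 2 nt).
#' @param nComponents mixture components for the pair-size fit (default 2).
#' @param muT optional manual expected pair size, skipping the mixture fit.
#' @param sigmaT spread used with a manual \code{muT} (default 2).
#' @param kernelWidth optional override of the pair-weighting kernel width
#'   (default \code{max(2 sigmaT, 1)} from the fitted model).
#' @param maxSpan maximum admissible pair size (default
#'   \code{muT + 4 max(sigmaT, 2)} post-fit; the high-confidence size harvest is
#'   pre-capped at 500 bp).
#' @param alphaPair combined pair p-value cutoff (default 0.05).
#' @param trackFormat signal-track output format (\code{"bedgraph"} or
#'   \code{"bigwig"}).
#' @param seed seed for the EM initialization (default 1).
#' @return a \code{list} of class \code{"exoConfig"}.
#' @seealso [runPipeline()]
#' @export
exoConfig <- function(alignments = character(),
                      chromSizes = "",
                      commonScale = 1e7,
                      biasCorrection = FALSE,
                      kmerSize = 6L,
                      minMapq = 20L,
                      method = "entropy",
                      pool = "position",
                      minSignal = 5,
                      mergeGap = 100L,
                      bgFlank = 500L,
                      alpha = 0.05,
                      collapseDist = 2L,
                      nComponents = 2L,
                      muT = NULL,
                      sigmaT = 2,
                      kernelWidth = NULL,
                      maxSpan = NULL,
                      alphaPair = 0.05,
                      trackFormat = "bedgraph",
                      seed = 1L) {
    method <- match.arg(method, c("entropy", "am", "gm", "snr"))
    pool <- match.arg(pool, c("position", "track"))
    trackFormat <- match.arg(trackFormat, c("bedgraph", "bigwig"))
    alignments <- as.character(unlist(alignments))  # YAML lists re-coerce
    structure(list(alignments = alignments, chromSizes = chromSizes,
                   commonScale = commonScale,
                   biasCorrection = isTRUE(biasCorrection),
                   kmerSize = as.integer(kmerSize),
                   minMapq = as.integer(minMapq),
                   method = method, pool = pool,
                   minSignal = minSignal, mergeGap = as.integer(mergeGap),
                   bgFlank = as.integer(bgFlank), alpha = alpha,
                   collapseDist = as.integer(collapseDist),
                   nComponents = as.integer(nComponents),
                   muT = muT, sigmaT = sigmaT, kernelWidth = kernelWidth,
                   maxSpan = maxSpan, alphaPair = alphaPair,
                   trackFormat = trackFormat, seed = as.integer(seed)),
              class = "exoConfig")
}

#' Serialize / deserialize a pipeline configuration
#'
#' Flat key-value YAML; unset optional keys (\code{muT}, \code{kernelWidth},
#' \code{maxSpan}) are omitted and restored as \code{NULL}.
#'
#' @param config an [exoConfig()] object.
#' @param path file path.
#' @return \code{writeExoConfig}: \code{path}, invisibly;
#'   \code{readExoConfig}: the config.
#' @export
writeExoConfig <- function(config, path) {
    stopifnot(inherits(config, "exoConfig"))
    x <- config[!vapply(config, is.null, logical(1L))]
    yaml::write_yaml(unclass(x), path)
    invisible(path)
}

#' @rdname writeExoConfig
#' @export
readExoConfig <- function(path) {
    x <- yaml::read_yaml(path)
    do.call(exoConfig, x)
}

#' Normalize one replicate to a coverage track
#'
#' Loads alignments, optionally fits/applies the k-mer bias model from the
#' replicate's singleton reads, builds strand-separated 5'-end coverage and
#' scales it by the size factor \code{commonScale / nReads}.
#'
#' @param path alignment file.
#' @param assembly \code{Seqinfo}.
#' @param config an [exoConfig()] object.
#' @param replicate replicate label.
#' @return list with elements \code{track} (normalized
#'   [StrandedCoverage-class]), \code{nReads}, \code{sizeFactor} and
#'   \code{biasModel} (\code{NULL} when correction is off).
#' @export
preprocessReplicate <- function(path, assembly, config = exoConfig(),
                                replicate = basename(path)) {
    reads <- loadAlignments(path, assembly, minMapq = config$minMapq,
                            replicate = replicate)
    if (length(reads) == 0L)
        stop("no usable alignments in ", path)
    model <- NULL
    if (config$biasCorrection) {
        singles <- findSingletonReads(reads)
        model <- estimateKmerBias(singles, k = config$kmerSize)
    }
    w <- applyReadWeights(reads, model)
    fj <- computeSizeFactor(length(reads), config$commonScale)
    track <- fivePrimeCoverage(reads, assembly, weights = w,
                               replicate = replicate)
    list(track = scaleTrack(track, fj), nReads = length(reads),
         sizeFactor = fj, biasModel = model)
}

#' Run the full border-pair workflow
#'
#' Executes the four stages -- per-replicate depth normalization (with
#' optional bias correction), entropy consolidation, Chebyshev border-peak
#' calling, and Gale-Shapley border pairing -- and writes all artifacts to
#' \code{outdir}: per-replicate and consolidated signal tracks
#' (\code{.fwd.}/\code{.rev.} suffixes), border peaks (BED6+2), border pairs
#' (BED6+4), the fitted pair-size model sidecar, and a TSV run manifest
#' recording parameters, input checksums and the package version.  Identical
#' inputs and config yield identical outputs.
#'
#' @param config an [exoConfig()] object with \code{alignments} and
#'   \code{chromSizes} set.
#' @param outdir output directory (created).
#' @return (invisibly) a list: \code{tracks}, \code{consolidated},
#'   \code{regions}, \code{peaks}, \code{sizeModel}, \code{pairs},
#'   \code{paths}.
#' @export
runPipeline <- function(config, outdir) {
    stopifnot(inherits(config, "exoConfig"))
    missing <- c(config$alignments, config$chromSizes)
    missing <- missing[!file.exists(missing)]
    if (length(missing))
        stop("[input] missing input file(s): ",
             paste(missing, collapse = ", "))
    assembly <- readChromSizes(config$chromSizes)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()

    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    }

    message("[preprocess] normalizing ", length(config$alignments),
            " replicate(s)")
    reps <- stage("preprocess", lapply(seq_along(config$alignments),
        function(j) preprocessReplicate(config$alignments[j], assembly,
                                        config, sprintf("rep%d", j))))
    tracks <- lapply(reps, `[[`, "track")
    for (j in seq_along(tracks))
        paths[[sprintf("track_rep%d", j)]] <- writeSignalTracks(
            tracks[[j]], file.path(outdir, sprintf("rep%d", j)),
            config$trackFormat)
    for (j in seq_along(reps))
        if (!is.null(reps[[j]]$biasModel))
            writeKmerBiasModel(reps[[j]]$biasModel,
                file.path(outdir, sprintf("rep%d.kmer_bias.tsv", j)))

    message("[consolidate] method=", config$method)
    consolidated <- stage("consolidate",
        consolidate(tracks, method = config$method, pool = config$pool))
    paths$consolidated <- writeSignalTracks(
        consolidated, file.path(outdir, "consolidated"), config$trackFormat)

    message("[callborders] segmenting and calling border peaks")
    regions <- stage("callborders", segmentCandidateRegions(
        consolidated, minSignal = config$minSignal,
        mergeGap = config$mergeGap, bgFlank = config$bgFlank))
    peaks <- stage("callborders", callBorderPeaks(
        consolidated, regions, alpha = config$alpha,
        collapseDist = config$collapseDist))
    paths$peaks <- file.path(outdir, "border_peaks.bed")
    writeBorderPeaks(peaks, paths$peaks)

    message("[pairborders] fitting size model and matching borders")
    sizes <- highConfidenceSizes(peaks)
    model <- stage("pairborders", {
        if (!is.null(config$muT))
            pairSizeModel(config$muT, config$sigmaT)
        else
            estimatePairSizeModel(sizes, C = config$nComponents,
                                  seed = config$seed)
    })
    if (!is.null(config$kernelWidth))
        model@K <- config$kernelWidth
    maxSpan <- if (!is.null(config$maxSpan)) config$maxSpan
               else .defaultMaxSpan(model)
    pairs <- stage("pairborders", callBorderPairs(
        peaks, model, alphaPair = config$alphaPair, maxSpan = maxSpan))
    paths$pairs <- file.path(outdir, "border_pairs.bed")
    writeBorderPairs(pairs, paths$pairs)
    paths$sizeModel <- file.path(outdir, "pair_size_model.txt")
    writePairSizeModel(model, paths$sizeModel, sizes)

    paths$manifest <- file.path(outdir, "manifest.tsv")
    .writeManifest(config, outdir, paths$manifest)
    message("[done] ", length(pairs), " border pair(s) -> ", outdir)
    invisible(list(tracks = tracks, consolidated = consolidated,
                   regions = regions, peaks = peaks, sizeModel = model,
                   pairs = pairs, paths = paths))
}

.writeManifest <- function(config, outdir, path) {
    flat <- unclass(config)
    flat <- flat[!vapply(flat, is.null, logical(1L))]
    kv <- data.frame(
        key = c("package", "version", names(flat), "input_md5"),
        value = c("exoBorders",
                  as.character(utils::packageVersion("exoBorders")),
                  vapply(flat, function(v) paste(format(v), collapse = ","),
                         character(1L)),
                  paste(tools::md5sum(c(config$alignments,
                                        config$chromSizes)),
                        collapse = ",")))
    utils::write.table(kv, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
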