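test_that("size factors follow commonScale / totalReads", {
    expect_equal(computeSizeFactor(1e7), 1)
    expect_equal(computeSizeFactor(2e7), 0.5)
    expect_equal(computeSizeFactor(1), 1e7)
    expect_equal(computeSizeFactor(5000, commonScale = 1000), 0.2)
    expect_error(computeSizeFactor(0), "no mapped reads")
})

test_that("singleton detection matches a brute-force pairwise oracle", {
    # spec'd edge cases
    asm <- Seqinfo("chr1", 100000L)
    disjoint <- GRanges("chr1", IRanges(c(101, 201), c(150, 250)),
                        strand = "+")
    expect_length(findSingletonReads(disjoint), 2L)
    touching <- GRanges("chr1", IRanges(c(101, 150), c(150, 199)),
                        strand = c("+", "-"))  # 1-base overlap, either strand
    expect_length(findSingletonReads(touching), 0L)
    lone <- GRanges("chr1", IRanges(500, 535), strand = "+")
    expect_length(findSingletonReads(lone), 1L)

    # randomized instances vs O(n^2) interval-intersection oracle
    set.seed(42)
    for (rep in 1:20) {
        n <- sample(5:60, 1)
        gr <- GRanges("chr1",
                      IRanges(sample(2000L, n, replace = TRUE), width = 36L),
                      strand = sample(c("+", "-"), n, replace = TRUE))
        overlapsAny <- vapply(seq_len(n), function(i) {
            any(start(gr)[-i] <= end(gr)[i] & end(gr)[-i] >= start(gr)[i])
        }, logical(1L))
        got <- findSingletonReads(gr)
        want <- gr[!overlapsAny]
        expect_equal(sort(got), sort(want))
    }
})

test_that("positionally exchangeable k-mer usage gives weights near 1", {
    # reads with iid uniform bases have no positional composition bias,
    # so every observed k-mer's start frequency matches its interior mean
    set.seed(7)
    n <- 1e5
    L <- 16L
    seqs <- do.call(paste0, as.data.frame(
        matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n)))
    reads <- GRanges("chr1", IRanges(seq_len(n) * 50L, width = L),
                     strand = "+", readPrefix = seqs)
    model <- estimateKmerBias(reads, k = 4L, readLength = L)
    w <- biasTable(model)$weight
    # weights concentrate around 1; residual spread is multinomial sampling
    # noise (~5% per k-mer at this depth), so bound the mean deviation
    expect_lt(mean(abs(w - 1)), 0.05)
    expect_lt(max(abs(w - 1)), 0.3)
})

test_that("weights equal clamped pnMean/p0 and p0 sums to 1", {
    set.seed(3)
    seqs <- c(rep("AAAATTTTGGGG", 30), rep("CCCCAAAATTTT", 20),
              rep("TTTTCCCCGGGG", 10))
    reads <- GRanges("chr1", IRanges(seq_along(seqs) * 100L, width = 12L),
                     strand = "+", readPrefix = seqs)
    model <- estimateKmerBias(reads, k = 4L, readLength = 12L)
    tab <- biasTable(model)
    expect_equal(sum(tab$p0), 1)
    recomputed <- ifelse(tab$p0 > 0, tab$pnMean / tab$p0, 10)
    expect_equal(tab$weight, pmin(pmax(recomputed, 0.1), 10))
    # a k-mer seen internally but never at a read start takes the upper clamp
    internalOnly <- tab[tab$p0 == 0 & tab$pnMean > 0, ]
    expect_gt(nrow(internalOnly), 0L)
    expect_true(all(internalOnly$weight == 10))
})

test_that("start frequency double the interior mean gives weight 0.5", {
    # 4 reads of length 6, k = 4 (interior offsets 1 and 2):
    # "AAAA" starts r1 and r2 (p0 = 0.5), appears at offset 1 only in r3 and
    # offset 2 only in r4 (interior mean = 0.25) -> W = 0.25/0.5 = 0.5
    reads <- GRanges("chr1", IRanges(c(10, 100, 200, 300), width = 6L),
                     strand = "+",
                     readPrefix = c("AAAAGC", "AAAACC", "CAAAAG", "GCAAAA"))
    model <- estimateKmerBias(reads, k = 4L, readLength = 6L)
    tab <- biasTable(model)
    expect_equal(tab$p0[tab$kmer == "AAAA"], 0.5)
    expect_equal(tab$pnMean[tab$kmer == "AAAA"], 0.25)
    expect_equal(tab$weight[tab$kmer == "AAAA"], 0.5)
})

test_that("read weighting looks up the first k-mer with fallback 1", {
    model <- estimateKmerBias(
        GRanges("chr1", IRanges(c(10, 100), width = 8L), strand = "+",
                readPrefix = c("AAAAAACG", "CGTACGTA")),
        k = 6L, readLength = 8L)
    tab <- biasTable(model)
    wAAA <- tab$weight[tab$kmer == "AAAAAA"]
    reads <- GRanges("chr1", IRanges(c(1, 2, 3, 4), width = 8L),
                     strand = "+",
                     readPrefix = c("AAAAAACG", "NNNNNNNN", NA, "TTTTTTTT"))
    w <- applyReadWeights(reads, model)
    expect_equal(w, c(wAAA, 1, 1, 1))
    # correction disabled: identity weights
    expect_equal(applyReadWeights(reads, NULL), rep(1, 4))
})

test_that("weighting rescales magnitudes but never moves nonzero positions", {
    set.seed(9)
    asm <- Seqinfo("chr1", 5000L)
    n <- 200L
    reads <- GRanges("chr1",
                     IRanges(sample(4000L, n, replace = TRUE), width = 36L),
                     strand = sample(c("+", "-"), n, replace = TRUE))
    plain <- fivePrimeCoverage(reads, asm)
    weighted <- fivePrimeCoverage(reads, asm,
                                  weights = runif(n, 0.2, 3))
    expect_equal(denseFwd(plain) > 0, denseFwd(weighted) > 0)
    expect_equal(denseRev(plain) > 0, denseRev(weighted) > 0)
})

test_that("normalized unweighted track mass equals the common scale", {
    set.seed(13)
    asm <- Seqinfo("chr1", 5000L)
    for (n in c(3L, 137L, 1000L)) {
        reads <- GRanges("chr1",
                         IRanges(sample(4000L, n, replace = TRUE),
                                 width = 36L),
                         strand = sample(c("+", "-"), n, replace = TRUE))
        track <- scaleTrack(fivePrimeCoverage(reads, asm),
                            computeSizeFactor(n))
        expect_equal(sum(trackMass(track)), 1e7)
    }
})

test_that("bias model serialization round-trips", {
    reads <- GRanges("chr1", IRanges(c(10, 100, 200), width = 10L),
                     strand = "+",
                     readPrefix = c("ACGTACGTAC", "TTTTTTTTTT", "GGGGGGGGGG"))
    model <- estimateKmerBias(reads, k = 4L, readLength = 10L)
    f <- tempfile(fileext = ".tsv")
    writeKmerBiasModel(model, f)
    back <- readKmerBiasModel(f)
    expect_equal(kmerSize(back), kmerSize(model))
    expect_equal(as.data.frame(biasTable(back)),
                 as.data.frame(biasTable(model)))
})

test_that("bias estimation without sequences advises disabling correction", {
    reads <- GRanges("chr1", IRanges(10, 45), strand = "+",
                     readPrefix = NA_character_)
    expect_error(estimateKmerBias(reads), "disable bias correction")
})
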