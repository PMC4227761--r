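# exoBorders

Border-pair detection for ChIP-exo data in R.

## The problem

ChIP-exo couples chromatin immunoprecipitation with a λ-exonuclease
digestion that chews unprotected DNA up to the footprint of the bound
protein. The 5′ ends of sequenced reads therefore pile up at the two
*borders* of each transcription-factor binding site (TFBS): a
forward-strand border at the upstream edge and a reverse-strand border at
the downstream edge, each resolvable to a single nucleotide. Generic
ChIP-seq peak callers model a single smeared enrichment peak and treat
clonal 5′-end pileups as PCR artifacts, so they discard exactly the signal
ChIP-exo was designed to produce. exoBorders is written for analysts who
want both boundaries of each site, with a statistical score per border
pair.

## The method

Four stages, each exposed as ordinary functions over Bioconductor
containers (`GRanges`, `RleList`, S4 classes with accessors):

1. **Normalization.** Strand-separated 5′-end coverage `C_ij` per replicate
   *j*; depth scaled by the size factor `F_j = 1e7 / T_j` where `T_j` is
   the unique-read count. Optionally, a positional k-mer composition bias
   model estimated from *singleton reads* (reads overlapping no other read)
   re-weights each read by `W(h) = mean_n P_n(h) / P_0(h)` for its first
   k-mer *h* (default hexamer); correction is off by default.
2. **Consolidation.** Replicate tracks are combined position-wise as
   `S_i = (1/n) Σ_j v_ij × H(p)/ln n`, where `p_j = v_ij / Σ_j v_ij` and
   `H` is Shannon entropy: reproducible positions keep their average,
   replicate-private noise is suppressed (weight 0 when one replicate
   carries all signal). Arithmetic mean, geometric mean and SNR are
   available as comparators.
3. **Border detection.** Within candidate regions, a position with signal
   X against a local background (mean m, sd s over the region ± 500 bp) is
   scored with the Chebyshev bound `Pr(X − m ≥ ks) ≤ 1/k²`,
   `k = (X − m)/s` — a distribution-free pseudo p-value (vacuous for
   k ≤ 1). Significant positions within 2 nt collapse to a single border.
4. **Border matching.** Pair sizes `d = rev − fwd + 1` from unambiguous
   regions are fitted with a Gaussian-mixture EM; the dominant mean `μ_T`
   centers the kernel `S_weighted = S_obs · exp(−(d − μ_T)²/K²)` that sets
   preferences for Gale–Shapley stable matching of forward to reverse
   borders. Each matched pair's two border pseudo p-values are combined by
   Fisher's method, `P_pair = q(1 − ln q)`, `q = P_fwd · P_rev`.

A deterministic simulator (`simulateChipExo`) plants sites with known
borders, clonal border reads, jitter, replicate depth variation and
uniform background, so the whole pipeline is testable against truth.

## Worked example

```r
library(exoBorders)

sim   <- simulateChipExo(simConfig(nSites = 20, seed = 42))
paths <- writeSimulation(sim, "exo_demo")
cfg   <- exoConfig(alignments = paths[c("rep1", "rep2", "rep3")],
                   chromSizes = paths[["chromSizes"]])
res   <- runPipeline(cfg, "exo_demo/out")
#> [preprocess] normalizing 3 replicate(s)
#> [consolidate] method=entropy
#> [callborders] segmenting and calling border peaks
#> [pairborders] fitting size model and matching borders
#> [done] 20 border pair(s) -> exo_demo/out

res$sizeModel
#> PairSizeModel with 2 component(s)
#>   comp 1: mean=49.00 sd=0.01 weight=0.504
#>   comp 2: mean=49.00 sd=0.01 weight=0.496
#>   muT=49.00 sigmaT=0.01 K=1.00 (EM converged, 3 iterations)

res$pairs[1:3]
#> GRanges object with 3 ranges and 7 metadata columns:
#>       seqnames      ranges strand |      dObs      sObs sWeighted   pForward
#>   [1]      sim   3645-3693      * |        49    343969    343969 0.00103409
#>   [2]      sim 10001-10049      * |        49    323726    323726 0.00107862
#>   [3]      sim 13197-13245      * |        49    299059    299059 0.00108549
#>         pReverse       pPair    region
#>   [1] 0.00104537 1.59314e-05         1
#>   [2] 0.00111855 1.76484e-05         2
#>   [3] 0.00106049 1.68928e-05         3
```

All 20 planted 49-bp sites come back as border pairs: `ranges` spans the
two recovered borders (width = `dObs` = 49, the planted width), `sObs` is
the summed normalized border signal, and `pPair` the Fisher-combined
Chebyshev bound for the two borders (here ≈ 1.6e−5: each border sits ~30
local SDs above background, capped by each border's own 1/k²).

The building blocks are usable directly:

```r
shannonEntropy(rep(0.25, 4))     # 1.386  -- four reproducible replicates
chebyshevPValue(19, m = 10, s = 2)  # 0.0494 -- a 4.5-SD border candidate
fisherCombine(0.01, 0.02)        # 0.0019 -- combined border-pair p-value
```

A thin CLI over the same functions lives at
`inst/scripts/exoborders.R` (subcommands `run`, `preprocess`,
`consolidate`, `callborders`, `pairborders`, `simulate`).

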