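---
title: "Calling TFBS border pairs from ChIP-exo data: models and choices"
author: "exoBorders maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling TFBS border pairs from ChIP-exo data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoBorders)
```

# The data model

λ exonuclease digests DNA 5′→3′ until it reaches a cross-linked
protein–DNA contact. Every immunoprecipitated fragment from one binding
site therefore starts (on its own strand) at nearly the same base, and the
5′ ends of the mapped reads form two single-nucleotide pileups: one on the
forward strand at the site's upstream boundary and one on the reverse
strand at its downstream boundary. Three consequences drive the design:

* **Clonal reads are signal.** Many reads sharing a 5′ coordinate are the
  expected outcome of digestion stopping at the same base. exoBorders
  never deduplicates (`loadAlignments` keeps identical records), which is
  the opposite of ChIP-seq practice.
* **Strands must be kept apart.** The forward pileup and the reverse
  pileup are different biological events (`StrandedCoverage` stores one
  `RleList` per strand; only the 5′ base of each read contributes).
* **A site is a *pair* of borders.** The caller's output unit is a matched
  forward+reverse pair, not a single summit.

# Stage 1: normalization and optional bias correction

Replicate *j* is scaled by the size factor $F_j = \mathrm{scale}/T_j$
(default scale $10^7$; $T_j$ = unique-read count), so every replicate's
track mass equals the common scale and positions are comparable across
replicates of different depths.

Library chemistry biases which k-mers appear at read starts. The
correction (off by default) estimates, from **singleton reads** only
(reads overlapping no other read, on either strand — these sample the
genome free of IP/exonuclease/PCR selection), the frequency
$\hat P_0(h)$ of each k-mer $h$ at offset 0 versus its mean frequency
$\bar P_n(h)$ over interior offsets $1..L-k$, and weights each read by
$W(h) = \bar P_n(h) / \hat P_0(h)$ for its first k-mer. Unbiased
libraries give $W \approx 1$.

Choices made here:

* $k = 6$ by default (configurable 4–8). Hexamers balance resolution
  against the $4^k$ table size and per-k-mer counting noise.
* $W$ is clamped to $[0.1, 10]$: the ratio is unbounded and a k-mer seen
  a handful of times would otherwise inject large noise; a k-mer seen
  internally but never at offset 0 takes the upper clamp (it is maximally
  depleted at starts, but the raw ratio is undefined).
* Correction defaults to **off** because on unbiased data it only adds
  estimation noise; the pipeline test suite verifies that switching it on
  over unbiased simulated reads changes under 5% of called pairs.
* MAPQ ≥ 20 stands in for "uniquely mapped" on SAM/BAM input, since
  aligners encode uniqueness in MAPQ differently; BED input is assumed
  pre-filtered (BED6 has no quality field).

# Stage 2: entropy consolidation

Spurious pileups (cross-linking artifacts, PCR jackpots) are largely
replicate-private, while true exonuclease stops recur across replicates.
With normalized values $v_{ij}$ at position $i$ and proportions
$p_j = v_{ij}/\sum_j v_{ij}$, the consolidated signal is

$$S_i = \frac{1}{n}\sum_j v_{ij} \times \frac{H(p)}{\ln n}, \qquad
  H(p) = -\sum_j p_j \ln p_j,\; 0\ln 0 \equiv 0 .$$

The relative-entropy weight lies in $[0,1]$: 1 when all replicates agree
exactly (for four equal replicates $H = \ln 4 = 1.386$; with one silent
replicate it drops to $\ln 3 = 1.099$), 0 when a single replicate carries
everything. Natural logarithms are used throughout.

The proportions are computed **per position** by default. The alternative
reading — one pooled proportion vector per replicate from its total track
mass, applied everywhere — is available as `pool = "track"`; it reduces
the weight to a per-replicate depth-balance constant and loses the
position-level noise suppression, so it is not the default, but it is
kept because the position-pooled definition is the only genuinely open
interpretation question in the signal model.

Comparators `am`, `gm` and `snr` exist for benchmarking. SNR uses the
sample (n−1) standard deviation; where the across-replicate sd is 0 with
positive mean, the divergent ratio is reported as mean × 10³ — the cap
keeps the comparator finite and is irrelevant to the default method.
With a single replicate, entropy consolidation passes the track through
with weight 1 and a warning rather than failing.

# Stage 3: Chebyshev border detection

Candidate regions are maximal runs with combined (fwd+rev) signal at or
above `minSignal` (default 5 normalized units), merged across gaps
shorter than `mergeGap` (default 100 bp). For each region, a per-strand
local background mean $m$ and standard deviation $s$ are computed over
the region extended by `bgFlank` (default 500 bp) on each side, **zeros
included** and with the population (1/N) denominator — the interval is
treated as the complete local population, and the population form is what
the empirical Chebyshev guarantee
$\#\{x - m \ge k s\}/N \le 1/k^2$ holds for unconditionally.

A position with signal $X$ gets the pseudo p-value $\min(1, 1/k^2)$,
$k = (X-m)/s$, vacuous ($p = 1$) for $k \le 1$ and for $s = 0$. This is a
distribution-free upper bound, deliberately conservative: a binding site
should contribute ~2 borders, and an inflated border list would poison
the matching stage. Because the values are bounds rather than calibrated
p-values, no multiple-testing correction is applied or meaningful; the
default cutoff is 0.05 (≈ 4.5 SDs).

Peak positions within 2 nt on a strand are collapsed to the strongest
(leftmost on ties) — digestion-stop wobble produces adjacent significant
bases that are one biological border. Background statistics include the
candidate positions themselves; excluding them would shrink $s$ and make
calls slightly more permissive, so inclusion is the conservative choice.

# Stage 4: size model and stable matching

Pair sizes are measured inclusively: $d = \mathrm{rev} - \mathrm{fwd} + 1$,
so a site whose borders sit on its first and last base has $d$ equal to
its width.

**Size model.** Sizes from unambiguous regions (exactly one significant
border per strand, pre-capped at 500 bp) feed a C-component 1-D Gaussian
mixture fitted by EM (default $C = 2$, since double exonuclease stops
produce bimodal size distributions). The EM is written in the package —
the per-iteration log-likelihood trace is part of the contract (asserted
nondecreasing in the tests) and initialization is a seeded draw, making
the fit reproducible; an independent mixture fitter (mclust) is used in
the test suite as a cross-check, not as the implementation. Component
sds are floored at 0.01 (with a warning) to avoid the classic
likelihood-singularity collapse. $\mu_T$ is the dominant component's
mean; fewer than 20 sizes is an error that points to the manual
`pairSizeModel(muT)` fallback.

**Kernel.** Candidate pairs are scored
$S_\mathrm{weighted} = S_\mathrm{obs}\,e^{-(d-\mu_T)^2/K^2}$ with
$S_\mathrm{obs}$ the **sum** of the two border signals (sum rather than
mean: clonal-read evidence is additive). $K$ defaults to
$\max(2\sigma_T, 1)$: twice the dominant component's spread, floored so
that a near-degenerate fit (all high-confidence sizes identical) still
tolerates ±1 nt jitter. Admissible pairs satisfy
$1 \le d \le \mu_T + 4\max(\sigma_T, 2)$ (same floor rationale;
quadratic all-vs-all pairing over long ranges is biologically
meaningless).

**Matching.** Within a region, forward borders propose (Gale–Shapley);
both sides rank partners by descending $S_\mathrm{weighted}$, ties broken
by $|d - \mu_T|$ then by partner coordinate. The result is stable — no
forward/reverse pair prefer each other over their assignments — and each
border joins at most one pair (pairing is exclusive; regions never share
borders by construction). When several stable matchings exist the
proposer side determines which is returned, so the proposer is fixed
(forward) for determinism. The test suite checks stability against an
independent blocking-pair oracle on hundreds of random instances.

**Scoring.** The two digestions are independent events, so border
p-values combine by Fisher's method; for two tests the $\chi^2_4$ tail is
the closed form $P = q(1-\ln q)$, $q = P_\mathrm{fwd}P_\mathrm{rev}$
(verified against the $\chi^2_4$ survival function to $10^{-10}$). Pairs
above `alphaPair` (default 0.05) are dropped.

# The simulator: what it does and does not emulate

`simulateChipExo` plants non-overlapping sites (forward border at the
left edge, reverse at the right), then per replicate draws
Poisson(`borderDepth` × depth factor) clonal reads per border with their
5′ ends at the border base plus a rounded Normal(0, `jitterSd`) offset,
plus uniform background reads on random strands. Defaults describe a
clean mid-depth experiment: 200 sites of width 49 bp on a 100-kb
chromosome, 50 reads per border, jitter sd 0.5 nt, background 0.5
reads/kb, 3 replicates at relative depths 0.8/1.0/1.2, 36-nt reads.
Width mixtures (e.g. 49/13 bp) mimic outer/inner double-stop geometry,
and an optional start-k-mer enrichment exercises the bias model (read
sequences travel in the BED name column, a package convention, since
BED6 has no sequence field).

Not emulated: genome sequence (reads have no real sequence unless the
k-mer option is on), mappability holes, fragment-length selection,
correlated (non-uniform) background, and PCR duplication as distinct
from clonal stops. Passing end-to-end tests therefore demonstrates the
algorithmic chain — normalization through stable matching — recovers
planted truth under realistic noise, not that every real-data pathology
is handled.

# Numerical and engineering choices

* Coordinates are 1-based closed inside R (`GRanges` convention);
  BED/bedGraph I/O converts at the boundary, so files are standard
  0-based half-open. The reverse-strand 5′ end is the read's rightmost
  aligned base.
* Coverage is run-length encoded; memory scales with covered runs, not
  genome length. Weighted coverage accumulation can leave ~1e-17
  floating-point residue at uncovered positions; values below 1e-10 are
  snapped to exact zero so sparsity and zero-tests stay meaningful.
* Everything downstream of input parsing is a pure function of
  (inputs, config, seed): the simulator and the EM restore the caller's
  RNG state, and the one seed in `exoConfig` drives EM initialization.
* Degenerate inputs are defined, not crashed on: empty alignment files
  give empty tracks; a region with constant signal yields no borders
  ($s=0$); an empty strand yields no pairs; `fisherCombine` rejects 0
  and >1 inputs (a Chebyshev pseudo p-value is never 0).

# Validation scale

The shipped tests run the full pipeline on simulations of 20–200 sites
(up to ~70k reads across three replicates), 200-instance randomized
stable-matching checks against a brute-force oracle, 500-draw mixture
recoveries, and 30k-sample empirical Chebyshev bounds — sizes chosen so
the whole suite completes in about a minute on one core while leaving
every statistical assertion comfortably powered. The same properties
hold at larger simulation sizes; nothing in the implementation is
specific to these scales (per-chromosome `Rle` arithmetic and
region-local matching are linear in covered positions and borders).

# Known limitations

* Pseudo p-values are upper bounds; ranking by them is conservative and
  not calibrated across regions with very different background shapes.
* One border joins at most one pair: overlapping sites that truly share
  a border are split, not multi-assigned (motif-guided rescue of
  unmatched borders is out of scope).
* Paired-end and spliced alignments are not modeled; alignment itself is
  upstream.
* With a single replicate the entropy weight is constant 1, i.e. no
  noise suppression — the method's value comes from ≥2 replicates, and
  ≥3 is markedly better in practice.
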