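---
title: "Methods: promoter bivalency calling, differential marking, state dynamics, and meta-programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter bivalency calling, differential marking, state dynamics, and meta-programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivalstate)
```

# Scope and model

`bivalstate` analyses promoter chromatin bivalency — the co-occurrence of the
active H3K4me3 and repressive H3K27me3 marks at the same promoter, which
poises genes between activation and silencing. The package covers five
connected analyses:

1. **Bona fide bivalent calling.** A gene's promoter window (TSS ± 1 kb by
   default, strand-aware) is tested for occupancy by H3K4me3 and H3K27me3
   peaks from *separate* ChIP-seq and by peaks from a *sequential*
   (re-ChIP, H3K27me3→H3K4me3) experiment. Separate ChIP can call a promoter
   "bivalent" when the two marks come from different cell subpopulations;
   sequential ChIP demonstrates co-occurrence on the same chromatin
   fragments. A gene is *bona fide* bivalent only when both assays agree
   (gene-level intersection; a promoter with several qualifying peaks counts
   once).
2. **Differential marking.** Promoter mark intensities from two conditions
   are placed on a common scale by an M-A linear rescaling fitted on commonly
   occupied promoters, and each gene's normalized intensity pair is tested
   with an exact conditional count test. A change is called at `p < 0.05`
   together with `|log2FC| >= 0.58` (the fold-change boundary inclusive, the
   p boundary strict).
3. **Chromatin bivalency states (CBS).** Bivalent promoters are classified
   by the ratio `r = (k4 + c) / (k27 + c)`: cluster I (H3K4me3-high,
   `r >= 1.5`), cluster II (H3K27me3-high, `1/r >= 1.5`), cluster III
   (equal). Transitions between two conditions form an alluvial-ready
   contingency table; resolution switches (II→I, III→I) are coupled to
   expression change, and mark change is correlated with expression change
   (Pearson).
4. **Factor co-occupancy.** The fraction of bivalent promoters carrying a
   peak of a transcription factor or chromatin regulator.
5. **Meta-programs.** Per-sample NMF of non-negative expression matrices over
   a sweep of ranks (k = 4..9), each factor summarized by its top-90 genes;
   programs recurring across ranks and samples are clustered by Jaccard
   similarity into consensus meta-programs.

# Coordinate and interval conventions

All file formats are BED-native 0-based half-open; internally intervals are
`GRanges` objects, with the conversion confined to the readers and writers.
Overlap is "any ≥ 1 bp": a peak ending exactly at a promoter start never
overlaps it. Promoter windows are clamped at position 0 rather than dropped
so that gene universes stay aligned across marks. One TSS per gene is
required; collapsing multi-TSS genes is upstream of this package.

Per-promoter "intensity" is deliberately abstract — any non-negative
peak-height summary (summit pileup, mean coverage, area) is accepted, since
different pipelines export different summaries. When several peaks overlap
one promoter, the maximum score is used as the conservative single-number
summary.

# The exact conditional count test

Under the null, the second count given the first follows
`P(y | x) = (x + y)! / (x! y! 2^(x + y + 1))`, which is the negative binomial
`NB(size = x + 1, prob = 1/2)`; tails are computed through `pnbinom`
(log-space internally, exact at large counts). The two-sided p-value doubles
the smaller tail and caps at 1.

One subtlety is orientation: conditioning on sample 1 versus sample 2 gives
different tail sums at small counts (e.g. the pair (1, 0) versus (0, 1)), so
the naive construction is not exchangeable in the two samples. `bivalstate`
therefore orders each pair and conditions on the **larger** count. This makes
`p(x1, x2) == p(x2, x1)` identically — the direction of a change is carried
by the sign of the fold-change, not by the p-value — and coincides with the
naive construction whenever `x1 >= x2`. Empirically the test is well
calibrated on equal-mean Poisson pairs (type-I error ≈ 0.05 at nominal 0.05
for means in 20–100; the test suite checks the 0.03–0.07 band).

Normalized intensities are rounded to integers for the test; the M/A
pseudocount defaults to 1 (0 is allowed when all intensities are positive).
No multiple-testing correction is applied by default, matching a raw-p
analysis; a Benjamini–Hochberg flag is available as a clearly optional
extension. The normalization fit is OLS with one outlier-removal pass
(`|residual| > 3·MAD`), a simple approximation to a robust fit that keeps the
estimator fully specified.

# The synthetic-data generator

The generator defines the conditions under which the package validates
itself; it emulates promoter-level structure, not reads or fragments.

* **States and counts.** Each gene gets one of five states per condition —
  the three bivalent states plus active (H3K4me3 only) and silent (neither).
  Default fractions: 10% / 12% / 8% bivalent (30% total), 35% active, 35%
  silent. Counts follow largest-remainder rounding, so planted totals are
  exact.
* **Intensities.** `x_mark = mu_mark(state) · exp(eps)` with
  `eps ~ N(0, sigma²)` drawn **once per gene and condition and shared by the
  two marks**: it models locus-level effects (copy number, accessibility,
  mappability, IP efficiency at that promoter) that scale both marks
  together. Mark contrast is carried by the state means —
  (8, 2), (2, 8), (5, 5), (8, 0.5), (0.5, 0.5) for
  (K4-high, K27-high, equal, active, silent) — chosen so the 1.5-fold
  classification rule is unambiguous at `sigma <= 0.3`. Because the shared
  factor cancels in the intensity ratio, classification errors at moderate
  noise come almost entirely from peak-emission dropouts, which is why CBS
  recovery stays above 95% at `sigma = 0.3` while remaining below 100%.
* **Peaks.** A separate-ChIP peak is emitted when the mark's intensity
  exceeds twice the silent-state mean; sequential peaks are emitted exactly
  at planted-bivalent promoters. At `sigma = 0` this makes the bona fide
  caller recover the planted set perfectly — the oracle identity the test
  suite asserts.
* **Switches and expression.** A configurable fraction of genes moves from
  cluster II or III to cluster I between conditions. Switch genes receive a
  positive expression log2FC with probability `coupling_prob` (default
  0.85), magnitude `Gamma(shape = 2, scale = 0.75)` (mean 1.5 log2 units);
  non-switch genes draw `N(0, 1)`.
* **Program matrices.** Multi-sample non-negative matrices are baseline
  Gamma noise plus additive Gamma blocks on (program genes × a random ~35%
  cell subset) for each program assigned to a sample. The default universe
  is 1000 genes with five disjoint 90-gene programs and a 550-gene
  background: the background pool is kept large so that two
  background-dominated factors overlap by chance at Jaccard ≈ 0.09, well
  below the clustering threshold — the regime of a real transcriptome, where
  non-program genes vastly outnumber program genes.

What the generator does **not** model: read-level noise, fragment-length and
GC effects, peak-caller artifacts, inter-replicate variance, single-cell
depth variation, and doublets. Passing tests demonstrate the correctness of
the algorithms under the stated statistical structure, not performance on
any particular real dataset.

# Meta-program discovery choices

NMF uses a deterministic NNDSVD initialization (positive/negative parts of
the truncated SVD; structural zeros filled with a small seeded perturbation
so multiplicative updates cannot lock them) and Frobenius multiplicative
updates, at most 500 iterations with a relative-objective stop. Determinism
given the seed was prioritized over restarts: meta-program calls should be
reproducible run-to-run.

Programs are the top-90 genes of each factor. Clustering is greedy: within a
sample, an instance must recur at another rank with Jaccard ≥ 0.7 to count
as robust; across samples, partnership needs Jaccard ≥ 0.2; clusters are
seeded from the instance with the most cross-sample partners, absorb all its
partners, and must span ≥ 2 samples. The two thresholds deliberately differ:
within one sample the same underlying program reappears across ranks almost
verbatim, so a strict threshold screens out rank-specific merged factors
(inevitable when the rank is below the number of real programs) that would
otherwise bridge two programs into one cluster, while cross-sample
recurrence of the same biology is looser. Consensus gene sets are the
top-90 genes by membership frequency, ties broken by summed normalized
loading, then lexicographically — every tie-break is deterministic.
Expression is `log1p`-transformed and clipped per gene at the 99.9th
quantile before factorization; no centering, since NMF requires
non-negativity.

# Problem sizes and numerical choices

The validation suite runs at desk scale by design: genomes of 300–2000 genes
for calling/classification oracles, 5000 genes × 10 replicates for null
calibration, 8000-gene genomes × 20 seeds for the switch-coupling
concentration check, and 8 samples × 1000 genes × 150 cells for meta-program
recovery. These sizes give the binomial/concentration bounds the tests
assert (e.g. ±0.03 around a planted 0.85 coupling at ≥ 2000 switch genes)
while keeping the full suite under a minute apart from the NMF block.

Degenerate inputs are handled explicitly: empty BED files are valid (zero
peaks); an empty bivalent set makes co-occupancy and switch fractions
errors rather than NaN; normalization requires ≥ 10 common promoters and
non-constant A; correlation requires ≥ 3 pairs and non-zero variance;
`classify_cbs` uses a 0.5 pseudocount so zero intensities among bivalent
calls stay classifiable, and a ratio of exactly 1.5 goes to the high
cluster on either side (the two high conditions are mutually exclusive for
any threshold > 1).

# Known limitations

* The M-A/exact-test model treats intensities as count-like; replicate-aware
  variance modelling (as in hierarchical extensions of the approach) is out
  of scope.
* Bivalency calling is binary occupancy within a fixed window; no minimum
  overlap width, no IgG/re-ChIP background subtraction.
* The k-means view of CBS clusters is a diagnostic cross-check only; the
  threshold rule is the classifier.
* Meta-program counts depend on the recurrence and Jaccard thresholds, which
  are config-exposed; absolute counts from real cohorts are not reproduced
  here.
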