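---
title: "Phenotype signatures and exhaustive pairwise GSEA: methods and design"
author: "phenoGSEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype signatures and exhaustive pairwise GSEA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoGSEA)
```

# Scope

phenoGSEA does two things.  First, it extracts *molecular signatures*: for a
contrast between test and reference phenotype classes, the genes whose
expression is higher in the test classes under one of five statistics, with
sample-permutation p-values and false discovery rate (FDR) control.  Second,
it runs the weighted Kolmogorov–Smirnov gene set enrichment statistic over
*every* pairwise comparison of phenotype classes in a dataset, corrects the
significance of all enrichments jointly, and renders the grid as a bubble
matrix.  This vignette records the statistical model, the defaults and why
they were chosen, the numerical conventions, and what the synthetic fixtures
do and do not establish about real data.

# Signature extraction

## The five statistics

For a contrast with pooled test samples $T$ and pooled reference samples $R$
on linear-scale intensities:

* **min-vs-max**: $\min(T) / \max(R)$.  The most stringent statistic and the
  only one without a permutation p-value: a gene passes the fold threshold
  only if its *worst* test replicate exceeds the *best* reference replicate
  by that factor, which is already a strong guarantee at low replicate
  counts.
* **mean-ratio**: $\bar{T} / \bar{R}$, the linear fold change.
* **min-pairwise-mean-ratio**: $\min_{i,j} \bar{T_i} / \bar{R_j}$ over all
  (test class $i$, reference class $j$) pairs.  Because the minimum over
  pairs can never exceed the pooled ratio when replicate counts are equal
  (the minimum numerator is at most the average, the maximum denominator at
  least the average), the pairwise signature is a subset of the pooled one
  at any common threshold — the suite asserts this "more stringent" relation
  on equal-replicate fixtures.
* **snr**: $(\bar{T} - \bar{R}) / (s_T + s_R)$ with sample standard
  deviations.
* **min-pairwise-snr**: the minimum per-pair SNR over class pairs.

Ratio statistics require strictly positive intensities and raise a
validation error naming the offending gene and sample otherwise; a
`log2Input` flag at load time exponentiates log2 data so that fold
thresholds such as "> 2x" keep their linear-scale meaning.

**SNR floor.** Standard deviations are floored at
$\max(s,\; 0.2\,|\bar{x}|,\; 0.2\,\delta)$, where $\delta$ is the smallest
positive value in the matrix.  This is the GSEA-ecosystem convention that
prevents zero denominators for constant genes and keeps near-constant genes
from dominating the ranking; the $0.2\,\delta$ term covers means near zero,
where a relative floor vanishes.

## Permutation p-values and the never-zero correction

P-values come from permuting the sample-to-class assignment restricted to
the union of test and reference samples, preserving every class's replicate
count.  With $b$ of $m$ permuted scores at least as large as the observed
score, $p = (b+1)/(m+1)$.  This "never-zero" estimator counts the observed
assignment as one realization of its own null, so $p \ge 1/(m+1) > 0$ — an
essential property, because step-up FDR procedures are applied downstream
and a spurious $p = 0$ would survive any correction.

When the number of distinct assignments is at most `nPerm`, the null is
enumerated exhaustively and $p$ is exact rather than Monte Carlo.  For the
pooled statistics (`mean-ratio`, `snr`) the score depends only on which
samples are labelled test, so distinct assignments are counted up to the
induced test/reference split: a triplicate class against 18 reference
samples has $\binom{21}{3} = 1330$ splits, giving an exact p-value floor of
$1/1330 \approx 7.5 \times 10^{-4}$.  For the pairwise statistics the full
label multiset is enumerated.  Sampled permutations are drawn uniformly and
may repeat; the estimator remains valid.

The p-value is one-sided (test above reference) because signatures are
defined as genes *more highly expressed* in the test classes.

Nulls are **gene-wise**: each gene's observed score is compared to its own
permuted scores.  A pooled-across-genes null (`nullPool = "pooled"`) is
available; it gives a much finer p-value grid but replaces the per-gene rank
test with a magnitude comparison, which penalizes true positives whose fold
change is modest, and measurement on planted fixtures showed materially
lower sensitivity.  Gene-wise is therefore the default.

## FDR control, and a floor the user should know about

`adjustPvalues()` applies Benjamini–Hochberg (independence / positive
dependence) or Benjamini–Yekutieli (arbitrary dependence,
$c(m) = \sum_{k \le m} 1/k$ inflation).  BY is the package default for
signature extraction because permutation scores of genes measured on the
same few samples are correlated.

At very small replicate counts, however, BY at strict thresholds is
mathematically unreachable with gene-wise nulls.  With the exhaustive floor
$p_{\min} = 1/1330$ of a triplicate class against six other triplicate
classes, 2000 genes of which roughly 50 are true discoveries, the best
possible BY-adjusted value is
$p_{\min} \cdot (2000/50) \cdot c(2000) \approx 0.25$.  No parameter
choice changes this: it is a property of the design size.  The
planted-recovery checks in the acceptance suite therefore use BH, for which
the same floor adjusts to $\approx 0.03 < 0.05$.  Users extracting
signatures from triplicate designs should do the same arithmetic before
choosing a threshold; with five or more replicates per class the exhaustive
null is fine enough that the distinction stops mattering.

Retention thresholds are strict (`score > fold`, `fdr < threshold`), reading
"> 2x" literally; a gene scoring exactly 2.0 is excluded.  Rows are sorted
by score descending with ties kept in dataset row order, so output is
deterministic.  An empty signature is legal — the negative-control class of
the default fixture produces one — and is returned with a warning rather
than an error.

# The enrichment engine

## Ranking and the running sum

For a class pair, all genes are ranked by the signal-to-noise ratio
(left minus right, same sd floor) descending; ties keep dataset row order.
For a gene set with $K$ members present in the list of $N$ genes, the
running sum gains $|m_i|^w / N_R$ at each member ($N_R$ the total hit
weight) and loses $1/(N-K)$ at each non-member; the enrichment score (ES)
is the running-sum value of largest magnitude.  With $w = 0$ this is the
classic Kolmogorov–Smirnov statistic; the default $w = 1$ weights hits by
differential expression, the conventional choice.  The implementation
evaluates only the $2K$ candidate extrema (the value at each hit and just
before each hit), which is algebraically identical to walking all $N$
positions; the suite checks it against a dense oracle, against exhaustive
enumeration of all member placements on small lists, and against an
independent implementation (fgsea).

**Tie-break.** If the maximum positive and negative deviations have exactly
equal magnitude, the one occurring earlier in the ranked list is taken.
Exact ties essentially occur only with $w = 0$ on rational grids; at
floating-point resolution two extrema can tie within rounding, in which case
either sign is statistically defensible and the tests compare magnitudes.

Set-size filtering (defaults 15–500 members present in the dataset) skips a
set with a distinguishable flag instead of failing; members absent from the
dataset are dropped silently and reported via `setSizeUsed`.  Identifier
matching is case-insensitive by default, since gene symbol capitalization
conventions differ across species and platforms.

## Nulls, NES, and class-swap symmetry

Geneset-permutation nulls draw random same-size member sets; sample
permutation shuffles the pair's class labels and re-ranks.  Sample
permutation requires at least 5 replicates per class (overridable): below
that the distinct shuffles are too few for a usable null, and triplicate
designs should use geneset permutation.

The normalized enrichment score divides ES by the mean magnitude of
same-sign null values; null values are normalized the same way, so the
normalized null has same-sign mean 1 by construction.  A cell whose null
contains no same-sign values gets an undefined-NES flag and the conservative
$p = 1/(m+1)$ fallback.

Null member sets are drawn as *gene identities* (through an alphabetical
index), not ranked positions.  Swapping a comparison's classes reverses the
ranked list and negates every metric; with identity-based draws the same
seed then reproduces the same null sets, whose scores negate exactly, so
observed ES and NES negate exactly too.  This is what lets mirrored directed
views be obtained by sign flip instead of recomputation.

# The map: pooling and map-wide FDR

`runBubbleMap()` computes each *unordered* pair once — GSEA statistics are
antisymmetric, so computing both orientations would double the runtime and,
worse, duplicate every test in the FDR family.  Directed views for display
carry sign-flipped ES/NES and identical p/FDR.

The map-wide p-value compares each cell's NES to the **normalized null NES
values of all cells pooled by sign**: raw ES distributions depend on set
size, so pooling is only coherent after normalization.  With $b$ same-sign
pooled values of magnitude at least $|NES|$ out of $m$, $p = (b+1)/(m+1)$,
the same never-zero estimator as in signature extraction.  The BY step-up
then runs once over the family of all unique cells (gene sets × unordered
pairs), so every bubble's FDR is comparable to every other's.  A fully null
map is the calibration check: the acceptance suite simulates 20 null maps
(6 classes × 3 replicates, 40 random sets, 500 permutations) and verifies
that the mean fraction of cells with FDR < 0.05 stays at or below 0.05 — BY
under these conditions is in fact strongly conservative.

Geneset-mode nulls depend only on the comparison and the set size, so they
are seeded from a sub-seed derived from `(seed, pair, size)` and shared
between same-size sets.  Two consequences: same-size cells in a pair share a
null (a pure memoization, not an approximation), and adding or removing a
gene set leaves every other cell's ES and NES bit-identical.  Removing a set
does *not* monotonically shrink all FDR values, though: it also removes that
set's contribution to the pooled null, which perturbs extreme cells'
p-values by roughly $m/(m-1)$, and that can outweigh the smaller BY family.
The suite asserts the two components separately — invariance of the
remaining cells' statistics, and the family-size monotonicity of the BY
step-up at fixed p-values.

Filtering and reordering a view (`filterGrid()`) never recomputes anything:
the multiple-testing family is fixed when the map is run, so a filtered
figure shows the same numbers as the full one.

# Visualization conventions

Bubble area is proportional to $|NES|$ (radius $\propto \sqrt{|NES|}$), fill
color is the enriched class's color, and fill opacity maps significance as
$\alpha = \mathrm{clamp}(\log_{10} f / \log_{10} f_{\mathrm{sat}},\,
0.15,\, 1)$ with saturation at $f_{\mathrm{sat}} = 10^{-3}$.  Cells above
the display threshold (default 0.25, the conventional discovery cut-off;
0.10 is the stricter confirmation-study choice) are drawn as empty circles
of the same area, so non-significance hides strength of effect but not its
direction or size.  The opacity law, the 5-color heatmap palette and its z
cut-points (−1.5, −0.5, 0.5, 1.5) are package conventions, configurable and
not anchored to any published color ramp.  SVG output is generated with
fixed-precision formatting and is byte-stable; heatmap rows are standardized
per gene, with constant genes mapping to the middle color.

# The synthetic generator

`simulateDataset()` draws
$\log_2 x = \mathrm{baseline} + \mathrm{effect} \cdot
[\text{gene planted for the sample's class}] + \mathcal{N}(0, \sigma)$,
a log-normal intensity model with additive class effects on the log scale —
the structure of RMA-normalized microarray data.  The default fixture
mirrors a seven-phenotype, triplicate immune-cell study: 2000 genes, six
planted blocks of 50 genes at 2.0 log2 (4-fold) effect, noise sd 0.5 log2,
baseline 7 log2, and a seventh class with no planted block as a negative
control.  `simulateGeneSets()` builds one fingerprint set per planted block
plus twice as many random padding sets (names carry the filterable
`fingerprint` infix); padding keeps the conservative map-wide correction
honest when most sets of interest are truly enriched.

What the generator does **not** emulate: probe- and platform-level effects,
batch structure, correlated gene modules beyond the planted blocks,
mean-variance trends, or cross-species ortholog mapping.  Passing tests
establish the statistical machinery — exact permutation nulls, FDR
calibration, antisymmetry, recovery of planted effects at the stated sizes —
not robustness to those real-data complications.

On this fixture the acceptance script reports fingerprint recovery 1.0
(every planted fingerprint positively enriched at map FDR < 0.10 in every
own-class comparison) and planted-gene sensitivity of roughly 92% for
mean-ratio > 2x at BH FDR < 0.05.  The missing ~8% are genes whose identity
split is beaten by at least one of the 1329 alternative splits
($p = 2/1330$, adjusted just above 0.05) — a floor effect of the triplicate
design, not of the implementation.

# Problem sizes and determinism

The test suite runs at deliberately desk-sized scales: null-map calibration
uses 20 repeats of a 6-class × 3-replicate, 40-set, 500-permutation map;
uniformity checks use 5000 genes at 199 permutations; recovery checks use
the default fixture at 1000–2000 permutations.  A published case study of
comparable shape (68 sets, 21 arrays, 7 phenotypes) would conventionally use
5000 geneset permutations; all counts here are arguments, not constants.
Every stochastic path takes an integer seed, sub-seeds are derived
deterministically per stream, and identical inputs plus seeds give
bit-identical signatures, grids and SVG bytes.

# Known limitations

* No leading-edge subset reporting or per-comparison enrichment plots.
* Ranking metrics are SNR and mean difference; no median-based or
  moderated-variance metrics.
* The sample-permutation mode re-ranks per permutation and is markedly
  slower than geneset mode; it is intended for designs with ≥ 5 replicates.
* GCT support is deliberately strict (`#1.2`, no NA cells); probe-to-symbol
  collapsing and CHIP files are out of scope.
* BY-adjusted signature FDR at triplicate scale is floor-limited (see
  above); the package surfaces the exact floor via the `nPermUsed`
  attribute so users can check attainability.
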