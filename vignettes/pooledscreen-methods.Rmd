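---
title: "Methods: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pooledscreen)
```

This vignette documents the statistical models, numerical conventions, and
design decisions behind `pooledscreen`. The package implements the
computational stages of a pooled shRNA dropout screen performed in a
PU.1-dosage myeloid leukemia model system (preleukemic and leukemic cell
lines versus a wild-type-like control), together with two companion
analyses: gene-signature scoring of single-cell expression along a
neutrophil differentiation trajectory, and a region-set enrichment analysis
that quantifies the redistribution of a transcription factor's (RUNX1)
chromatin binding relative to co-binding with PU.1.

## 1. The screen model

A pooled dropout screen transduces a library of barcoded shRNAs into cells,
harvests an input sample shortly after transduction, grows the population
for a fixed number of doublings `G` (default 10), and sequences the barcodes
of both samples. If knocking down a gene slows growth, its shRNAs' barcodes
deplete. The library design mirrored by the default `sim_config()` is: 344
target genes with 5 shRNAs each, 30 killing-control shRNAs against three
universally essential genes (10 barcodes each, treated as three
pseudo-genes), and 45 non-targeting controls (NTCs), screened in three cell
lines with three replicates each.

### Growth and sequencing model

Each clone carries a fitness effect `f` in `[-1, 0]` (0 neutral, -1 no
growth). Over `G` doublings its abundance is multiplied by `2^(G(1+f))`, so
the expected log2 fold change versus a neutral clone is `G*f`. Initial clone
abundances are log-normal (`abundance_sigma`, default 1.0 on the natural-log
scale), mimicking uneven library representation; the paper gives no
abundance model, and this choice reproduces the broad per-shRNA logFC spread
seen in real screens. Every sequenced sample is a multinomial draw of
exactly `depth` reads from the (renormalized) abundances, so column sums are
exact by construction.

**Replicate overdispersion (a deliberate deviation).** A pure multinomial
model makes a shRNA's logFC noise scale as `count^-1/2`. Essential-gene
shRNAs deplete by `~2^6` at the default effect, so their fold-change noise
is ~5 times the NTC noise *at any sequencing depth*. An NTC-anchored
empirical cutoff (Section 4) then badly underestimates the null spread of
depleted shRNAs, and essential genes with no true line difference are
classified "preferentially inhibited" at rates far above the nominal
quantile. Real screens do not look like this: replicate-to-replicate
variation (biology, transduction, PCR) dominates and affects all shRNAs
comparably. The generator therefore applies per-sample, per-clone
log-normal jitter of `replicate_sigma = 0.5` (log2 units) to abundances
before each multinomial draw. Setting `replicate_sigma = 0` recovers the
pure multinomial model. With the default, the NTC-based procedures are
calibrated (false preferential classification ~1% at the 5% NTC quantile).

### Ground truth

`generate_screen_truth()` plants one shared set of essential genes
(`n_essential`, default half the targets; the real screen found roughly half
of its signature-3 library essential). For each essential gene only
`n_effective` of its shRNAs (default 4/5) carry the effect — one shRNA is a
dud, which makes the ≥3/5 support rule meaningful. Preferential genes
(`n_preferential`) are essential genes given an extra line-specific
depletion `delta` (default -1, clamped so the total stays ≥ -1) in one
non-reference line, assigned in rotation. Killing controls carry
`killing_effect = -0.9` everywhere; NTCs are exactly neutral. The truth
object records per-gene essential flags (≥3 shRNAs at or below the effect
threshold) used by the recovery tests. Fully line-disjoint essential sets
are not modeled; no test scenario requires them.

## 2. Normalization and fold changes

Counts are normalized to the NTCs: the per-sample factor is the NTC count
median (robust to a few outlier controls; the total is available via
`stat = "total"`) divided by the geometric mean of those medians, so factors
have geometric mean 1 and dividing by them equalizes NTC medians across
samples. Per-shRNA log2 fold changes compare each final sample with its
replicate-matched input (falling back to a line's single input), with a
pseudocount of 0.5 applied after size-factor scaling. No precision
(voom-style) weighting is applied: downstream aggregation is rank-based and
the DFC stage works on differences of means, where weights are second-order;
the exact weighting recipe used upstream of the original analysis is not
specified for barcode counts.

### Quantile normalization and ties

`quantile_normalize()` replaces each column by the mean of the across-column
order statistics, assigned by within-column rank, making the sorted values
of every column identical. Ties required a decision. Averaging the
reference values across a tied run keeps equal inputs equal, but puts the
averaged value *outside* the common reference distribution; columns with
different tie patterns then no longer share their sorted values, and a
second pass moves values again — quantile normalization stops being
idempotent, and exact ties are common in discrete count data. The default
(`ties = "split"`) instead hands tied entries distinct consecutive reference
values in row order: every output column is then an exact permutation of the
reference, the "identical sorted columns" contract holds exactly, and the
operation is exactly idempotent. The cost is that tied inputs can receive
(adjacent, nearly equal) different outputs, with a deterministic row-order
dependence. `ties = "average"` provides the averaging convention for
comparison.

## 3. Essentiality: NTC null, alpha-RRA, permutation FDR

Per-shRNA significance uses the empirical NTC null on replicate-mean
quantile-normalized logFC: `p = (#{NTC <= x} + 1) / (N_ntc + 1)` (one-sided,
depletion). This anchors inference on the same controls as normalization and
only the ordering matters downstream. Normalized ranks `r = rank/N` are
computed over target shRNAs, ties broken by logFC then id for
reproducibility.

The gene score is the alpha-RRA statistic: with ranks
`r_1 <= ... <= r_n` and `j` shRNAs selected at `p < alpha` (default
`alpha = 0.25`, the aggregation tool's conventional default),
`rho = min_{k<=j} pbeta(r_k; k, n-k+1)` — the tail probability of the k-th
order statistic of `n` uniforms — and `rho = 1` when nothing is selected.

Significance comes from permuting shRNA-to-gene labels (preserving per-gene
shRNA counts), pooling null `rho` values across genes with equal shRNA
count: `p_perm = (#{null <= observed} + 1) / (n_null + 1)`, followed by
Benjamini–Hochberg across target genes. A gene is called essential when it
(a) is depleted on average, (b) has FDR < 0.01, and (c) has ≥3 supporting
shRNAs (`p < alpha` and depleted). Killing pseudo-genes and NTCs are
excluded by role.

Two calibration notes established by the tests:

* On a fully null screen, `p_perm` is uniform below ~0.7 (pointwise within
  binomial error), but alpha-RRA has an atom at `rho = 1` (a null gene has
  no selected shRNA with probability `(1-alpha)^n`, ~24% at defaults), so a
  global KS test against U(0,1) always rejects. Calibration is therefore
  asserted pointwise at several thresholds, and the operative guarantee —
  ≤2% of null genes at FDR < 0.01 — holds with margin (measured 0%).
* Under strong signal the permutation null is contaminated by the real
  effects, making `p_perm` conservative; with 40 planted essential genes in
  the 344-gene design, sensitivity at FDR < 0.01 averages 0.94 over 20
  simulations.

## 4. Differential essentiality (DFC)

For two lines A and B, the per-shRNA DFC is the difference of
replicate-mean qn-logFC (A minus B); negative means preferential growth
inhibition in A. Replicate averaging precedes subtraction because the
screen's inputs are per-line, not replicate-paired across lines. The
empirical cutoff is a lower quantile (default `q = 0.05`, type-7
linear-interpolation convention, recorded on the result) of the NTC DFCs —
the quantile itself is not stated in the source analysis and is exposed as a
parameter. A gene is classified preferential in A when it is essential in A
and at least 3 of its shRNAs fall below the cutoff; support is counted on
per-shRNA DFCs (not the gene mean), matching the ≥3-shRNA wording and
per-shRNA heatmap logic of the original analysis. Classification is
invariant to adding a constant to all logFC of both lines, and the DFC table
is exactly antisymmetric under swapping lines.

## 5. Single-cell signature scoring

The expression container is a genes × cells count matrix (dense or sparse)
plus a cell annotation (cluster, genotype, optional pseudotime; pseudotime
is consumed, never estimated). Operations:

* `percent_expressing_per_cell()` — a gene is "expressed" when its raw count
  is non-zero; the statistic is the percentage of signature genes expressed.
* `signature_mean_score()` — raw counts are normalized to counts-per-10k
  and `log1p`-transformed (skipped for already-normalized input; auto-detect
  treats non-negative integer matrices as raw), then each gene is z-scored
  across cells (zero-variance genes contribute 0) and the score is the mean
  over signature genes. This is deliberately the simplest defensible module
  score — no control-gene-bin correction — because the original scoring
  method is unstated and a transparent convention is easier to test; the
  same convention stands in for the lineage progenitor scores
  (`lineage_scores()` is two signature scores side by side). One caveat the
  tests quantify: because scores are computed after per-cell depth
  normalization, planting a large shift in a signature that is a sizable
  fraction of the gene universe drags the scores of other signatures in the
  opposite direction (compositional coupling); with realistic universe sizes
  the coupling is negligible.
* `aggregate_by_cluster()` — box-plot summaries (median, type-7 quartiles,
  whiskers at the most extreme points within 1.5 IQR) per cluster/genotype.
* `pseudotime_profile()` — mean score in equal-width bins over the pooled
  pseudotime range, per genotype; empty bins are reported as missing rather
  than interpolated.

The expression generator plants cluster-level baseline trends (stem
signature high early, neutrophil signature rising along the C1→C2→C3
trajectory, monocytic signature concentrated in the off-trajectory cluster)
and genotype effects defaulting to the biology being emulated: pro-survival
and neutrophil signatures up, monocytic signature down in the PU.1-low
genotype. Counts are Poisson around group-level profiles scaled to a common
library size; the default 4000 cells is a desk-scale stand-in for the
~10,000-cell experiment. What a green recovery test establishes is that the
scoring pipeline detects planted shifts of the stated size under Poisson
noise — not that the generator reproduces real single-cell features such as
batch structure, doublets, or gene-gene correlation.

## 6. Region-set GSEA

Coordinates are BED-convention 0-based half-open throughout; TSS tables
supplied 1-based are converted on read. A peak is assigned to a gene when it
overlaps the window `[tss - w, tss + w]` (inclusive of the TSS base) by at
least one base, `w = 50` kb by default; multi-assignment is kept. Overlap
uses `GenomicRanges` internally and is verified against quadratic
brute-force oracles in the tests. Signature region sets are the TF peaks
assigned to a signature's TSS windows, by default *excluding* peaks cobound
by the partner TF — the main-text reading of the source analysis; the
figure-legend reading (require co-binding) is available via
`exclude_cobound = FALSE` plus subsetting, or the CLI's `--require-cobound`.

`preranked_gsea()` ranks regions by decreasing statistic (ties broken by id)
and computes the weighted running-sum enrichment score: hits add
`|stat|^weight` (normalized over hits), misses subtract `1/(N - N_hits)`;
the ES is the signed maximum deviation, with exact ties resolved to the
positive extreme (a `1e-9`-relative tolerance absorbs float noise so the
O(k log k) sweep and the explicit running sum agree on knife-edge cases).
The null is drawn from random same-size region sets — the appropriate
permutation unit when the ranking statistic has no replicate-level input —
with `NES = ES / mean(|null ES| of matching sign)` and a same-sign
permutation p-value. FDRs are Benjamini–Hochberg over the tested sets
(fgsea-style) rather than the classic pooled-NES construction. When an
external per-region statistic is absent, `simple_region_logfc()` provides a
plain ranking statistic: library-size-normalized condition means compared as
`log2((mean_A + 0.5) / (mean_B + 0.5))`; model-based differential-binding
fitting is out of scope. Note the pseudocount makes the statistic invariant
to a uniform depth change only up to `O(pc/count)`.

The genomic generator lays genes on a grid with spacing larger than twice
the TSS window, so window membership is unambiguous by construction, plants
partner co-binding as identical intervals with configurable probability, and
adds a location shift to the statistics of single-bound peaks near one
signature's TSSs. The planted-shift recovery test asserts the shifted
signature attains the top NES at FDR < 0.05.

## 7. Numerical and degenerate-input conventions

* All quantiles use R's type-7 (linear interpolation) convention, recorded
  on outputs where it matters.
* Empirical p-values always use the `(count + 1)/(n + 1)` form, so they are
  never zero.
* Seeds: every stochastic function takes or derives an explicit seed, uses
  it via an internal `with_seed()` that restores the caller's RNG state, and
  is byte-reproducible; generators derive sub-seeds by small fixed offsets.
* Degenerate inputs: single-column matrices pass through quantile
  normalization; a single sample gets size factor 1; empty signatures,
  all-zero NTCs, too-few controls (<10), invalid alpha/quantiles, unpaired
  final samples, and out-of-bounds peaks are errors naming the offender;
  empty region sets and empty clusters are dropped with warnings.

## 8. Known limitations

* No count-level variance model (no negative-binomial GLM) and no batch
  correction; the NTC empirical null subsumes these at the ranking level.
* The permutation FDR is conservative under dense true signal (null
  contamination), which is the standard behavior of label permutation.
* The synthetic screen has no transduction/MOI or selection model and no
  sequence-level errors (library reports state no transduction bias for the
  emulated design).
* Signature scores are global z-means; they are comparable within a dataset
  but not across datasets, and are subject to the compositional caveat of
  Section 5.
* Region-set inference treats regions as exchangeable; correlated peaks
  (e.g. the same locus in two sets) are allowed and not corrected for.
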