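---
title: "Methods: single-cell enhancer, super-enhancer and marker calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell enhancer, super-enhancer and marker calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scregulon calls tissue/cell-type-specific regulatory elements from
scATAC-seq kept in count form. This vignette describes the models and
procedures, the parameters that matter, the choices made where the design
was genuinely open, and what the simulation-based tests do and do not
demonstrate.

All coordinates are 0-based half-open throughout; GTF input (1-based
inclusive) is converted on read and back on write.

## Preprocessing

Counts are never binarized: binarizing a scATAC matrix discards
quantitative regulatory information, so every downstream statistic works
on raw fragment counts. Three quality filters are applied, in a fixed
order (cells first, then peaks, then the cell-type split):

* cells with fewer than 200 peaks carrying a nonzero count are removed —
  "peaks per cell" counts nonzero peaks, not total fragments, and the
  threshold is strict, so exactly 200 survives;
* peaks nonzero in fewer than 10 cells, or on uncommon chromosomes, are
  removed. "Uncommon" is a configurable regular-expression list
  defaulting to mitochondrial contigs (`chrM`/`chrMT`/`MT`) plus
  scaffold/random/alt/unplaced names, since only the mitochondrial case
  is canonical; the support filter and the chromosome filter commute and
  the tests assert it;
* cell types with fewer than 100 cells are dropped, and within each
  surviving sub-matrix all-zero peaks are removed (these per-population
  re-filters run after the split, because that is where an all-zero row
  becomes well defined).

All filters are idempotent; a `qc_report()` records every step.

## Consensus (typical) enhancers

Each cell's peak profile is treated as an independent, noisy replicate of
its population's accessibility landscape. Cell quality is scored by
similarity to the rest of the population with the Tanimoto coefficient

$$T(A,B)=\frac{A\cdot B}{\lVert A\rVert^2+\lVert B\rVert^2-A\cdot B},$$

which extends the Jaccard index to counts (on binary vectors the two are
identical — a property test asserts this on 1000 random pairs). The
weight of cell $t$ is its off-diagonal row sum of the Tanimoto matrix,
normalized by the sum over all ordered pairs of distinct cells. The
index bounds of that denominator admit a reading in which the excluded
pairs depend on $t$, but that breaks normalization; we sum over all
ordered pairs $i \ne k$, independent of $t$, so the weights are
nonnegative and sum to exactly 1 and combined scores are comparable
across cell types. The consensus score of peak $i$ is then
$S(i)=\sum_t \mathrm{count}_{t}(i)\,w_t$ — linear in the counts, with
"relative fragment count" taken as the raw count, consistent with the
count-based stance (an optional per-cell depth normalization is not
applied by default).

A peak is a typical enhancer iff it passes four criteria:

1. **support** — nonzero counts in at least one-third of cells,
   operationalized as `ceiling(m/3)` cells since "at least one-third" of
   an integer count;
2. **annotation** — no ≥1 bp overlap with promoter windows or exons.
   Promoter windows are strand-aware `[TSS−2000, TSS+100)`: 2 kb matches
   the promoter distance used for gene activity, and the +100 bp guards
   the TSS itself;
3. **shuffle null** — the combined score must strictly exceed the 95th
   percentile of null scores obtained by relocating every peak uniformly
   within its own chromosome (width preserved, overlaps among shuffled
   peaks allowed — the minimal reading of shuffling "across the entire
   DNA sequence"), re-counting fragments per cell, and re-weighting.
   20 replicates are pooled; the pooled-null variant was chosen over a
   per-peak matched null because it is stable at small replicate counts,
   and per-width matching is noted as an alternative. Without a fragment
   file this criterion is skipped and flagged `NA`;
4. **promoter co-accessibility** — best co-accessibility score to any
   promoter-overlapping site of at least 0.1.

## Co-accessibility

Counts are made continuous by TF-IDF:
$\ln\!\big(1+\tfrac{c_{ij}}{\mathrm{tot}_j}\cdot\tfrac{m}{m_i}\cdot 10^4\big)$,
followed by truncated SVD (LSI). Component 1 is depth-correlated by
convention and excluded; components 2–50 are retained. Component signs
are fixed (largest-magnitude loading positive) so the embedding is
deterministic; a dense SVD is used below 600 cells and a seeded
randomized solver above. A 2-D UMAP of the retained components
(single-threaded, seeded, hence reproducible) supports metacell
construction; `method = "lsi"` is a documented pass-through returning
LSI components 2–3 for fast deterministic runs.

Sparse counts are aggregated into overlapping metacells: the k nearest
neighbors of randomly ordered seed cells, greedily accepted unless a
candidate shares more than `max_overlap * k` members with an accepted
one. The function default k = 50 follows the established practice of
the co-accessibility tools this procedure mirrors; the pipeline default
is adaptive, `k = min(50, max(10, floor(m/10)))` with `max_overlap`
0.75, because covariance estimation needs tens of effective
observations, and at a few hundred cells a fixed k = 50 leaves too few
metacells for stable correlations. This choice was made from the sample
size arithmetic, not tuned on outcomes.

Within overlapping windows of width `2 * max_dist` (500 kb default
distance bound, a species-dependent config parameter), the correlation
matrix of depth-normalized metacell counts (ridge-shrunk by 1%) is fed
to a graphical lasso with an element-wise penalty
$\rho_{ij} = \text{penalty\_scale} \cdot d_{ij}/d_{\max}$, and
$\rho_{ij}$ large enough to force exact zeros beyond $d_{\max}$. The
solver is the standard blockwise coordinate-descent graphical lasso,
implemented in the package because the penalty must vary per element.
`penalty_scale = 1` makes the penalty interpretable on the correlation
scale: a pair at the full distance bound must beat a penalty of 1 (an
impossible correlation), a pair at 10% of the bound a penalty of 0.1,
so distance and evidence trade off linearly. The co-accessibility score
is the regularized partial correlation
$-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$. Pairs covered by several
windows keep the score of the window whose center is nearest the pair
midpoint — deterministic and simple; averaging is an alternative we
rejected to keep window effects legible. Non-converged windows are
skipped and reported, never silently averaged.

Enhancer–promoter links require exactly one side in a promoter window
and a score ≥ 0.1; promoter–promoter pairs are excluded, and the gene
label comes from the promoter side.

## Super-enhancers

Candidate enhancers (a narrowPeak/BED set; peak calling itself is
upstream of this package) are stitched per chromosome in one
left-to-right pass: merge while the gap to the running maximum end is at
most the stitch distance (12.5 kb human and mouse, 2 kb fly; presets in
`stitch_distance_preset()`). The total signal of a stitched region is
the sum of count fields of all ≥1 bp-overlapping fragments from the cell
type's barcodes — the discrete form of integrating the coverage signal
over the region; no control subtraction is applied because scATAC has no
input track. Duplicate collapsing is left to the count field. A fragment
spanning two regions counts once in each, which keeps regions
independent; the alternative (fractional assignment) would make scores
depend on neighboring regions. TSS exclusion before stitching is
available as an option but off by default.

Regions are ranked by signal ascending and both axes min-max scaled.
The consecutive-point slope formula with denominator $R_i - R_{i+1}$ is
sign-ambiguous for ascending ranks, so the "slope = 1" cutoff is
operationalized exactly as the lower tangent point of a slope-1 line on
the scaled curve: `argmin(scaled_y - scaled_x)`, ties to the largest
index (most stringent). An exhaustive oracle — try every anchor, check
all points lie on or above the anchored line — verifies this on 200
random curves in the tests. Classification is strict
(`signal > cutoff_signal`, so the tangent region itself is not super),
a flat curve yields zero super-enhancers, and the cutoff is invariant to
rescaling all signals. Finally, only super-enhancers intersecting (≥1
bp) at least one typical enhancer of the same cell type are retained.

## Gene activity and markers

Gene activity is the sum of counts of peaks overlapping the strand-aware
window [gene body ∪ 2 kb upstream of the TSS]; a peak in two genes'
windows counts toward both. The activity matrix is log-normalized
(`ln(1 + 1e4 * x / cell_total)`; the method is stated only as
"normalizing" in the sources this follows, so the convention of the
single-cell toolchain is used). Markers are one-vs-rest two-sided
Wilcoxon rank-sum tests (normal approximation with tie correction),
prefiltered by expressing fraction ≥ 0.3 and
`log2((mean_in + 1)/(mean_out + 1)) ≥ 0.585` on de-logged normalized
means — the pseudocount of 1 keeps the ≈1.5× threshold interpretable at
zero means, and computing the fold change on normalized rather than raw
means was chosen (and is flagged here) because the test statistic acts
on the same normalized values. Bonferroni correction uses the number of
genes actually tested per type; markers satisfy adjusted p < 1e-5. At
least three annotated cell types with ≥3 cells each are required.

## Overlap validation

Interval-set validation against a reference catalogue counts ≥1 bp
overlaps (a reciprocal-fraction mode is available; "overlap" is not
defined more precisely in the sources, and the printed worked ratios are
reproducible from their counts under either reading), forms the universe
N as the number of merged regions in the base-pair union of both sets,
and computes hypergeometric significance. Both the point mass
P(X = k) and the upper tail P(X ≥ k) are returned; the tail is reported
as the significance because a point mass is not a valid enrichment
p-value, and the discrepancy between the printed formula and the
reported tail-like values is surfaced rather than hidden. Percentages
round half-up to two decimals. Jaccard similarity is base-pair-level on
merged sets, making it invariant to splitting intervals into abutting
pieces. Signal comparisons between overlapping and non-overlapping
regions use log2 fold change of group means and a two-sided t-test
(Welch by default).

## The simulator and what the tests show

`simulate_dataset()` generates the full data bundle — fragments, MTX
matrix, labels, GTF, truth tables — with the statistical structure the
pipeline assumes:

* counts are Poisson draws whose rate mixes a per-cell gamma depth
  factor (shape 10: ±32% depth variation) with peak-role means, giving
  overdispersed negative-binomial-like marginals;
* each cell type owns marker genes (all peaks elevated by the signal
  multiplier), target genes whose promoter peak and one intergenic
  enhancer share a per-cell on/off burst state (on-probability 0.5,
  boost `multiplier / p_on`, so the expected elevation is
  `multiplier + 0.2`), and super-enhancer clusters of 8 member peaks
  spaced 1 kb apart whose members burst independently while the paired
  promoter integrates the mean member state — so member–promoter edges
  are conditionally independent, exactly the structure a graphical
  lasso should recover;
* 40 housekeeping genes are open at baseline in every type, keeping
  per-cell complexity (~250 nonzero peaks) above the 200-peak QC floor
  regardless of how many types are simulated;
* closed peaks receive Poisson(noise_rate) counts (default 0.01);
  `noise_rate = 0` makes them exactly silent;
* every in-peak count unit becomes one fragment (50–500 bp, uniform in
  its peak); background fragments (20% of reads) are placed strictly
  outside peaks, so the fragment-file total reconciles exactly with the
  matrix total plus the reported background count;
* gene blocks are separated by ≥60 kb, peaks by ≥200 bp (except inside
  SE clusters), enhancers sit 20–80 kb from their target promoter
  (within the 500 kb co-accessibility horizon), and identical seeds
  give byte-identical outputs. A generation-time assertion checks the
  realized SE-member mean is at least the multiplier times the baseline
  mean within three standard errors.

The recovery tests run at desk scale: 2–3 cell types × 150 cells,
~100–160 genes, ~470–600 peaks on two ~8 Mb chromosomes, 1500 fragments
per cell; ten seeds for the recovery suites, 60-cell populations for the
determinism runs. These sizes were chosen so the full suite exercises
every stage end to end in minutes on a laptop.

Passing them shows that the weighting, QC-criteria, tangent-cutoff,
linking and marker machinery recover structure they were designed to
see, under a generative model matched to their assumptions, and that
the pipeline is byte-deterministic. They do not show robustness to what
real scATAC-seq adds: Tn5 sequence bias, doublets, batch effects,
ambient contamination, peak-calling errors, unbalanced or nested cell
types, or co-accessibility driven by shared trans factors rather than
physical contact. The generator makes no attempt at read-level realism
(no FASTQ, no duplicate structure beyond the count field).

## Numerical and degenerate-case choices

* Tanimoto of two all-zero vectors is defined as 0 with a warning;
  all-disjoint populations fall back to uniform weights.
* `ceiling(m/3)` support; all thresholds strict where worded "fewer
  than", "at least", "exceed".
* The rank-curve tangent uses a 1e-12 tie tolerance; ties break to the
  largest index.
* Graphical-lasso windows use a 1% ridge on the correlation matrix;
  window convergence tolerance 1e-4 relative to mean off-diagonal
  magnitude; exact zeros beyond the distance bound are enforced through
  the penalty, not post-hoc masking.
* Percentages round half-up with a 1e-9 epsilon so exact halves round
  up under binary floating point.
* The hypergeometric functions use the log-space base distributions;
  infeasible count combinations are rejected as domain errors.
* One master seed fans out to per-stage seeds through a fixed integer
  derivation (kept below 2^31), so `run_all()` is reproducible while
  stages stay independent.

## Known limitations

The O(m²) Tanimoto matrix is computed densely on the cells-by-cells
side; beyond ~20k cells it should be subsampled or blocked (the cap is
configurable upstream of this package's scope). The windowed graphical
lasso assumes the 500 kb horizon makes windows weakly coupled; very
peak-dense windows (>~200 sites) will be slow. Marker detection
inherits the composition sensitivity of library-size normalization when
one gene dominates a cell's counts; with realistically many genes the
effect is negligible, and the tests include a case documenting it.
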