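---
title: "Scoring TSS profile shape differences with tssshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring TSS profile shape differences with tssshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tssshape)
```

## The problem

Promoters differ not only in how much transcription they drive but in
*where* transcription starts. Focused (sharp) promoters initiate at a
single well-defined base; dispersed (broad) promoters spread initiation
over tens of bases. These shapes track distinct regulatory mechanisms, so
when reporter assays (TSS-aware MPRAs) or perturbations (motif mutations,
SNPs) are used to study initiation, one needs a sensitive, quantitative
answer to the question: *how different are these two TSS profiles, and is
the difference larger than what replicates show?*

`tssshape` represents a TSS profile as a vector of per-base 5'-end read
counts over a region, stored 5'-to-3' on the transcribed strand
(`tss_profile`), and provides the full path from aligned reads to
calibrated shape-difference calls.

## The WIP dissimilarity score

Two profiles are first made comparable: raw counts are scaled to counts
per million (CPM) using the experiment's total mapped reads, then each
profile is divided by its own sum so it becomes a unit-mass distribution.
From there the windowed initiation profile (WIP) score compares the two
distributions $a$ and $b$ of length $L$ at several scales at once. For
each window length $k = 1, \dots, K$ (default $K = 5$):

$$\mathrm{kdiff}(k) \;=\; \sum_{s=1}^{L-k+1}
\Big|\sum_{j=s}^{s+k-1} a_j \;-\; \sum_{j=s}^{s+k-1} b_j\Big|,
\qquad
\mathrm{WIP} \;=\; \sum_{k=1}^{K} k \cdot \mathrm{kdiff}(k).$$

Windows slide at stride 1 and must be fully contained (no padding). For
$k = 1$ this is the L1 distance between the distributions; larger $k$
compares signal redistributed over wider neighborhoods, and the weight
$k$ emphasizes those broader rearrangements. The score is symmetric,
non-negative, zero exactly when the unit-normalized profiles are equal,
and invariant to each profile's raw scale. For two unit spikes separated
by $d$ interior bases the score has the closed form
$2\sum_{k=1}^{K} k\min(k, d)$ — 30 for adjacent bases, saturating at 110
for $d \ge K$ — which the test suite verifies against a literal
nested-loop reference implementation (`wip_score_oracle`).

Reading "absolute differences in normalized array values at each window"
as a per-window comparison of *window sums* is a deliberate
interpretation: differencing individual positions inside each window
would make every $k$ a rescaled copy of $k = 1$ and the multi-scale
structure vacuous. Window sums are the reading under which window length
carries information.

The baseline comparator is the 1D earth mover's distance (`emd_1d`),
computed exactly as the sum of absolute cumulative-sum differences (the
closed form of Wasserstein-1 on the integer grid), verified in tests
against a brute-force minimum-cost transport.

## Calibrating "significantly different"

A WIP value alone does not say whether a difference exceeds normal
replicate variability, which depends on signal level and assay noise. The
package therefore fits a one-class SVM (`fit_outlier_model`) on
replicate-pair features: the WIP score between two replicates of the same
promoter and the log2 mean of their quantile-normalized abundances
(promoters with fewer than 25 raw reads in either replicate are excluded
first; exactly 25 passes). Features are z-scored; the kernel is RBF with
$\nu = 0.05$ and $\gamma = 1/2$. $\nu$ bounds the fraction of replicate
pairs treated as outliers and so doubles as the expected replicate
false-positive rate.

Decision values are mapped to a 0–1 outlier score by a piecewise-linear
monotone map anchored on the training decision range, with the SVM
frontier (decision value 0) pinned at 0.5 so the decision rule "score
strictly greater than 0.5 is significantly different" coincides with the
fitted boundary; values beyond the training extremes clip to 0 and 1.
Two further choices deserve note:

* **One-sided monotone envelope.** A raw RBF decision surface need not be
  monotone along the WIP axis. Scoring therefore uses the most
  inlier-like decision value found at any equal-or-greater WIP (evaluated
  over a fixed grid of upper-half training WIP quantiles; beyond the
  training maximum the RBF decision value is itself monotone). A pair can
  never be flagged while more dissimilar pairs at the same abundance are
  considered normal, and identical profiles are in-distribution by
  construction.
* **Abundance transform.** "Mean quantile-normalized abundance" is given
  no scale in the underlying method description; `log2(mean + 1)`
  stabilizes the dynamic range of count data.

Models serialize to a versioned JSON file (`save_outlier_model`) holding
the scaler, hyperparameters, support vectors, coefficients and
calibration anchors; `load_outlier_model` reconstructs a
scoring-equivalent model without refitting.

## Supporting analytics

* `focus_ratio` — fraction of a region's reads within ±10 bp (inclusive,
  clipped at array edges: 21 positions for an interior focal base) of a
  focal TSS; 1 = fully focused, near 0 = dispersed.
* `extract_window` — the −150/+150 window around an annotated TSS,
  oriented 5'→3' on the transcribed strand; windows must lie fully inside
  the profile and are taken before unit normalization.
* `barcode_variance` — log2 DNA-normalized RNA levels centered by insert
  group median; the pooled SD (also reported as fold change) defines
  outliers at ≥ 3 SD. A 0.5 pseudocount on both CPM columns tolerates
  zeros; centering makes the outlier set invariant to global scaling.
* `rank_recovery` — for each insert, all inserts are ranked by ascending
  dissimilarity (self included, ranking first with score 0; remaining
  ties broken deterministically by insert id) and group members among the
  top 4 are counted. Self-inclusion is the convention under which a
  perfect metric scores 4/4 with 4-fold barcode groups.
* `classify_tss_contribution` — per-position labels at a 3× contribution
  threshold, boundary inclusive (with a relative $10^{-9}$ guard so exact
  fold multiples stay inclusive under floating point).
* `fit_bias_curve` / `normalize_profile_by_size` — a natural cubic spline
  through a user-supplied fragment-size → relative-efficiency table;
  evaluation clamps outside the knot range (splines extrapolate wildly)
  and floors efficiencies at $10^{-3}$. A TSS at position $i$ of an
  insert of length $n$ maps to fragment size $n - i +$ adapter constant
  (121 bp by default, configurable). The bundled table
  (`inst/extdata/synthetic_size_bias.tsv`) is synthetic, for examples and
  tests; users supply their own measured table.

## The synthetic-data generator

`sim_spec`/`simulate_profiles` generate the study conditions every test
runs under:

* One true unit profile per insert group. Focused groups get a dominant
  base (60–90% of mass) plus 2–4 satellite positions within ±8 bp —
  sharp promoters are not literally single-base, and the satellites give
  each group its own fine structure while keeping the focus ratio at the
  main TSS exactly 1. Dispersed groups get a group-specific random
  mixture of 2–4 Gaussian modes (offsets within ±2 spreads, spread
  default 20 bp); broad promoters are multimodal, and a shared
  translated template would make all broad shapes identical up to shift.
* The main TSS sits at a common mid-profile offset with ~3 bp jitter,
  because MPRA inserts are synthesized around their most active TSS;
  discrimination must come from shape, not gross position.
* Replicates draw: a per-group lognormal activity factor (`activity_sd`,
  default 1 — real promoters span orders of magnitude in expression,
  which is what makes abundance an informative model feature); a
  per-barcode lognormal scale (`sigma`, default 0.2); a per-replicate,
  per-position lognormal shape perturbation (`shape_noise`, default
  0.25) capturing barcode-specific overdispersion — with pure Poisson
  noise, unit-normalized replicates would be implausibly identical in
  shape; and finally Poisson counts per position.
* `simulate_reads` writes SAM alignments whose re-quantification through
  `count_tss`/`count_barcodes` reproduces the input counts exactly
  (integer equality), which anchors the quantification tests.

What the generator does **not** emulate: sequence-dependent initiation
(no promoter grammar), mapping artifacts and multi-mappers, PCR
duplicates, RNA degradation, or cross-contamination between barcodes.
Passing tests therefore demonstrate the correctness and calibration of
the algorithms under a realistic noise model, not fidelity on any
particular experimental dataset.

## Benchmark configurations and problem sizes

The package's acceptance checks (mirrored by `scripts/acceptance.R`) use:
closed-form and oracle comparisons at profile lengths 20–50 (500 random
pairs); EMD-vs-transport at lengths ≤ 12 (200 trials); metric axioms on
1,000 random pairs; calibration with 500 training promoters at depth
1,000 and `sigma` 0.2, tested on fresh replicate pairs, on 100
sharp-versus-broad contrasts (focus ratio 1 vs < 0.2, equal totals), and
on two replicate runs of a cross-assay comparison in which 37% of
promoters genuinely differ; and the replicate rank-recovery benchmark on
100 groups × 4 barcodes at uniform depth 500 (`activity_sd = 0`, so the
metric comparison reflects shape discrimination rather than depth
heterogeneity). On this benchmark WIP recovery exceeds EMD recovery at
most seeds, but the two metrics are genuinely close under this noise
model and EMD can edge ahead by ~0.01 at some seeds.

## Numerical and convention choices

* Coordinates are 0-based half-open (BED convention) throughout;
  bedgraph export writes one single-base interval per nonzero position,
  one file per strand.
* Minus-strand profiles are stored 5'→3' on the transcribed strand; the
  counted 5' end of a minus-strand alignment is its reference end
  coordinate.
* All-zero profiles raise errors in normalization, focus ratios and
  scoring rather than returning NaN; the supported path is filtering with
  `passes_min_reads` (strictly fewer than 25 reads fails).
* Unit normalization is idempotent and verified to $10^{-9}$; quantile
  normalization delegates to `limma::normalizeQuantiles` with tie means
  (with ties, output columns match the reference distribution only up to
  tie-collapsing, so the "identical sorted values" property is exact for
  tie-free data).
* Reads are kept when mapped, primary and non-supplementary; for paired
  data only read 1 is counted. Duplicates are kept — 5' libraries pile
  up at genuine TSS positions, and deduplication would erase signal.
* Barcode matching is exact (libraries use distance-separated 11-mers);
  mismatching reads are tallied as `unassigned`, never guessed.

## Limitations

* The OCSVM score is a calibrated novelty score, not a p-value; no
  multiple-testing control is applied across promoters.
* The WIP window-sum reading and the window parameters ($K = 5$, stride
  1, full containment) are conventions; scores with different $K$ are
  not comparable.
* EMD is the only alternative metric implemented; correlation, DTW and
  related comparators are out of scope.
* The size-bias module interpolates whatever table it is given; it does
  not model GC or PCR bias, and the fragment-size mapping assumes a
  fixed 3' end per insert.
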