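# tssshape

Single-nucleotide TSS profile quantification and shape comparison for
5'-end sequencing and TSS-aware MPRA data.

## What problem this solves

Promoters can be classified by the shape of their transcription start
site (TSS) profile: focused (sharp) promoters initiate at one
well-defined base, dispersed (broad) promoters spread initiation over
tens of bases, and the shape reflects the underlying regulatory
mechanism. Experiments that read out initiation at base resolution —
csRNA-seq, CAGE-style assays, TSS-aware massively parallel reporter
assays (MPRAs) — pose a recurring analysis question: *how different are
two TSS profiles, and is the difference significant relative to
replicate variability?* This package is for genomicists running such
experiments: it turns aligned 5'-end reads into per-base TSS profiles,
scores profile-pair dissimilarity, and calibrates significance calls on
replicate data.

## The core method

A TSS profile is a vector of per-base 5'-end read counts over a region.
Profiles are CPM-scaled, then normalized to unit mass, and compared with
the **windowed initiation profile (WIP) score**: for each window length
*k* = 1..*K* (default *K* = 5) a length-*k* window slides over both
arrays, the absolute difference of the two window sums is accumulated
into a *k*-diff score, and

    WIP = sum over k of ( k × kdiff(k) )

Zero means identical unit-normalized profiles; larger values mean more
divergent shapes, with multi-base windows capturing redistribution of
initiation that single-base (L1) comparison misses. The 1D earth mover's
distance (cumulative-sum closed form of Wasserstein-1) is included as
the standard baseline, and an all-vs-all `score_matrix` feeds a
barcode-replicate rank-recovery benchmark on which the WIP score is
compared against EMD.

Whether a WIP value is *significant* is decided by a one-class SVM
trained on replicate pairs — features are the WIP score and the log2
mean quantile-normalized abundance — whose decision values are mapped to
a 0–1 outlier score with the SVM frontier pinned at 0.5: pairs scoring
strictly above 0.5 are called significantly different.

Around this core the package provides MPRA barcode counting with
RNA/DNA (CPM ratio) normalization, the fewer-than-25-reads filter,
±10 bp focus ratios, −150/+150 TSS windows, barcode-replicate variance
with a 3-SD outlier rule, position-specific nucleotide-frequency
matrices, a 3× per-TSS contribution classifier, spline-based
fragment-size bias correction, single-nucleotide bedgraph export, a
synthetic-data generator, and a `tss-shape` command-line interface
(`inst/cli/tss-shape`).

## Worked example

```r
library(tssshape)
set.seed(42)

# a sharp promoter, a 3-bp-shifted copy, and a broad promoter (sd 25 bp)
sharp   <- tss_profile(replace(numeric(300), 151, 980))
shifted <- tss_profile(replace(numeric(300), 154, 1015))
broad   <- tss_profile(rpois(300, 900 * dnorm(0:299, 150, 25) /
                                   sum(dnorm(0:299, 150, 25))))

wip_score(sharp, shifted)
#> <shape_score> metric=wip value=82 (K=5)
wip_score(sharp, broad)
#> <shape_score> metric=wip value=102.345 (K=5)
emd_1d(sharp, broad)
#> <shape_score> metric=emd value=19.3808
focus_ratio(broad, 150)
#> <focus_result> position=150 ratio=0.3322 (287 / 864 reads)
```

The sharp-vs-shifted score of 82 (= 2·Σ k·min(k,3)) reflects a 3-bp
shift of a single-base TSS; the sharp-vs-broad score approaches the
110 saturation value of fully separated shapes. The broad profile keeps
only 33% of its reads within ±10 bp of the focal TSS.

Calibrating calls on simulated replicate data:

```r
sim  <- simulate_profiles(sim_spec(n_groups = 300, replicates_per_group = 2,
                                   seed = 7))
gids <- names(sim$true_profiles)
rep1 <- setNames(sim$replicate_profiles[paste0(gids, "_bc1")], gids)
rep2 <- setNames(sim$replicate_profiles[paste0(gids, "_bc2")], gids)
feats <- build_training_features(rep1, rep2,
  vapply(rep1, function(p) p$total_raw, numeric(1)),
  vapply(rep2, function(p) p$total_raw, numeric(1)))
model <- fit_outlier_model(feats, seed = 7)
model
#> <shape_outlier_model> one-class SVM (RBF, nu=0.05, gamma=0.5), 300 training pairs
#>   decision-value anchors [-0.2678, 0.2876]; threshold 0.50

res <- call_significant(model, sharp, broad, 950, 900)
sprintf("wip = %.2f, outlier score = %.3f, different = %s",
        res$wip, res$score, res$is_different)
#> "wip = 102.34, outlier score = 1.000, different = TRUE"

call_significant(model, sharp, sharp, 950, 950)$score
#> 0.435   # identical profiles stay below the 0.5 threshold
```

The command-line interface wraps the same functions:

```sh
inst/cli/tss-shape simulate --out demo --n-groups 6 --depth 150 --seed 4
inst/cli/tss-shape quantify --alignments demo/reads_r1.sam \
    --library-fasta demo/library.fa --library-meta demo/library.tsv \
    --out demo/profiles.tsv
inst/cli/tss-shape score-matrix --profiles demo/profiles.tsv --out demo/matrix.tsv
inst/cli/tss-shape rank-recovery --matrix demo/matrix.tsv --library-meta demo/library.tsv
```

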