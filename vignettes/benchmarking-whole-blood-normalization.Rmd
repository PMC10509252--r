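---
title: "Benchmarking count normalization against leukocyte composition in whole blood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking count normalization against leukocyte composition in whole blood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodnorm)
```

## The problem

Whole blood is the most accessible tissue for transcriptomic biomarker
discovery, and also the least well-behaved for standard RNA-seq
normalization. Nearly all mRNA in a (globin-depleted) whole-blood specimen
comes from leukocytes, and the two dominant populations — neutrophils and
lymphocytes — carry radically different transcriptomes: the neutrophil
transcriptome concentrates most of its mass in a handful of very highly
expressed genes, while the lymphocyte transcriptome is flatter and more
diverse. Because the neutrophil-to-lymphocyte ratio (NLR = relative
neutrophil count / relative lymphocyte count) varies several-fold even in
healthy donors, two technically perfect whole-blood libraries can differ
genome-wide for purely compositional reasons.

Median-ratio normalization (MRN), trimmed-mean-of-M-values (TMM)
normalization and quantile normalization all assume either that most genes
are not differentially abundant between specimens, or that all specimens
share one distribution of transcript abundance. Both assumptions fail under
NLR heterogeneity. `bloodnorm` provides the machinery to measure what that
failure costs: a fully synthetic whole-blood study with known cell
fractions, the four normalizers implemented from scratch, composition
metrics, constrained permutation nulls, and marker-gene deconvolution
benchmarked against the ground-truth differentials.

## The synthetic study

### Cell signatures

`generate_signatures()` draws one base abundance profile per leukocyte
population from a log-normal law. The log-scale spread (the population's
`concentration`) controls how strongly the transcriptome mass concentrates
in few genes: the defaults (neutrophil 2.5, lymphocyte 1.2, monocyte 1.6,
eosinophil 1.9, NK 1.5) make the neutrophil-like signature markedly more
skewed than the lymphocyte-like one, which is the single structural
contrast the whole benchmark rests on. Per-population pseudo-sample counts
(6/35/6/6/6) mirror the shape of public isolated-leukocyte reference
panels, with the lymphocyte class pooling many subsets and a natural-killer
population included only as competition during marker selection.

Marker genes are planted explicitly: for each population, 30 genes receive
an abundance high in that population's TPM distribution and at least
1000-fold above every other population, with extra headroom so the
enrichment survives per-sample noise and column renormalization. The
planted assignments are retained on the object, so marker selection can be
tested against exact ground truth.

### Cohort and mixtures

`sample_cohort()` draws NLR from a log-normal law with location
`log(2.57)` and log-scale spread `0.84`, truncated to `[0.48, 23.98]`.
The location and truncation bounds are the observed median and range of a
138-donor emergency-department cohort; the spread was chosen once so the
truncation bounds sit near the 1st/99th percentiles of the untruncated
law — the only free parameter a median-plus-range summary leaves open.
Monocyte and eosinophil fractions are Beta-distributed around 7.2% and
1.5%; the neutrophil and lymphocyte fractions then solve
`f_n / f_l = NLR` and `f_n + f_l = 1 - f_mono - f_eos`, so lymphocyte
fractions are strictly positive and NLR is always finite.

`synthesize_counts()` mixes the per-class mean signatures weighted by each
sample's fractions. Mixing is mRNA-mass-proportional: fractions weight the
TPM signatures directly, since per-cell mRNA yields are not part of the
model (a deliberate assumption — no public per-cell yield was available to
calibrate one). Expected proportions are perturbed by per-sample, per-gene
log-normal noise (`expression_noise_sd`, default 0.3) representing
inter-donor expression variation beyond composition, renormalized, and
sampled multinomially at a log-normal sequencing depth (mean 1e6, sd
1.5e5).

Two calibration notes. First, the noise default was set by balancing two
observable properties of the regime being emulated: with no noise the
matched-NLR permutation null is unrealistically clean (median permuted
percent of genes at ≥ 1.5-fold ~0.2%), while noise large enough to push
that null toward the ~10% seen in real clinical cohorts (log-sd ~0.75)
degrades raw-count deconvolution far below the accuracy the study design
assumes; 0.3 keeps raw-count deconvolution in its intended operating range
(pooled Spearman rho ~0.85) at a null median of ~1%. Second, per-gene iid
noise is the only extra-compositional variance modeled: real cohorts also
carry donor-coherent expression programs (sex, infection state), which
group-median statistics and median-of-ratios size factors are largely
robust to — prototyping such modules moved the permutation null by under
three points while degrading deconvolution, so they were left out. The
residual gap between the synthetic null (~1%) and clinical nulls (~10%)
is a known limitation of the generator, not of the permutation machinery.

## The normalizers

All four evaluated strategies are pure transformations of a count matrix,
implemented from first principles and cross-checked in the test suite
against the canonical implementations:

* **RPM** — `value = count / column_sum × 1e6`. No compositional
  assumption.
* **MRN** — per-gene reference = geometric mean across samples over genes
  positive in every sample; size factor = median of count/reference;
  output = count / size factor. Matches the median-of-ratios size factors
  of the standard differential-expression workflow (to the log- vs
  linear-scale median interpolation at even gene counts).
* **TMM** — reference column chosen by the 75th percentile of depth-scaled
  counts; per-gene M and A values against the reference; 30% M-trim and 5%
  A-trim per tail; precision-weighted mean of surviving M values; factors
  rescaled to geometric mean 1 and combined with library size. Matches
  `edgeR::calcNormFactors` to 1e-8 on random matrices.
* **Quantile** — within-column ranks with ties broken by a seeded random
  stream; reference distribution = across-column mean of sorted values.
  The tie seed is recorded in the output metadata; quantile normalization
  is applied to raw counts (a pre-scaling flag is the natural extension
  point, but the default keeps the transformation elementary).

No pseudocounts are used anywhere; normalized outputs are real-valued and
tagged with their transform so downstream code can never confuse them.

## Composition metrics

`fold_difference_profile()` compares two sample groups by per-gene group
medians over the reliably detected genes. "Reliably detected" defaults to
a positive median in both groups — the weakest rule that guarantees finite
folds without pseudocounts; a prevalence-based alternative is selectable.
The signed fold is `medA/medB` when group A is higher and `-(medB/medA)`
otherwise, so every magnitude is ≥ 1 and the sign names the higher group.
Genes with equal medians take fold +1: the convention breaks that tie
upward, which is why the group-swap antisymmetry property holds exactly
only for non-tied genes.

Profile-level statistics are the percent of genes at or above a fold
threshold, the cumulative absolute fold difference (linear scale, matching
the magnitude-≥-1 convention), Spearman correlation of signed folds
between two profiles, and directional agreement (sign concordance) within
reference-defined fold subsets. Empty agreement subsets report `NaN` with
a flag rather than a silent zero.

One structural property deserves emphasis because it shaped the benchmark:
the signed-fold encoding is strictly monotone in the underlying median
ratio, so any transformation that rescales whole samples — which is all
that MRN and TMM do — shifts every between-group ratio by an approximately
common factor and leaves the *rank* correlation of fold profiles nearly
unchanged. Rank correlation is therefore close to blind to these methods'
compositional distortion. Sign concordance is not: dividing all ratios by
the typical (composition-absorbed) fold drags every gene with a modest
true fold across the null boundary and flips its direction. This is why
the benchmark's fold-profile verdict is based on the directional-agreement
comparison, while the correlation comparison is computed and reported
alongside.

## Resampling

Empirical p-values always use the add-one correction
`p = (1 + #(null ≥ observed)) / (n_perm + 1)`, so p is never zero and an
observation beating all N draws reports `1/(N+1)`.

`matched_proportion_permutation()` partitions all samples into two groups
whose class counts equal the largest-remainder quotas of the pooled class
proportions (a 6 + 35 pool split 6/35 yields exactly 1 and 5 neutrophils
per group), so no permuted comparison carries a class contrast. Permuted
groups are disjoint partitions rather than independent draws.

`matched_nlr_permutation()` draws disjoint groups at the NLR-quartile
sizes by rejection sampling until the group median NLRs differ by less
than 5% of the larger median (the comparator is configurable to absolute
differences; the relative form is the default because it scales with the
heavily right-skewed NLR distribution). The attempt cap converts a
pathological constraint into an explicit error reporting the acceptance
rate.

Bootstrap comparisons of correlation coefficients use the percentile
bootstrap with paired resampling: the 95% interval is read from the
2.5th/97.5th percentiles of the resampled differences and the two-sided p
doubles the smaller tail proportion, add-one corrected and capped at 1.
Resamples in which a vector degenerates to a constant yield an undefined
correlation and are dropped from the percentiles.

## Deconvolution

Marker selection works on weighted medians: within a class pooling several
subpopulations, each subpopulation receives equal total weight so a
35-sample lymphocyte pool cannot outvote a 6-sample neutrophil panel. The
weighted median is the smallest value whose cumulative normalized weight
reaches one half — the boundary convention matters and is pinned in one
internal function. A gene becomes a marker of the class where its weighted
median is maximal if that median is at least 100-fold above the maximal
other class (all populations compete, including non-target ones) and at
least 1.0 TPM.

`infer_cell_counts()` projects each class's marker submatrix (samples ×
genes, gene-centered, unscaled by default) onto its first principal
component. Centering without scaling follows the view that marker
magnitude is signal, not nuisance; a `scale_genes` flag provides the
standardized alternative. The component sign is arbitrary, so scores are
oriented to correlate positively with mean marker expression — markers are
positively enriched, so abundance must load positively — and unity-scaled
to [0, 1]. Classes with fewer than two markers present, or constant
submatrices, are flagged and skipped rather than fatal.

`evaluate_deconvolution()` reports Spearman rho per class against the
true fractions, the pooled rho (arithmetic mean across classes), and
percentile-bootstrap intervals; the pooled interval bootstraps the whole
per-class computation jointly over samples.

## The benchmark and its verdicts

`run_benchmark()` chains the stages under sub-seeds of one master seed:
simulate; normalize four ways; summarize distributions; build the
isolated-cell reference profile from the pure neutrophil and lymphocyte
pseudo-samples; contrast upper vs lower NLR quartiles (`floor(n/4 + 0.5)`
per tail, so 138 splits 35/68/35); optionally run the matched-NLR
permutation; select markers and deconvolve every matrix with the identical
marker panel; and derive verdicts mechanically at p < 0.05 from the
bootstrap comparisons (a Holm-adjusted column is reported alongside).

* **Distributions maintained** — the Spearman correlation between NLR and
  the per-sample median positive value must retain at least 80% of its
  raw-data strength with the same sign. The location summary is the right
  probe here: the top-1% skew share is invariant to the per-sample
  rescaling MRN/TMM apply and would call their flattening of Fig-3-style
  distribution patterns "maintained".
* **Fold-profile criterion** — directional agreement with the reference
  profile versus raw, paired gene bootstrap (see the monotonicity argument
  above).
* **Deconvolution criterion** — pooled deconvolution rho versus raw,
  paired sample bootstrap.

```{r benchmark, eval = FALSE}
report <- run_benchmark(benchmark_config(seed = 1))
report$verdicts
```

## What passing — and failing — shows

Under the default conditions (138 samples, 2000 genes, 200 permutations,
500 bootstraps; the problem sizes every shipped test and script use), the
expected verdict pattern is stable across seeds for most of the table:
depth scaling retains the NLR–distribution relationship while MRN, TMM and
quantile normalization disrupt it; MRN, TMM and quantile normalization are
reduced on the fold-profile criterion in essentially every seed; quantile
normalization is reduced on deconvolution in most seeds; and depth scaling
improves deconvolution over raw counts in essentially every seed.

Two cells of the published-style table are *not* reproduced by this
generator, and the package reports them as it finds them rather than
forcing them. MRN and TMM come out "improved" or "unchanged", not
"reduced", on the deconvolution criterion: in a mass-proportional mixture
their size factors remove per-sample scalar noise (depth, total-mass
fluctuation) more thoroughly than raw counts retain it, and their only
cost — a smooth composition-dependent bias — amplifies the neutrophil
gradient while flattening the lymphocyte one, netting out at or slightly
above raw accuracy for rank-based evaluation. And RPM's fold-profile
improvement over raw reaches significance only in a minority of seeds,
because 35-sample group medians cancel per-sample depth factors to first
order. Real whole-blood data contain structure this generator deliberately
omits (donor-coherent expression programs, zero-inflation,
annotation-scale gene sets with tens of thousands of genes) that
plausibly drives both effects; within the model implemented here, the
honest summary is that these two contrasts are not identifiable.

## Numerical and degenerate-input choices

* All randomness flows from integer seeds through an internal
  save/restore helper, so library calls never disturb the caller's RNG
  stream; sub-seeds are derived deterministically per stage, keeping
  results independent of evaluation order.
* Zero-depth samples, all-zero reference genes (MRN), fewer than 10 genes
  surviving TMM trimming, empty reliably-detected sets, and constant
  bootstrap inputs are all explicit errors or flags, never silent
  coercions.
* Quantile tie-breaking randomizes tied ranks only; the reference uses the
  plain mean of column-sorted values without interpolation.
* `count_matrix()` rejects non-integer values unless rounding is
  requested, and names the offending gene/sample in every validation
  error.
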