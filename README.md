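# bloodnorm

Benchmarking RNA-seq count normalization against leukocyte composition in
whole blood.

## The problem

Whole-blood gene expression is the workhorse of transcriptomic biomarker
discovery, but whole blood is cellularly dynamic in a way solid tissues are
not. Virtually all of its mRNA comes from white blood cells, dominated by
neutrophils and lymphocytes, and the neutrophil-to-lymphocyte ratio
(NLR = relative neutrophil count / relative lymphocyte count) varies
several-fold across donors — far more in disease. Because the neutrophil
transcriptome concentrates most of its mass in a few very highly expressed
genes while the lymphocyte transcriptome is flat and diverse, NLR shifts
reshape the whole-blood transcriptome genome-wide.

That breaks the assumptions behind the most common RNA-seq normalizers.
Median-ratio normalization (MRN, the DESeq2 default) and trimmed mean of
M-values (TMM, the edgeR default) assume most genes are not differentially
abundant between specimens; quantile normalization assumes all specimens
share one abundance distribution. When those assumptions fail, normalization
does not just remove technical variance — it removes biology.

`bloodnorm` is for analysts choosing a normalization strategy for
whole-blood biomarker studies, and for methodologists who want the failure
mode on the bench. It provides:

* a **synthetic whole-blood study** with full ground truth: skewed vs flat
  cell-type signatures with planted marker genes, a donor cohort with a
  realistic NLR distribution (median 2.57, range 0.48–23.98), and count
  matrices drawn as mRNA-mass-proportional signature mixtures;
* **from-scratch normalizers** — RPM, TPM, MRN, TMM, quantile (with random
  tie-breaking) — cross-checked in the tests against DESeq2, edgeR and
  limma;
* **composition metrics**: per-sample distribution summaries, signed
  fold-difference profiles between sample groups
  (`fold = medA/medB` if A is higher, `-(medB/medA)` otherwise),
  percent of genes at ≥ k-fold, cumulative absolute fold difference,
  profile correlation and directional agreement;
* **constrained permutation nulls** (matched class proportions via
  largest-remainder quotas; matched median NLR via rejection sampling) with
  add-one empirical p-values, and percentile-bootstrap comparison of
  Spearman correlations;
* **marker-gene deconvolution**: weighted-median marker selection
  (≥ 100-fold enrichment, ≥ 1 TPM) and per-class cell abundances as the
  first principal component of each marker submatrix, unity-scaled and
  benchmarked against the true cell fractions;
* an **end-to-end benchmark** that grades every normalizer on three
  criteria against raw counts and emits a verdict table.

## Worked example

```r
library(bloodnorm)
report <- run_benchmark(benchmark_config(seed = 1))
print(report)
```

```
Whole-blood normalization benchmark (seed 1 )
cohort: n = 138, NLR median 2.78 [0.52, 21.42]
raw fold profile: 68.1% of genes >= 1.5-fold between NLR quartiles; rho vs isolated-cell profile = 0.833
matched-NLR null: median 0.7%, p = 0.004975
raw deconvolution pooled rho = 0.875

Verdicts:
   method distributions_maintained fold_profile deconvolution
      rpm                      Yes     improved      improved
      mrn                       No      reduced     unchanged
      tmm                       No      reduced     unchanged
 quantile                       No      reduced       reduced
```

Reading it: the simulated 138-donor cohort reproduces the target NLR
distribution; 68% of reliably detected genes differ ≥ 1.5-fold in raw
counts between the upper and lower NLR quartiles, while pseudo-random
groups matched on median NLR produce a median of only 0.7% (permutation
p ≈ 0.005) — composition, not chance, drives the contrast. Those
whole-blood fold differences correlate strongly (rho = 0.833) with the
folds between isolated neutrophils and lymphocytes, and PCA deconvolution
from raw counts recovers the true cell fractions at pooled Spearman
rho = 0.875. The verdict table then grades each normalizer against raw
counts: depth scaling (RPM) keeps the NLR–distribution relationship and
improves both fold-direction recovery and deconvolution; MRN, TMM and
quantile normalization flatten the distribution structure and lose
fold-direction agreement; quantile normalization also degrades
deconvolution outright (pooled rho drops to ~0.60). Verdicts come from
percentile-bootstrap comparisons at p < 0.05. One caveat is deliberate and
documented in the methods vignette: in this mixture model MRN/TMM do not
lose *deconvolution* accuracy relative to raw counts the way they do on
real whole-blood data, because their size factors also remove depth noise
and the evaluation is rank-based.

Individual stages are available as plain functions — `simulate_blood_study()`,
`rpm()` / `mrn()` / `tmm()` / `quantile_norm()`, `fold_difference_profile()`,
`matched_nlr_permutation()`, `select_markers()`, `infer_cell_counts()` — and
everything reads and writes TSV (`read_count_matrix()`,
`write_marker_list()`, ...), so real count tables and converted reference
data flow through the identical code paths as the synthetic study.

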