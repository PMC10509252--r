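# Marker selection by weighted-median enrichment and PCA deconvolution.

test_that("weighted medians follow the smallest-value-at-half-weight convention", {
  wm <- bloodnorm:::weighted_median
  expect_equal(wm(c(1, 3, 5), rep(1, 3)), 3)
  expect_equal(wm(c(1, 1, 5), c(0.5, 0.5, 1)), 1)   # two subpop-A samples vs one B
  expect_equal(wm(rep(4.2, 6), runif(6) + 0.1), 4.2)
})

test_that("class medians weight subpopulations equally regardless of sample count", {
  # lymphocyte class pooled from two subpopulations of very different size;
  # equal-weight medians must sit at the boundary value, not the big pool's
  g <- c("gA", "gB")
  popA <- matrix(c(1, 10, 1, 10), 2, dimnames = list(g, c("a1", "a2")))
  popB <- matrix(c(5, 2), nrow = 2, ncol = 1, dimnames = list(g, "b1"))
  sig <- suppressMessages(cell_signatures(
    list(bigpool = popA, smallpool = popB),
    c(bigpool = "lymphocyte", smallpool = "lymphocyte")))
  med <- weighted_population_medians(sig)
  # per gene: values (1, 1, 5) with weights (.5, .5, 1) reach half weight at
  # 1; values (10, 10, 2) reach half weight already at 2
  expect_equal(unname(med[, "lymphocyte"]), c(1, 2))
})

test_that("marker selection applies the fold threshold and TPM floor per gene", {
  med <- rbind(strong = c(500, 2, 3, 4, 1),
               weak   = c(500, 6, 1, 1, 1),
               faint  = c(0.9, 0.009, 0.001, 0.001, 0.001))
  colnames(med) <- c("neut", "lymph", "mono", "eos", "nk")
  sig <- signatures_from_medians(med, c(neut = "neutrophil", lymph = "lymphocyte",
                                        mono = "monocyte", eos = "eosinophil",
                                        nk = "other"))
  mk <- suppressWarnings(select_markers(sig))
  expect_equal(mk$gene_id, "strong")
  expect_equal(mk$target_class, "neutrophil")
  expect_equal(mk$enrichment_fold, 125)       # 500 / max(others) = 500/4
  expect_equal(mk$median_tpm, 500)
})

test_that("marker selection is invariant to a global rescale of all signatures", {
  study <- small_study(seed = 4, n_samples = 10, n_genes = 500)
  sig <- study$signatures
  scaled <- sig
  scaled$populations <- lapply(sig$populations, function(m) m * 3.7)
  mk1 <- select_markers(sig)
  mk2 <- suppressMessages(select_markers(scaled))
  expect_equal(mk1$gene_id, mk2$gene_id)
  expect_equal(mk1$enrichment_fold, mk2$enrichment_fold, tolerance = 1e-12)
})

test_that("rank-one marker structure is recovered exactly by the first component", {
  set.seed(27)
  f <- c(1, 2, 3, 5, 8, 13)                       # per-sample abundance
  genes <- sprintf("m%02d", 1:6)
  m <- outer(runif(6, 1, 10), f)                  # value = c_g * f_s
  dimnames(m) <- list(genes, sprintf("s%d", seq_along(f)))
  mk <- marker_list(genes, rep("neutrophil", 6), rep(200, 6), rep(10, 6))
  res <- infer_cell_counts(m, mk)
  expect_equal(cor(res$inferred[, "neutrophil"], f, method = "spearman"), 1)
  expect_equal(unname(range(res$inferred[, "neutrophil"])), c(0, 1))
  expect_gt(res$variance_explained[["neutrophil"]], 0.99)
  # exactly linear structure: unity-scaled scores reproduce scaled f
  expect_equal(unname(res$inferred[, "neutrophil"]),
               (f - min(f)) / diff(range(f)), tolerance = 1e-8)
})

test_that("component orientation always aligns with mean marker expression", {
  set.seed(33)
  study <- small_study(seed = 5, n_samples = 20, n_genes = 500)
  mk <- select_markers(study$signatures)
  res <- infer_cell_counts(rpm(study$counts), mk)
  m <- expr_values(rpm(study$counts))
  for (cl in colnames(res$inferred)) {
    mean_expr <- colMeans(m[res$markers_used[[cl]], , drop = FALSE])
    expect_gt(cor(res$inferred[, cl], mean_expr, method = "spearman"), 0)
  }
})

test_that("classes with too few markers or constant submatrices are flagged, not fatal", {
  m <- matrix(runif(20, 1, 5), 4, 5,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:5)))
  mk <- marker_list(c("g1", "g2", "g9"), c("neutrophil", "neutrophil", "monocyte"),
                    rep(150, 3), rep(5, 3))
  res <- infer_cell_counts(m, mk)
  expect_identical(res$skipped_classes, "monocyte")
  const <- matrix(3, 4, 5, dimnames = dimnames(m))
  mk2 <- marker_list(c("g1", "g2"), rep("neutrophil", 2), rep(150, 2), rep(5, 2))
  res2 <- infer_cell_counts(const, mk2)
  expect_identical(res2$constant_classes, "neutrophil")
})

test_that("evaluation returns perfect scores for exact and reversed recovery", {
  d <- sample_cohort(cohort_config(n_samples = 20, random_seed = 6))
  truth <- as.matrix(d[, c("frac_neutrophil", "frac_lymphocyte",
                           "frac_monocyte", "frac_eosinophil")])
  colnames(truth) <- c("neutrophil", "lymphocyte", "monocyte", "eosinophil")
  rownames(truth) <- d$sample_id
  res <- structure(list(inferred = truth, markers_used = list(),
                        variance_explained = rep(NA, 4),
                        skipped_classes = character(0),
                        constant_classes = character(0)),
                   class = "deconv_result")
  ev <- evaluate_deconvolution(res, d, n_boot = 50)
  expect_equal(ev$per_class$rho, rep(1, 4))
  expect_equal(ev$pooled_rho, 1)
  res$inferred <- -truth
  ev2 <- evaluate_deconvolution(res, d, n_boot = 50)
  expect_equal(ev2$pooled_rho, -1)
})

test_that("deconvolution recovers a synthetic cohort's composition from raw counts", {
  study <- small_study(seed = 9, n_samples = 60, n_genes = 800)
  mk <- select_markers(study$signatures)
  res <- infer_cell_counts(expr_matrix(unclass(study$counts), "raw"), mk)
  ev <- evaluate_deconvolution(res, study$differential, n_boot = 100, seed = 1)
  expect_gte(ev$pooled_rho, 0.8)
})

test_that("deconvolution ranks survive per-sample depth rescaling of RPM input", {
  study <- small_study(seed = 10, n_samples = 15, n_genes = 500)
  mk <- select_markers(study$signatures)
  base <- expr_values(rpm(study$counts))
  rescaled <- sweep(base, 2, runif(ncol(base), 0.5, 2), "*")
  r1 <- infer_cell_counts(base, mk)
  # rpm of the rescaled matrix undoes the rescaling exactly
  r3 <- infer_cell_counts(rpm(count_matrix(round(rescaled * 10), round = TRUE)), mk)
  for (cl in colnames(r1$inferred))
    expect_gt(cor(r1$inferred[, cl], r3$inferred[, cl], method = "spearman"), 0.99)
})
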