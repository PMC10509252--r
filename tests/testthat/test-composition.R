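# Composition metrics: hand examples, brute-force oracles, and the
# symmetry/invariance properties fold-based statistics must satisfy.

test_that("distribution summaries count detection and collapse on constant columns", {
  m <- matrix(c(0, 2, 0, 7, 3, 3, 3, 3), ncol = 2,
              dimnames = list(sprintf("g%d", 1:4), c("a", "b")))
  ds <- distribution_summary(m)
  expect_equal(ds$n_detected, c(2L, 4L))
  expect_equal(unname(unlist(ds[2, c("p75", "p90", "p99")])), rep(3, 3))
  expect_equal(ds$median_positive[2], 3)
})

test_that("neutrophil-heavy samples are more skewed and less diverse than lymphocyte-heavy ones", {
  sig <- generate_signatures(signature_config(random_seed = 21))
  d <- sample_differential(c("neut_hi", "lymph_hi"),
                           neutrophil = c(0.95, 0.05), lymphocyte = c(0.05, 0.95),
                           monocyte = c(0, 0), eosinophil = c(0, 0))
  attr(d, "depths") <- c(neut_hi = 2e5, lymph_hi = 2e5)
  counts <- synthesize_counts(sig, d,
                              cohort_config(n_samples = 4, expression_noise_sd = 0,
                                            random_seed = 2))
  ds <- distribution_summary(counts)
  expect_gt(ds$top1_share[1], ds$top1_share[2])
  expect_lt(ds$n_detected[1], ds$n_detected[2])
})

test_that("fold differences are signed ratios of group medians over reliably detected genes", {
  m <- matrix(c(6, 3, 0, 6, 3, 0,     # group A columns
                3, 6, 5, 3, 6, 5),    # group B columns
              ncol = 4,
              dimnames = list(c("up", "down", "zeroA"), sprintf("s%d", 1:4)))
  p <- fold_difference_profile(m, c("s1", "s2"), c("s3", "s4"))
  expect_setequal(p$gene_id, c("up", "down"))   # zero-median gene excluded
  expect_equal(p$fold[p$gene_id == "up"], 2)
  expect_equal(p$fold[p$gene_id == "down"], -2)
  expect_equal(p$cumulative_abs_fold, cumsum(abs(p$fold)))
  expect_error(fold_difference_profile(m, c("s1", "s2"), c("s2", "s3")), "disjoint")
})

test_that("threshold fractions and cumulative folds match brute force", {
  p <- profile_from_folds(c(1.2, -1.6, 2.0, -1.0))
  expect_equal(pct_at_least_fold(p, 1.5), 0.5)
  expect_equal(pct_at_least_fold(p, 1.0), 1.0)
  expect_equal(cumulative_abs_fold(profile_from_folds(c(2, -3, 1.5))), 6.5)
  expect_equal(cumulative_abs_fold(profile_from_folds(rep(1, 7))), 7)
  set.seed(31)
  for (i in 1:10) {
    folds <- sample(c(-1, 1), 20, TRUE) * runif(20, 1, 10)
    pr <- profile_from_folds(folds)
    thr <- runif(1, 1, 5)
    expect_equal(pct_at_least_fold(pr, thr), sum(abs(folds) >= thr) / 20)
    expect_equal(cumulative_abs_fold(pr), sum(abs(folds)))
    expect_equal(cumulative_abs_fold(pr), pr$cumulative_abs_fold[nrow(pr)])
  }
})

test_that("profile correlation equals rank-then-Pearson and honors shared-gene matching", {
  set.seed(17)
  f1 <- sample(c(-1, 1), 50, TRUE) * runif(50, 1, 20)
  f2 <- sample(c(-1, 1), 50, TRUE) * runif(50, 1, 20)
  p1 <- profile_from_folds(f1)
  p2 <- profile_from_folds(f2)
  pc <- profile_correlation(p1, p2)
  shared <- intersect(p1$gene_id, p2$gene_id)
  brute <- cor(rank(p1$fold[match(shared, p1$gene_id)]),
               rank(p2$fold[match(shared, p2$gene_id)]))
  expect_equal(pc$rho, brute, tolerance = 1e-12)
  expect_equal(pc$n_shared, 50L)
  expect_equal(profile_correlation(p1, p1)$rho, 1)
  flipped <- p1; flipped$fold <- -flipped$fold
  expect_equal(profile_correlation(p1, flipped)$rho, -1)
  expect_error(profile_correlation(p1, profile_from_folds(c(2, -2), prefix = "x")),
               "shared")
})

test_that("directional agreement is exact on identical profiles and flags empty subsets", {
  p <- profile_from_folds(c(2, -3, 1.5, -8, 4))
  ag <- directional_agreement(p, p)
  expect_equal(unname(ag), rep(1, 4), ignore_attr = TRUE)
  ag2 <- directional_agreement(p, p, fold_subsets = c(1, 100))
  expect_true(is.nan(ag2[["fold_100"]]))
  expect_identical(attr(ag2, "undefined"), "fold_100")
})

test_that("agreement of random signs against a reference is near one half", {
  set.seed(53)
  n <- 2000
  ref <- profile_from_folds(sample(c(-1, 1), n, TRUE) * runif(n, 1, 10))
  rnd <- ref
  rnd$fold <- sample(c(-1, 1), n, TRUE) * abs(rnd$fold)
  ag <- directional_agreement(rnd, ref, fold_subsets = 1)
  expect_lt(abs(ag[["fold_1"]] - 0.5), 3 * sqrt(0.25 / n))
})

test_that("group swap negates folds and preserves magnitude statistics", {
  m <- unclass(random_counts(60, 8, seed = 41)) + 1   # all-positive medians
  a <- sprintf("s%02d", 1:4); b <- sprintf("s%02d", 5:8)
  p_ab <- fold_difference_profile(m, a, b)
  p_ba <- fold_difference_profile(m, b, a)
  # genes with equal group medians carry fold +1 in both orientations (the
  # sign convention breaks the tie upward), so antisymmetry is asserted on
  # the non-tied genes
  swapped <- p_ba$fold[match(p_ab$gene_id, p_ba$gene_id)]
  nontied <- abs(p_ab$fold) > 1
  expect_equal(swapped[nontied], -p_ab$fold[nontied])
  expect_equal(pct_at_least_fold(p_ab, 1.5), pct_at_least_fold(p_ba, 1.5))
  expect_equal(cumulative_abs_fold(p_ab), cumulative_abs_fold(p_ba))
})

test_that("fold metrics are invariant to global positive rescaling", {
  m <- unclass(random_counts(60, 6, seed = 43)) + 1
  a <- sprintf("s%02d", 1:3); b <- sprintf("s%02d", 4:6)
  p1 <- fold_difference_profile(m, a, b)
  p2 <- fold_difference_profile(m * 7.3, a, b)
  expect_equal(p2$fold, p1$fold, tolerance = 1e-12)
  expect_equal(cumulative_abs_fold(p2), cumulative_abs_fold(p1), tolerance = 1e-12)
})

test_that("pure-class contrasts dwarf same-composition contrasts", {
  for (seed in 1:5) {
    sig <- generate_signatures(signature_config(n_genes = 500,
                                                n_markers_per_population = 5,
                                                random_seed = seed))
    neut <- sig$populations$neutrophil
    lymph <- sig$populations$lymphocyte[, 1:6]
    m <- cbind(neut, lymph)
    pure <- fold_difference_profile(m, colnames(neut), colnames(lymph))
    same <- fold_difference_profile(cbind(sig$populations$lymphocyte[, 1:12]),
                                    colnames(sig$populations$lymphocyte)[1:6],
                                    colnames(sig$populations$lymphocyte)[7:12])
    expect_gt(pct_at_least_fold(pure, 1.5), pct_at_least_fold(same, 1.5))
  }
})
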