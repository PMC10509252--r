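# Normalizers: hand oracles, identities, and cross-checks against the
# canonical implementations (DESeq2 / edgeR / limma) on independent fixtures.
test_that("rpm scales every column to one million", {
  cm <- toy_counts(cbind(c(2, 3, 5), c(10, 30, 60)))
  out <- rpm(cm)
  expect_equal(unname(out$values[, 1]), c(200000, 300000, 500000))
  expect_equal(unname(colSums(out$values)), rep(1e6, 2))
  expect_identical(out$transform, "rpm")
  # proportional columns collapse to identical output
  cm2 <- toy_counts(cbind(c(2, 8, 4), c(4, 16, 8)))
  out2 <- rpm(cm2)
  expect_equal(out2$values[, 1], out2$values[, 2], ignore_attr = TRUE)
})

test_that("rpm refuses zero-depth columns by name", {
  m <- toy_counts(cbind(c(1, 2), c(0, 0)))
  expect_error(rpm(m), "s02")
})

test_that("tpm adjusts for gene length and sums to one million", {
  cm <- toy_counts(cbind(c(10, 10)))
  out <- tpm(cm, c(g01 = 1, g02 = 2))
  expect_equal(unname(out$values[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-12)
  # equal lengths cancel: tpm == rpm
  cm2 <- random_counts(30, 4, seed = 11)
  expect_equal(tpm(cm2, setNames(rep(500, 30), rownames(cm2)))$values,
               rpm(cm2)$values, tolerance = 1e-12)
  expect_equal(unname(colSums(out$values)), 1e6)
  expect_error(tpm(cm, c(g01 = 1, g02 = 0)), "positive")
})

test_that("mrn matches the hand-computed median-of-ratios example", {
  cm <- toy_counts(cbind(c(2, 8, 4), c(4, 16, 8)))
  out <- mrn(cm)
  expect_equal(unname(out$metadata$size_factors), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  expect_equal(unname(out$values[, 1]), c(2, 8, 4) * sqrt(2), tolerance = 1e-12)
  expect_equal(out$values[, 1], out$values[, 2], ignore_attr = TRUE)
})

test_that("mrn is the identity on identical samples and symmetric under column permutation", {
  m <- random_counts(40, 3, seed = 5)
  same <- count_matrix(matrix(m[, 1], 40, 3,
                              dimnames = list(rownames(m), colnames(m))))
  out <- mrn(same)
  expect_equal(unname(out$metadata$size_factors), rep(1, 3))
  expect_equal(out$values, unclass(same), ignore_attr = TRUE)
  perm <- c(3, 1, 2)
  out_p <- mrn(count_matrix(unclass(m)[, perm]))
  expect_equal(unname(out_p$metadata$size_factors),
               unname(mrn(m)$metadata$size_factors[perm]))
})

test_that("mrn errors when no gene is positive everywhere", {
  m <- toy_counts(cbind(c(0, 5), c(3, 0)))
  expect_error(mrn(m), "positive")
})

test_that("mrn agrees with DESeq2 size factors on random matrices", {
  skip_if_not_installed("DESeq2")
  for (seed in 1:5) {
    m <- random_counts(60, 5, seed = 100 + seed)
    sf_pkg <- mrn(m)$metadata$size_factors
    sf_ref <- DESeq2::estimateSizeFactorsForMatrix(unclass(m))
    # DESeq2 interpolates the median on the log scale at even gene counts,
    # ours on the ratio scale: agreement is close but not bitwise
    expect_equal(unname(sf_pkg), unname(sf_ref), tolerance = 1e-3)
  }
})

test_that("tmm yields unit factors on proportional columns and geometric mean one always", {
  cm <- toy_counts(cbind(c(5, 10, 20, 40), c(10, 20, 40, 80)))
  out <- tmm(cm)
  expect_equal(unname(out$metadata$scaling_factors), c(1, 1))
  expect_equal(out$values[, 1], out$values[, 2], ignore_attr = TRUE)
  for (seed in 1:5) {
    m <- random_counts(80, 4, seed = 200 + seed)
    f <- tmm(m)$metadata$scaling_factors
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  }
})

test_that("tmm equals rpm when all columns are identical", {
  m <- random_counts(50, 1, seed = 7)
  same <- count_matrix(matrix(m[, 1], 50, 3,
                              dimnames = list(rownames(m), sprintf("s%02d", 1:3))))
  expect_equal(tmm(same)$values, rpm(same)$values, tolerance = 1e-12)
})

test_that("tmm factors agree with edgeR on random matrices", {
  skip_if_not_installed("edgeR")
  for (seed in 1:5) {
    m <- random_counts(200, 5, seed = 300 + seed)
    f_pkg <- tmm(m)$metadata$scaling_factors
    f_ref <- edgeR::calcNormFactors(unclass(m), method = "TMM")
    expect_equal(unname(f_pkg), unname(f_ref), tolerance = 1e-8)
  }
})

test_that("tmm recovers a known composition offset from asymmetric changes", {
  # majority of genes unchanged; 5% strongly up in sample B only -> B's
  # library is inflated by a known factor the trimmed mean must undo
  set.seed(42)
  n <- 2000
  mu <- rlnorm(n, meanlog = 4, sdlog = 1)
  up <- seq_len(n * 0.05)
  a <- rpois(n, mu)
  mu_b <- mu
  mu_b[up] <- mu_b[up] * 16
  b <- rpois(n, mu_b)
  m <- count_matrix(matrix(c(a, b), ncol = 2,
                           dimnames = list(sprintf("g%04d", 1:n), c("A", "B"))))
  f <- tmm(m)$metadata$scaling_factors
  true_offset <- sum(mu_b) / sum(mu)      # composition inflation of B
  # the trimmed mean must shrink B by the inflation factor
  expect_equal(log2(f[["B"]] / f[["A"]]), -log2(true_offset), tolerance = 0.05)
})

test_that("quantile normalization matches the hand oracle on the worked example", {
  cm <- toy_counts(cbind(c(1, 5, 3), c(2, 4, 6)))
  out <- quantile_norm(cm)
  expect_equal(unname(out$values[, 1]), c(1.5, 5.5, 3.5))
  expect_equal(unname(out$values[, 2]), c(1.5, 3.5, 5.5))
})

test_that("quantile output columns share one multiset and ties break reproducibly", {
  m <- random_counts(50, 4, seed = 9, max_count = 10)   # low counts -> ties
  p1 <- normalization_params(quantile_tie_seed = 123)
  out1 <- quantile_norm(m, p1)
  out2 <- quantile_norm(m, p1)
  expect_identical(out1$values, out2$values)
  sorted <- apply(out1$values, 2, sort)
  for (j in 2:4) expect_equal(sorted[, j], sorted[, 1])
  # a different tie seed may only permute values among tied entries
  out3 <- quantile_norm(m, normalization_params(quantile_tie_seed = 456))
  expect_equal(apply(out3$values, 2, sort), sorted)
})

test_that("quantile normalization is the identity on already-identical columns", {
  m <- random_counts(30, 1, seed = 13)
  same <- count_matrix(matrix(m[, 1], 30, 3,
                              dimnames = list(rownames(m), sprintf("s%02d", 1:3))))
  out <- quantile_norm(same)
  expect_equal(out$values, unclass(same), ignore_attr = TRUE)
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(21)
  m <- matrix(sample(seq_len(4000), 200), nrow = 50)   # all distinct
  dimnames(m) <- list(sprintf("g%03d", 1:50), sprintf("s%02d", 1:4))
  out <- quantile_norm(count_matrix(m))
  ref <- limma::normalizeQuantiles(m)
  expect_equal(out$values, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mrn and quantile match brute-force oracles exactly on random matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- random_counts(sample(5:50, 1), sample(2:5, 1), seed = 400 + seed)
    expect_equal(mrn(m)$values, brute_force_mrn(unclass(m)),
                 ignore_attr = TRUE)
    tie_seed <- 500 + seed
    expect_equal(quantile_norm(m, normalization_params(quantile_tie_seed = tie_seed))$values,
                 brute_force_quantile(unclass(m), tie_seed),
                 ignore_attr = TRUE)
  }
})

test_that("normalize_counts dispatches and tags transforms", {
  m <- random_counts(40, 3, seed = 31)
  for (mth in c("rpm", "mrn", "tmm", "quantile")) {
    out <- normalize_counts(m, mth)
    expect_identical(out$transform, mth)
  }
  expect_error(normalization_params(tmm_logratio_trim = 0.6), "0.5")
})
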