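# Constrained permutation nulls for composition statistics and
# percentile-bootstrap machinery for comparing correlation coefficients.
# Empirical p-values always use the add-one correction
# p = (1 + #{null >= observed}) / (n_perm + 1), so p is never exactly zero
# and an observed value beating every null draw reports p = 1/(N+1).

perm_statistic <- function(statistic = c("pct_at_least_fold", "cumulative_abs_fold"),
                           threshold = 1.5) {
  statistic <- match.arg(statistic)
  if (statistic == "pct_at_least_fold") {
    list(name = sprintf("pct_at_least_fold@%g", threshold),
         fn = function(profile) pct_at_least_fold(profile, threshold))
  } else {
    list(name = "cumulative_abs_fold", fn = cumulative_abs_fold)
  }
}

empirical_p <- function(null_values, observed) {
  (1 + sum(null_values >= observed)) / (length(null_values) + 1)
}

perm_null <- function(statistic_name, null_values, observed, constraint, seed) {
  structure(list(statistic = statistic_name,
                 null_values = null_values,
                 observed = observed,
                 p_value = empirical_p(null_values, observed),
                 constraint = constraint,
                 seed = seed),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> %s | observed = %.4g | null median = %.4g | p = %.4g (%d permutations)\n",
              x$statistic, x$observed, median(x$null_values), x$p_value,
              length(x$null_values)))
  cat("constraint:", x$constraint, "\n")
  invisible(x)
}

# largest-remainder apportionment of `size` slots across classes with the
# pooled class proportions
largest_remainder_quota <- function(class_counts, size) {
  exact <- size * class_counts / sum(class_counts)
  quota <- floor(exact)
  short <- size - sum(quota)
  if (short > 0) {
    give <- order(exact - quota, decreasing = TRUE)[seq_len(short)]
    quota[give] <- quota[give] + 1L
  }
  quota
}

#' Matched-proportion permutation null
#'
#' Contextualizes a between-class composition statistic (e.g. the percent of
#' genes at >= 1.5-fold between neutrophil and lymphocyte samples) against
#' comparisons of pseudo-random groups constrained to contain equivalent
#' class proportions: each permutation partitions all samples into groups of
#' sizes `n1` and `n2` whose class counts equal the largest-remainder quotas
#' of the pooled proportions, so no permuted comparison carries a class
#' contrast.
#'
#' @param expr Expression matrix covering all labeled samples.
#' @param labels Named character vector (sample id -> class) with exactly two
#'   classes.
#' @param sizes Integer vector `c(n1, n2)` with `n1 + n2 == length(labels)`.
#' @param statistic `"pct_at_least_fold"` or `"cumulative_abs_fold"`.
#' @param threshold Fold threshold when `statistic` is
#'   `"pct_at_least_fold"`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param keep_partitions Retain the permuted group-1 memberships in the
#'   result (for diagnostics; default off).
#' @return A `perm_null` object; the observed value is the statistic on the
#'   true class split.
#' @export
matched_proportion_permutation <- function(expr, labels, sizes,
                                           statistic = "pct_at_least_fold",
                                           threshold = 1.5, n_perm = 1000,
                                           seed = 1L, keep_partitions = FALSE) {
  m <- expr_values(expr)
  assert_that(!is.null(names(labels)), "labels must be named by sample id")
  assert_that(all(names(labels) %in% colnames(m)), "labels name unknown samples")
  classes <- sort(unique(labels))
  assert_that(length(classes) == 2L, "exactly two classes required")
  assert_that(sum(sizes) == length(labels), "sizes must partition all samples")
  class_counts <- table(factor(labels, levels = classes))
  quota1 <- largest_remainder_quota(as.numeric(class_counts), sizes[1L])
  quota2 <- as.numeric(class_counts) - quota1
  if (any(quota1 < 0) || any(quota2 < 0) || any(quota1 > class_counts))
    stop_ctx("matching infeasible: a class is smaller than its required quota")
  stat <- perm_statistic(statistic, threshold)

  obs_profile <- fold_difference_profile(m, names(labels)[labels == classes[1L]],
                                         names(labels)[labels == classes[2L]])
  observed <- stat$fn(obs_profile)

  by_class <- split(names(labels), factor(labels, levels = classes))
  partitions <- if (keep_partitions) vector("list", n_perm) else NULL
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      g1 <- unlist(lapply(seq_along(classes), function(k) {
        sample(by_class[[k]], quota1[k])
      }), use.names = FALSE)
      g2 <- setdiff(names(labels), g1)
      if (keep_partitions) partitions[[i]] <<- g1
      stat$fn(fold_difference_profile(m, g1, g2))
    }, numeric(1L))
  })
  out <- perm_null(stat$name, null_values, observed,
                   constraint = sprintf("matched class proportions; quotas group1 = (%s)",
                                        paste(quota1, collapse = ", ")),
                   seed = seed)
  out$quota_group1 <- setNames(quota1, classes)
  if (keep_partitions) out$partitions <- partitions
  out
}

#' Matched-NLR permutation null
#'
#' The observed statistic contrasts upper- versus lower-NLR-quartile
#' samples; the null is built from pseudo-random disjoint groups constrained
#' (by rejection sampling) to have closely matched median NLR, so permuted
#' comparisons carry no composition signal.
#'
#' @param expr Expression matrix covering the cohort.
#' @param differential A [sample_differential()] for the same samples.
#' @param sizes Group sizes `c(n1, n2)`; default both equal to the quartile
#'   size `floor(n/4 + 0.5)`.
#' @param max_rel_diff Maximum allowed difference of group median NLRs,
#'   relative to the larger median (default 0.05); set
#'   `mode = "absolute"` to interpret it as an absolute difference.
#' @param mode `"relative"` (default) or `"absolute"` comparator for the
#'   median-NLR constraint.
#' @param statistic,threshold,n_perm,seed As in
#'   [matched_proportion_permutation()].
#' @param max_attempts_per_perm Rejection-sampling cap per permutation.
#' @return A `perm_null` object.
#' @export
matched_nlr_permutation <- function(expr, differential, sizes = NULL,
                                    max_rel_diff = 0.05,
                                    mode = c("relative", "absolute"),
                                    statistic = "pct_at_least_fold",
                                    threshold = 1.5, n_perm = 1000, seed = 1L,
                                    max_attempts_per_perm = 1000L) {
  mode <- match.arg(mode)
  m <- expr_values(expr)
  assert_that(all(differential$sample_id %in% colnames(m)),
              "differential names samples absent from the expression matrix")
  n <- nrow(differential)
  if (is.null(sizes)) sizes <- rep(floor(n / 4 + 0.5), 2L)
  assert_that(sum(sizes) <= n, "not enough samples for disjoint groups")
  stat <- perm_statistic(statistic, threshold)

  qg <- quartile_groups(differential)
  observed <- stat$fn(fold_difference_profile(m, qg$upper, qg$lower))

  ids <- differential$sample_id
  nlr <- setNames(differential$nlr, ids)
  ok_pair <- function(g1, g2) {
    m1 <- median(nlr[g1]); m2 <- median(nlr[g2])
    if (mode == "relative") abs(m1 - m2) < max_rel_diff * max(m1, m2)
    else abs(m1 - m2) < max_rel_diff
  }
  attempts <- 0L
  null_values <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      for (a in seq_len(max_attempts_per_perm)) {
        attempts <<- attempts + 1L
        pick <- sample(ids, sum(sizes))
        g1 <- pick[seq_len(sizes[1L])]
        g2 <- pick[sizes[1L] + seq_len(sizes[2L])]
        if (ok_pair(g1, g2))
          return(stat$fn(fold_difference_profile(m, g1, g2)))
      }
      stop_ctx("matched-NLR rejection sampling exhausted ",
               max_attempts_per_perm, " attempts (acceptance rate ",
               sprintf("%.2g", (i - 1) / attempts), ")")
    }, numeric(1L))
  })
  perm_null(stat$name, null_values, observed,
            constraint = sprintf("median NLR difference < %g (%s)", max_rel_diff, mode),
            seed = seed)
}

boot_indices <- function(n, n_boot) {
  matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
}

#' Percentile-bootstrap comparison of two Spearman correlations
#'
#' Both correlations share the outcome vector `y`; paired resampling of the
#' samples yields the bootstrap distribution of the difference
#' `rho(x_treatment, y) - rho(x_baseline, y)`, from which the 95% CI (2.5th
#' and 97.5th percentiles) and a two-sided p-value are read off.
#'
#' @param x_baseline,x_treatment,y Equal-length paired numeric vectors,
#'   n >= 5.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return List of class `boot_compare` with `rho_baseline`,
#'   `rho_treatment`, `difference`, `ci` (length 2), `p_value`, `n_boot`,
#'   `seed`.
#' @export
bootstrap_corr_compare <- function(x_baseline, x_treatment, y,
                                   n_boot = 1000, seed = 1L) {
  n <- length(y)
  assert_that(length(x_baseline) == n && length(x_treatment) == n,
              "vectors must have equal length")
  assert_that(n >= 5, "need at least 5 paired observations")
  if (length(unique(y)) < 2L ||
      (length(unique(x_baseline)) < 2L && length(unique(x_treatment)) < 2L))
    stop_ctx("all-constant input vectors")
  rho_b <- spearman_rho(x_baseline, y)
  rho_t <- spearman_rho(x_treatment, y)
  diffs <- with_seed(seed, {
    idx <- boot_indices(n, n_boot)
    vapply(seq_len(n_boot), function(b) {
      i <- idx[, b]
      spearman_rho(x_treatment[i], y[i]) - spearman_rho(x_baseline[i], y[i])
    }, numeric(1L))
  })
  diffs_ok <- diffs[!is.na(diffs)]
  nb <- length(diffs_ok)
  p <- min(1, 2 * min((1 + sum(diffs_ok <= 0)) / (nb + 1),
                      (1 + sum(diffs_ok >= 0)) / (nb + 1)))
  structure(list(rho_baseline = rho_b, rho_treatment = rho_t,
                 difference = rho_t - rho_b,
                 ci = unname(quantile(diffs_ok, c(0.025, 0.975))),
                 p_value = p, n_boot = n_boot, seed = seed),
            class = "boot_compare")
}

#' @export
print.boot_compare <- function(x, ...) {
  cat(sprintf("<boot_compare> rho %.3f -> %.3f | diff = %.3f [%.3f, %.3f] | p = %.4g\n",
              x$rho_baseline, x$rho_treatment, x$difference, x$ci[1L], x$ci[2L],
              x$p_value))
  invisible(x)
}

#' Percentile-bootstrap comparison of directional agreement
#'
#' Paired bootstrap over genes of the difference in sign concordance with a
#' reference fold profile: `agreement(x_treatment, ref) -
#' agreement(x_baseline, ref)`. Unlike rank correlation of signed folds,
#' sign concordance is sensitive to normalizations that push fold
#' differences across the null boundary, which is how composition-naive
#' scaling manifests as discordance.
#'
#' @param x_baseline,x_treatment,ref Equal-length signed fold vectors over
#'   the same genes.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return List of class `boot_compare` with agreement fractions in place
#'   of correlations.
#' @export
bootstrap_agreement_compare <- function(x_baseline, x_treatment, ref,
                                        n_boot = 1000, seed = 1L) {
  n <- length(ref)
  assert_that(length(x_baseline) == n && length(x_treatment) == n,
              "vectors must have equal length")
  assert_that(n >= 5, "need at least 5 genes")
  a_base <- sign(x_baseline) == sign(ref)
  a_trt <- sign(x_treatment) == sign(ref)
  diffs <- with_seed(seed, {
    idx <- boot_indices(n, n_boot)
    vapply(seq_len(n_boot), function(b) {
      i <- idx[, b]
      mean(a_trt[i]) - mean(a_base[i])
    }, numeric(1L))
  })
  p <- min(1, 2 * min((1 + sum(diffs <= 0)) / (n_boot + 1),
                      (1 + sum(diffs >= 0)) / (n_boot + 1)))
  structure(list(rho_baseline = mean(a_base), rho_treatment = mean(a_trt),
                 difference = mean(a_trt) - mean(a_base),
                 ci = unname(quantile(diffs, c(0.025, 0.975))),
                 p_value = p, n_boot = n_boot, seed = seed),
            class = "boot_compare")
}

#' Percentile-bootstrap confidence interval for a Spearman correlation
#'
#' @param x,y Paired numeric vectors, n >= 5.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return List with `rho`, `ci` (length 2), `n_boot`, `seed`.
#' @export
bootstrap_corr_ci <- function(x, y, n_boot = 1000, seed = 1L, level = 0.95) {
  n <- length(y)
  assert_that(length(x) == n, "vectors must have equal length")
  assert_that(n >= 5, "need at least 5 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop_ctx("all-constant input vectors")
  rhos <- with_seed(seed, {
    idx <- boot_indices(n, n_boot)
    vapply(seq_len(n_boot), function(b) {
      i <- idx[, b]
      spearman_rho(x[i], y[i])
    }, numeric(1L))
  })
  alpha <- (1 - level) / 2
  list(rho = spearman_rho(x, y),
       ci = unname(quantile(rhos[!is.na(rhos)], c(alpha, 1 - alpha))),
       n_boot = n_boot, seed = seed)
}
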