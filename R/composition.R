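# Transcriptome composition metrics: per-sample distribution summaries and
# between-group fold-difference profiles, the quantities through which the
# leukocyte-composition signal is measured.

#' Per-sample distribution summaries
#'
#' For each sample: the median and chosen upper percentiles of positive
#' values, the number of detected genes (value strictly greater than zero),
#' and a skew indicator, the share of total signal carried by the top 1% of
#' genes. Neutrophil-dominated specimens show higher upper percentiles,
#' lower medians, fewer detected genes and a larger top-1% share than
#' lymphocyte-dominated ones.
#'
#' @param expr `expr_matrix`, `count_matrix` or matrix.
#' @param percentiles Upper percentiles of positive values to report.
#' @return A `data.frame`, one row per sample: `sample_id`,
#'   `median_positive`, one `p<q>` column per percentile, `n_detected`,
#'   `top1_share`.
#' @export
distribution_summary <- function(expr, percentiles = c(0.75, 0.90, 0.99)) {
  m <- expr_values(expr)
  assert_that(nrow(m) > 0 && ncol(m) > 0, "empty expression matrix")
  n_top <- max(1L, ceiling(0.01 * nrow(m)))
  rows <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    pos <- x[x > 0]
    qs <- if (length(pos)) unname(quantile(pos, percentiles)) else rep(NA_real_, length(percentiles))
    tot <- sum(x)
    data.frame(sample_id = colnames(m)[j],
               median_positive = if (length(pos)) median(pos) else NA_real_,
               rbind(setNames(qs, sprintf("p%02d", round(100 * percentiles)))),
               n_detected = sum(x > 0),
               top1_share = if (tot > 0) sum(sort(x, decreasing = TRUE)[seq_len(n_top)]) / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Between-group fold-difference profile
#'
#' Per-gene group medians are computed for two disjoint sample groups;
#' genes reliably detected in both groups (default rule: positive median in
#' both, which guarantees finite folds without pseudocounts) receive a
#' signed fold difference of magnitude >= 1 — `medA/medB` when group A is
#' higher, `-(medB/medA)` otherwise. The profile is ordered by descending
#' magnitude and carries the running cumulative absolute fold difference.
#'
#' @param expr `expr_matrix`, `count_matrix` or matrix.
#' @param group_a,group_b Disjoint character vectors of sample ids (or
#'   column indices).
#' @param detect_rule `"median_positive"` (default) or `"min_prevalence"`
#'   (gene detected in more than half the samples of each group).
#' @return A `data.frame` of class `fold_profile` with columns `gene_id`,
#'   `median_a`, `median_b`, `fold`, `cumulative_abs_fold`, ordered by
#'   descending `|fold|`.
#' @export
fold_difference_profile <- function(expr, group_a, group_b,
                                    detect_rule = c("median_positive", "min_prevalence")) {
  detect_rule <- match.arg(detect_rule)
  m <- expr_values(expr)
  resolve <- function(g) {
    if (is.character(g)) {
      missing <- setdiff(g, colnames(m))
      if (length(missing)) stop_ctx("unknown sample id(s): ", paste(missing, collapse = ", "))
      match(g, colnames(m))
    } else as.integer(g)
  }
  ia <- resolve(group_a); ib <- resolve(group_b)
  assert_that(length(ia) > 0 && length(ib) > 0, "both groups must be non-empty")
  if (length(intersect(ia, ib))) stop_ctx("groups must be disjoint")
  med_a <- row_medians(m[, ia, drop = FALSE])
  med_b <- row_medians(m[, ib, drop = FALSE])
  keep <- switch(detect_rule,
    median_positive = med_a > 0 & med_b > 0,
    min_prevalence = rowMeans(m[, ia, drop = FALSE] > 0) > 0.5 &
                     rowMeans(m[, ib, drop = FALSE] > 0) > 0.5 &
                     med_a > 0 & med_b > 0)
  if (!any(keep)) stop_ctx("no reliably detected genes shared by both groups")
  ga <- med_a[keep]; gb <- med_b[keep]
  # medians equal to within floating-point noise are true ties (fold +1);
  # without the guard, rescaling the matrix could flip their sign
  tied <- abs(ga - gb) <= 1e-9 * pmax(ga, gb)
  fold <- ifelse(tied, 1, ifelse(ga >= gb, ga / gb, -(gb / ga)))
  ord <- order(abs(fold), decreasing = TRUE)
  out <- data.frame(gene_id = rownames(m)[keep][ord],
                    median_a = ga[ord], median_b = gb[ord], fold = fold[ord],
                    stringsAsFactors = FALSE)
  out$cumulative_abs_fold <- cumsum(abs(out$fold))
  class(out) <- c("fold_profile", "data.frame")
  out
}

#' Fraction of profile genes at or above a fold threshold
#'
#' @param profile A [fold_difference_profile()] result.
#' @param threshold Fold-change threshold (>= 1).
#' @return Fraction in [0, 1] of profile genes with `|fold| >= threshold`.
#' @export
pct_at_least_fold <- function(profile, threshold = 1.5) {
  assert_that(threshold >= 1, "threshold must be >= 1")
  mean(abs(profile$fold) >= threshold)
}

#' Genome-wide cumulative absolute fold difference
#'
#' @param profile A [fold_difference_profile()] result.
#' @return The sum over profile genes of `|fold|`, a genome-wide divergence
#'   summary.
#' @export
cumulative_abs_fold <- function(profile) {
  assert_that(nrow(profile) > 0, "empty profile")
  sum(abs(profile$fold))
}

#' Spearman correlation between two fold-difference profiles
#'
#' Signed fold differences of the genes shared by both profiles are rank
#' correlated; used to ask whether whole-blood between-quartile folds echo
#' the isolated-cell folds.
#'
#' @param p1,p2 Two [fold_difference_profile()] results.
#' @param log_scale Correlate signed log2 fold values instead of signed
#'   linear folds (rank-based, so this matters only through sign/magnitude
#'   encoding; default off).
#' @return List with `rho`, `p_value`, `n_shared`.
#' @export
profile_correlation <- function(p1, p2, log_scale = FALSE) {
  shared <- intersect(p1$gene_id, p2$gene_id)
  if (length(shared) < 3L) stop_ctx("need >= 3 shared genes, got ", length(shared))
  f1 <- p1$fold[match(shared, p1$gene_id)]
  f2 <- p2$fold[match(shared, p2$gene_id)]
  if (log_scale) {
    f1 <- sign(f1) * log2(abs(f1))
    f2 <- sign(f2) * log2(abs(f2))
  }
  ct <- suppressWarnings(cor.test(f1, f2, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_shared = length(shared))
}

#' Directional agreement between fold-difference profiles
#'
#' For each threshold, among shared genes whose magnitude in the reference
#' profile `p2` is at least the threshold, the fraction whose fold sign in
#' `p1` agrees with `p2`. Empty subsets yield `NaN` flagged in the
#' `"undefined"` attribute rather than a silent zero.
#'
#' @param p1 Profile under evaluation (e.g. whole-blood folds).
#' @param p2 Reference profile defining the subsets (e.g. isolated-cell
#'   folds).
#' @param fold_subsets Thresholds on `|fold|` in `p2` (default 1, 2, 4, 8).
#' @return Named numeric vector of agreement fractions, one per threshold,
#'   with attribute `"undefined"` marking empty subsets.
#' @export
directional_agreement <- function(p1, p2, fold_subsets = c(1, 2, 4, 8)) {
  shared <- intersect(p1$gene_id, p2$gene_id)
  f1 <- p1$fold[match(shared, p1$gene_id)]
  f2 <- p2$fold[match(shared, p2$gene_id)]
  out <- vapply(fold_subsets, function(t) {
    sel <- abs(f2) >= t
    if (!any(sel)) return(NaN)
    mean(sign(f1[sel]) == sign(f2[sel]))
  }, numeric(1L))
  names(out) <- sprintf("fold_%g", fold_subsets)
  attr(out, "undefined") <- names(out)[is.nan(out)]
  out
}
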