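# Marker-gene selection by weighted-median enrichment and PCA-based
# cellular deconvolution: the inferred abundance of each cell class is the
# first principal component score of its marker-gene submatrix, oriented to
# load positively on marker expression and unity-scaled to [0, 1].

#' Per-class weighted-median signature profiles
#'
#' Within a class that pools several subpopulations, every subpopulation
#' receives equal total weight (each of its samples weighted by
#' 1/n_subpopulation_samples), removing the bias a plain median would carry
#' from unequal sample counts. The weighted median is the smallest value
#' whose cumulative normalized weight reaches one half.
#'
#' @param signatures A [cell_signatures()].
#' @param classes Classes to summarize; defaults to every class present in
#'   the signature set.
#' @return Numeric matrix, genes x classes, of weighted-median TPM values.
#' @export
weighted_population_medians <- function(signatures, classes = NULL) {
  stopifnot(inherits(signatures, "cell_signatures"))
  if (is.null(classes)) classes <- unique(unname(signatures$class_map))
  n_genes <- length(signatures$gene_ids)
  out <- vapply(classes, function(cl) {
    pops <- names(signatures$class_map)[signatures$class_map == cl]
    if (!length(pops)) stop_ctx("no population mapped to class '", cl, "'")
    vals <- do.call(cbind, signatures$populations[pops])
    w <- unlist(lapply(pops, function(p) {
      k <- ncol(signatures$populations[[p]])
      rep(1 / k, k)
    }), use.names = FALSE)
    # per-gene weighted median: sort each row once
    vapply(seq_len(n_genes), function(g) weighted_median(vals[g, ], w), numeric(1L))
  }, numeric(n_genes))
  rownames(out) <- signatures$gene_ids
  colnames(out) <- classes
  out
}

#' Marker selection parameters
#'
#' @param fold_threshold Minimum weighted-median fold enrichment of a marker
#'   in its target class over the maximal other class (default 100).
#' @param min_median_tpm Minimum weighted-median abundance in the target
#'   class (default 1.0 TPM).
#' @param target_classes Classes for which markers are requested.
#' @return A list of class `marker_selection_params`.
#' @export
marker_selection_params <- function(fold_threshold = 100, min_median_tpm = 1.0,
                                    target_classes = TARGET_CLASSES) {
  assert_that(fold_threshold > 1, "fold_threshold must exceed 1")
  assert_that(min_median_tpm >= 0, "min_median_tpm must be non-negative")
  structure(list(fold_threshold = fold_threshold,
                 min_median_tpm = min_median_tpm,
                 target_classes = target_classes),
            class = "marker_selection_params")
}

#' Select cell-class marker genes by weighted-median enrichment
#'
#' A gene becomes a marker of the class in which its weighted-median
#' abundance is maximal, provided that abundance is at least
#' `fold_threshold` times the maximal weighted median over every other
#' class in the comparison pool (which includes non-target classes such as
#' a natural-killer population) and at least `min_median_tpm`. Each gene is
#' assigned to at most one class.
#'
#' @param signatures A [cell_signatures()].
#' @param params A [marker_selection_params()].
#' @return A [marker_list()]; classes yielding no markers are reported with
#'   a warning, not an error.
#' @export
select_markers <- function(signatures, params = marker_selection_params()) {
  med <- weighted_population_medians(signatures)
  pool <- colnames(med)
  targets <- intersect(params$target_classes, pool)
  if (length(pool) < 2L) stop_ctx("need >= 2 classes in the comparison pool")
  rows <- list()
  for (cl in targets) {
    own <- med[, cl]
    other_max <- apply(med[, setdiff(pool, cl), drop = FALSE], 1L, max)
    enrich <- ifelse(other_max > 0, own / other_max, Inf)
    sel <- own >= params$min_median_tpm &
      own >= params$fold_threshold * other_max &
      own > 0 &
      own == matrixStats::rowMaxs(med)        # assign to the maximal class only
    if (!any(sel)) {
      warning("no marker genes found for class '", cl, "'", call. = FALSE)
      next
    }
    rows[[cl]] <- data.frame(gene_id = rownames(med)[sel],
                             target_class = cl,
                             enrichment_fold = enrich[sel],
                             median_tpm = own[sel],
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(marker_list(character(0L), character(0L), numeric(0L), numeric(0L)))
  df <- do.call(rbind, rows)
  marker_list(df$gene_id, df$target_class, df$enrichment_fold, df$median_tpm)
}

#' Infer per-sample cell abundances from marker-gene expression
#'
#' For every class, the marker-gene submatrix (samples as observations,
#' genes as variables) is gene-centered and projected onto its first
#' principal component; the component sign is oriented so scores correlate
#' positively with mean marker expression (markers are positively enriched,
#' so abundance must load positively), and scores are unity-scaled to
#' [0, 1]. The input matrix is used exactly as handed over (raw or
#' normalized) — the benchmark contrasts these choices deliberately.
#'
#' @param expr `expr_matrix`, `count_matrix` or matrix with >= 3 samples.
#' @param markers A [marker_list()]; classes with fewer than 2 markers
#'   present in `expr` are flagged and skipped.
#' @param scale_genes Standardize marker genes to unit variance before PCA
#'   (default off: center only).
#' @return List of class `deconv_result`: `inferred` (samples x classes
#'   matrix in [0, 1]), `markers_used`, `variance_explained`,
#'   `skipped_classes`, `constant_classes`.
#' @export
infer_cell_counts <- function(expr, markers, scale_genes = FALSE) {
  m <- expr_values(expr)
  assert_that(ncol(m) >= 3L, "deconvolution needs >= 3 samples")
  classes <- unique(markers$target_class)
  inferred <- matrix(NA_real_, nrow = ncol(m), ncol = length(classes),
                     dimnames = list(colnames(m), classes))
  varexp <- setNames(rep(NA_real_, length(classes)), classes)
  used <- list()
  skipped <- character(0L)
  constant <- character(0L)
  for (cl in classes) {
    genes <- intersect(markers$gene_id[markers$target_class == cl], rownames(m))
    if (length(genes) < 2L) {
      skipped <- c(skipped, cl)
      next
    }
    sub <- t(m[genes, , drop = FALSE])           # samples x genes
    if (all(apply(sub, 2L, function(x) diff(range(x)) == 0))) {
      constant <- c(constant, cl)
      next
    }
    keep <- apply(sub, 2L, function(x) diff(range(x)) > 0)
    pc <- prcomp(sub[, keep, drop = FALSE], center = TRUE, scale. = scale_genes)
    scores <- pc$x[, 1L]
    orient <- stats::cor(scores, rowMeans(sub))
    if (!is.na(orient) && orient < 0) scores <- -scores
    rng <- range(scores)
    inferred[, cl] <- if (diff(rng) > 0) (scores - rng[1L]) / diff(rng) else NA_real_
    varexp[cl] <- pc$sdev[1L]^2 / sum(pc$sdev^2)
    used[[cl]] <- genes
  }
  structure(list(inferred = inferred, markers_used = used,
                 variance_explained = varexp,
                 skipped_classes = skipped, constant_classes = constant),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("<deconv_result> %d samples x %d classes\n",
              nrow(x$inferred), ncol(x$inferred)))
  for (cl in colnames(x$inferred))
    cat(sprintf("  %s: %d markers, %.1f%% variance on PC1\n", cl,
                length(x$markers_used[[cl]]), 100 * x$variance_explained[cl]))
  if (length(x$skipped_classes))
    cat("skipped (too few markers):", paste(x$skipped_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Benchmark inferred cell counts against a known differential
#'
#' Spearman rho between inferred and true fractions per class, the pooled
#' rho (arithmetic mean across classes), and percentile-bootstrap CIs.
#'
#' @param result A [infer_cell_counts()] result.
#' @param truth A [sample_differential()] covering the same samples.
#' @param n_boot Bootstrap resamples for the per-class CIs.
#' @param seed Integer seed.
#' @return List with `per_class` (data.frame: class, rho, ci_lower,
#'   ci_upper), `pooled_rho`, `pooled_ci`, `missing_classes`.
#' @export
evaluate_deconvolution <- function(result, truth, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(result, "deconv_result"),
            inherits(truth, "sample_differential"))
  samples <- rownames(result$inferred)
  assert_that(all(samples %in% truth$sample_id),
              "truth table missing inferred samples")
  tr <- truth[match(samples, truth$sample_id), ]
  truth_cols <- c(neutrophil = "frac_neutrophil", lymphocyte = "frac_lymphocyte",
                  monocyte = "frac_monocyte", eosinophil = "frac_eosinophil")
  classes <- colnames(result$inferred)
  missing <- classes[!classes %in% names(truth_cols)]
  classes <- setdiff(classes, missing)
  rows <- list()
  class_rhos <- c()
  for (k in seq_along(classes)) {
    cl <- classes[k]
    inf <- result$inferred[, cl]
    if (anyNA(inf)) { missing <- c(missing, cl); next }
    tv <- tr[[truth_cols[cl]]]
    ci <- bootstrap_corr_ci(inf, tv, n_boot = n_boot, seed = sub_seed(seed, k))
    rows[[cl]] <- data.frame(class = cl, rho = ci$rho,
                             ci_lower = ci$ci[1L], ci_upper = ci$ci[2L],
                             stringsAsFactors = FALSE)
    class_rhos[cl] <- ci$rho
  }
  if (!length(rows)) stop_ctx("no class could be evaluated against the truth table")
  per_class <- do.call(rbind, rows)
  rownames(per_class) <- NULL
  # pooled rho bootstrap: resample samples, recompute every class rho, average
  n <- length(samples)
  pooled_boot <- with_seed(sub_seed(seed, 999L), {
    idx <- boot_indices(n, n_boot)
    vapply(seq_len(n_boot), function(b) {
      i <- idx[, b]
      mean(vapply(names(class_rhos), function(cl) {
        spearman_rho(result$inferred[i, cl], tr[[truth_cols[cl]]][i])
      }, numeric(1L)), na.rm = TRUE)
    }, numeric(1L))
  })
  list(per_class = per_class,
       pooled_rho = mean(class_rhos),
       pooled_ci = unname(quantile(pooled_boot, c(0.025, 0.975), na.rm = TRUE)),
       missing_classes = unique(missing))
}
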