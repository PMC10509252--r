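# From-scratch implementations of the evaluated normalization strategies.
# Each is a pure transformation of a count matrix returning an expr_matrix
# tagged with its transform and carrying its scaling metadata. No
# pseudocounts are added anywhere; outputs are real-valued.

#' Normalization tuning parameters
#'
#' @param tmm_logratio_trim Fraction of extreme log-ratios (M-values)
#'   trimmed from each tail (default 0.30).
#' @param tmm_abs_trim Fraction of extreme average abundances (A-values)
#'   trimmed from each tail (default 0.05).
#' @param tmm_weighting Precision weighting of the trimmed mean by inverse
#'   asymptotic binomial variance (default on).
#' @param tmm_min_genes Minimum genes that must survive trimming.
#' @param quantile_tie_seed Seed for the random tie-breaking stream of
#'   quantile normalization; recorded in the output metadata.
#' @param pseudocount Non-negative offset, used only by optional log-scale
#'   reporting, never by the normalizers themselves.
#' @return A list of class `normalization_params`.
#' @export
normalization_params <- function(tmm_logratio_trim = 0.30,
                                 tmm_abs_trim = 0.05,
                                 tmm_weighting = TRUE,
                                 tmm_min_genes = 10L,
                                 quantile_tie_seed = 1L,
                                 pseudocount = 0) {
  assert_that(tmm_logratio_trim >= 0 && tmm_logratio_trim < 0.5,
              "tmm_logratio_trim must lie in [0, 0.5)")
  assert_that(tmm_abs_trim >= 0 && tmm_abs_trim < 0.5,
              "tmm_abs_trim must lie in [0, 0.5)")
  assert_that(pseudocount >= 0, "pseudocount must be non-negative")
  structure(list(tmm_logratio_trim = tmm_logratio_trim,
                 tmm_abs_trim = tmm_abs_trim,
                 tmm_weighting = isTRUE(tmm_weighting),
                 tmm_min_genes = as.integer(tmm_min_genes),
                 quantile_tie_seed = as.integer(quantile_tie_seed),
                 pseudocount = pseudocount),
            class = "normalization_params")
}

as_counts <- function(counts) {
  m <- expr_values(counts)
  assert_that(ncol(m) >= 1L, "empty count matrix")
  m
}

#' Reads-per-million (depth) scaling
#'
#' Scales every sample column so it sums to one million:
#' `value = count / column_sum * 1e6`. The only evaluated strategy that
#' makes no assumption about transcriptome composition.
#'
#' @param counts A `count_matrix` (or matrix).
#' @return An `expr_matrix` tagged `"rpm"`; metadata records the library
#'   sizes.
#' @export
rpm <- function(counts) {
  m <- as_counts(counts)
  libs <- colSums(m)
  if (any(libs == 0))
    stop_ctx("zero sequencing depth in sample(s): ",
             paste(colnames(m)[libs == 0], collapse = ", "))
  expr_matrix(sweep(m, 2L, libs, "/") * 1e6, "rpm",
              metadata = list(library_sizes = libs))
}

#' Transcripts-per-million scaling
#'
#' Divides counts by gene length before depth scaling:
#' `rate = count / length`, `value = rate / sum(rate) * 1e6`.
#'
#' @param counts A `count_matrix`.
#' @param gene_lengths Named numeric vector of positive lengths covering
#'   every gene in `counts`.
#' @return An `expr_matrix` tagged `"tpm"`.
#' @export
tpm <- function(counts, gene_lengths) {
  m <- as_counts(counts)
  if (is.null(names(gene_lengths))) {
    assert_that(length(gene_lengths) == nrow(m), "gene_lengths length mismatch")
    names(gene_lengths) <- rownames(m)
  }
  missing <- setdiff(rownames(m), names(gene_lengths))
  if (length(missing))
    stop_ctx("missing gene length(s): ", paste(head(missing, 5L), collapse = ", "))
  len <- gene_lengths[rownames(m)]
  if (any(!is.finite(len)) || any(len <= 0))
    stop_ctx("gene lengths must be positive and finite")
  rate <- m / len
  expr_matrix(sweep(rate, 2L, colSums(rate), "/") * 1e6, "tpm",
              metadata = list(gene_lengths = len))
}

#' Median-ratio normalization (MRN)
#'
#' The per-gene reference is the geometric mean of counts across samples,
#' computed over genes with strictly positive counts in every sample; each
#' sample's size factor is the median over those genes of the ratio of its
#' count to the reference, and counts are divided by the size factor.
#' Assumes a majority of genes are not differentially abundant between
#' samples.
#'
#' @param counts A `count_matrix`.
#' @return An `expr_matrix` tagged `"mrn"`; metadata records the size
#'   factors.
#' @export
mrn <- function(counts) {
  m <- as_counts(counts)
  assert_that(ncol(m) >= 2L, "MRN needs at least 2 samples")
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos))
    stop_ctx("no gene with strictly positive counts in all samples; ",
             "filter all-zero-prone genes before MRN")
  ref <- exp(rowMeans(log(m[allpos, , drop = FALSE])))
  sf <- apply(m[allpos, , drop = FALSE], 2L, function(col) median(col / ref))
  expr_matrix(sweep(m, 2L, sf, "/"), "mrn", metadata = list(size_factors = sf))
}

# TMM scaling factor of one sample against the reference column.
tmm_pair_factor <- function(obs, ref, params) {
  obs <- as.numeric(obs)
  ref <- as.numeric(ref)
  n_obs <- sum(obs)
  n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m_val <- log2((obs / n_obs) / (ref / n_ref))
  a_val <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  fin <- is.finite(m_val) & is.finite(a_val)
  m_val <- m_val[fin]; a_val <- a_val[fin]; obs <- obs[fin]; ref <- ref[fin]
  if (!length(m_val)) return(1)
  if (max(abs(m_val)) < 1e-6) return(1)           # proportional columns
  n <- length(m_val)
  lo_m <- floor(n * params$tmm_logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * params$tmm_abs_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m_val); ra <- rank(a_val)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (sum(keep2) < params$tmm_min_genes)
    stop_ctx("fewer than ", params$tmm_min_genes, " genes survive TMM trimming")
  if (params$tmm_weighting) {
    w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
    f <- sum(m_val[keep2] / w[keep2]) / sum(1 / w[keep2])
  } else {
    f <- mean(m_val[keep2])
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values (TMM) normalization
#'
#' The reference sample is the column whose 75th percentile of depth-scaled
#' counts is closest to the mean of those percentiles. For every sample,
#' gene-wise log2 ratios (M) and mean log2 abundances (A) against the
#' reference are computed over genes positive in both; the configured
#' fractions of extreme M and A values are trimmed from each tail and the
#' scaling factor is 2 to the (precision-weighted) mean of the remaining M
#' values. Factors are rescaled to geometric mean 1 and combined with
#' library size: `value = count / (column_sum * factor) * 1e6`. Assumes a
#' majority of genes are not differentially abundant.
#'
#' @param counts A `count_matrix` with at least two samples.
#' @param params A [normalization_params()].
#' @return An `expr_matrix` tagged `"tmm"`; metadata records the scaling
#'   factors and the reference sample.
#' @export
tmm <- function(counts, params = normalization_params()) {
  m <- as_counts(counts)
  assert_that(ncol(m) >= 2L, "TMM needs at least 2 samples")
  libs <- colSums(m)
  if (any(libs == 0))
    stop_ctx("zero sequencing depth in sample(s): ",
             paste(colnames(m)[libs == 0], collapse = ", "))
  f75 <- vapply(seq_len(ncol(m)), function(j) {
    unname(quantile(m[, j] / libs[j], 0.75))
  }, numeric(1L))
  ref_idx <- which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref_idx) return(tmm_pair_factor(m[, j], m[, ref_idx], params))
    tmm_pair_factor(m[, j], m[, ref_idx], params)
  }, numeric(1L))
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(m)
  expr_matrix(sweep(m, 2L, libs * factors, "/") * 1e6, "tmm",
              metadata = list(scaling_factors = factors,
                              reference_sample = colnames(m)[ref_idx]))
}

#' Quantile normalization with random tie-breaking
#'
#' Every sample is forced onto one shared empirical distribution: within
#' each column values are ranked with ties broken by a seeded random
#' stream, the reference distribution is the across-column mean of sorted
#' values, and each value is replaced by the reference value at its rank.
#' All output columns therefore hold identical sorted multisets. Assumes
#' all specimens share the same distribution of transcript abundance.
#'
#' @param counts A `count_matrix` with at least two samples.
#' @param params A [normalization_params()]; `quantile_tie_seed` drives the
#'   tie-breaking stream and is recorded in the metadata.
#' @return An `expr_matrix` tagged `"quantile"`.
#' @export
quantile_norm <- function(counts, params = normalization_params()) {
  m <- as_counts(counts)
  assert_that(ncol(m) >= 2L, "quantile normalization needs at least 2 samples")
  ref <- rowMeans(apply(m, 2L, sort))
  out <- with_seed(params$quantile_tie_seed, {
    vapply(seq_len(ncol(m)), function(j) {
      ref[rank(m[, j], ties.method = "random")]
    }, numeric(nrow(m)))
  })
  dimnames(out) <- dimnames(m)
  expr_matrix(out, "quantile",
              metadata = list(tie_seed = params$quantile_tie_seed))
}

#' Apply a normalization strategy by name
#'
#' @param counts A `count_matrix`.
#' @param method One of `"raw"`, `"rpm"`, `"mrn"`, `"tmm"`, `"quantile"`,
#'   `"tpm"`.
#' @param params A [normalization_params()].
#' @param gene_lengths Required for `method = "tpm"` only.
#' @return An `expr_matrix`.
#' @export
normalize_counts <- function(counts, method, params = normalization_params(),
                             gene_lengths = NULL) {
  method <- match.arg(method, VALID_TRANSFORMS)
  switch(method,
         raw = expr_matrix(as_counts(counts), "raw"),
         rpm = rpm(counts),
         tpm = tpm(counts, gene_lengths),
         mrn = mrn(counts),
         tmm = tmm(counts, params),
         quantile = quantile_norm(counts, params))
}
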