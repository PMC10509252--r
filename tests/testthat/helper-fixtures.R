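# Fixtures are built in code. Small matrices get deterministic dimnames via
# these helpers; random fixtures always draw under an explicit seed.

toy_counts <- function(values, n_genes = nrow(values), n_samples = ncol(values)) {
  m <- matrix(as.numeric(values), nrow = n_genes, ncol = n_samples)
  rownames(m) <- sprintf("g%02d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  count_matrix(m)
}

random_counts <- function(n_genes, n_samples, seed, max_count = 200) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda = runif(n_genes, 1, max_count)),
              nrow = n_genes)
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  count_matrix(m)
}

# signature set with one sample per population holding exact per-class values;
# `medians` is a genes x populations matrix (population names as colnames)
signatures_from_medians <- function(medians, class_map, tpm_rescale = FALSE) {
  pops <- lapply(colnames(medians), function(nm) {
    m <- matrix(medians[, nm], ncol = 1,
                dimnames = list(rownames(medians), paste0(nm, "_01")))
    if (tpm_rescale) m <- m / sum(m) * 1e6
    m
  })
  names(pops) <- colnames(medians)
  suppressMessages(cell_signatures(pops, class_map))
}

# tiny fold profile straight from fold values
profile_from_folds <- function(folds, prefix = "g") {
  stopifnot(all(abs(folds) >= 1))
  ord <- order(abs(folds), decreasing = TRUE)
  out <- data.frame(gene_id = sprintf("%s%03d", prefix, seq_along(folds))[ord],
                    median_a = NA_real_, median_b = NA_real_, fold = folds[ord],
                    stringsAsFactors = FALSE)
  out$cumulative_abs_fold <- cumsum(abs(out$fold))
  class(out) <- c("fold_profile", "data.frame")
  out
}

small_study <- function(seed = 1, n_samples = 60, n_genes = 800,
                        expression_noise_sd = 0.3) {
  simulate_blood_study(
    signature_config(n_genes = n_genes,
                     n_markers_per_population = min(10L, n_genes %/% 50L),
                     random_seed = 1),
    cohort_config(n_samples = n_samples,
                  expression_noise_sd = expression_noise_sd, random_seed = 1),
    seed = seed)
}
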