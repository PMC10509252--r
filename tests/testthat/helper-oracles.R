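# Brute-force oracles shared by unit and acceptance tests. Kept deliberately
# naive and independent of the implementation paths they check.

brute_force_mrn <- function(m) {
  allpos <- apply(m > 0, 1, all)
  ref <- apply(m[allpos, , drop = FALSE], 1, function(x) prod(x)^(1 / length(x)))
  sf <- vapply(seq_len(ncol(m)), function(j)
    median(m[allpos, j] / ref), numeric(1))
  sweep(m, 2, sf, "/")
}

brute_force_quantile <- function(m, seed) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  set.seed(seed)
  for (j in seq_len(ncol(m))) out[, j] <- ref[rank(m[, j], ties.method = "random")]
  out
}

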