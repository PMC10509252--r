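# Internal helpers shared across modules.

#' @importFrom stats median quantile cor cor.test prcomp rlnorm rpois rmultinom
#'   rbeta rnorm runif setNames kruskal.test
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All exported stochastic operations route
# their randomness through this so a single integer seed makes a whole
# pipeline reproducible without clobbering the user's session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-stream seeds: one master integer fans out to per-stage /
# per-iteration seeds, all kept inside 32-bit integer range.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 2971 + 1000003 * as.numeric(k)) %% 2147483647)
}

row_medians <- function(x) matrixStats::rowMedians(x, useNames = TRUE)

# Weighted median: smallest value whose cumulative normalized weight reaches
# one half. Boundary convention matters for ties and is relied on by the
# marker-selection rules, so it is pinned here rather than delegated.
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), any(w > 0))
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1L]]
}

# Spearman rho via rank-then-Pearson; returns 0 with a "constant" attribute
# when either vector is constant (undefined correlation).
spearman_rho <- function(x, y) {
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(structure(NA_real_, constant = TRUE))
  }
  stats::cor(rank(x), rank(y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop_ctx(...)
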