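# S3 containers used throughout the package. Count matrices are plain
# integer matrices (genes x samples, dimnames mandatory); normalized
# expression carries its provenance in an `expr_matrix` wrapper so a value
# can never be mistaken for a different transform downstream.

VALID_TRANSFORMS <- c("raw", "rpm", "tpm", "mrn", "tmm", "quantile")
CELL_CLASSES <- c("neutrophil", "lymphocyte", "monocyte", "eosinophil", "other")
TARGET_CLASSES <- c("neutrophil", "lymphocyte", "monocyte", "eosinophil")

#' Validate a gene-by-sample count matrix
#'
#' Checks the invariants every comparative operation in the package relies
#' on: a numeric matrix with unique gene row names and sample column names,
#' non-negative integer-valued entries, and no missing values.
#'
#' @param x Numeric matrix, genes as rows, samples as columns, with dimnames.
#' @param round Logical; if `TRUE`, non-integer values are rounded instead of
#'   rejected (useful when consuming pre-scaled tables as pseudo-counts).
#' @return The validated (integer-valued) matrix, invisibly classed
#'   `count_matrix`.
#' @export
count_matrix <- function(x, round = FALSE) {
  assert_that(is.matrix(x) && is.numeric(x), "counts must be a numeric matrix")
  assert_that(!is.null(rownames(x)) && !is.null(colnames(x)),
              "count matrix needs gene rownames and sample colnames")
  assert_that(!anyNA(x), "count matrix contains missing values")
  if (anyDuplicated(rownames(x)))
    stop_ctx("duplicate gene identifier(s): ",
             paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop_ctx("duplicate sample identifier(s): ",
             paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop_ctx("negative count at gene '", rownames(x)[bad[1L]],
             "', sample '", colnames(x)[bad[2L]], "'")
  }
  nonint <- abs(x - round(x)) > 1e-8
  if (any(nonint)) {
    if (round) x <- round(x)
    else {
      bad <- which(nonint, arr.ind = TRUE)[1L, ]
      stop_ctx("non-integer count at gene '", rownames(x)[bad[1L]],
               "', sample '", colnames(x)[bad[2L]],
               "' (use round = TRUE to accept)")
    }
  }
  structure(x, class = c("count_matrix", class(x)))
}

#' Construct a tagged expression matrix
#'
#' @param values Non-negative numeric matrix (genes x samples) with dimnames.
#' @param transform One of `"raw"`, `"rpm"`, `"tpm"`, `"mrn"`, `"tmm"`,
#'   `"quantile"` recording the transformation that produced the values.
#' @param metadata Named list of normalization metadata (size factors,
#'   scaling factors, seeds, ...).
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, transform = "raw", metadata = list()) {
  transform <- match.arg(transform, VALID_TRANSFORMS)
  assert_that(is.matrix(values) && is.numeric(values), "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "expression matrix needs gene rownames and sample colnames")
  assert_that(all(values >= 0), "expression values must be non-negative")
  structure(list(values = values, transform = transform, metadata = metadata),
            class = "expr_matrix")
}

#' Extract the numeric matrix from an expression container
#'
#' Accepts an `expr_matrix`, a `count_matrix`, or a plain matrix, so every
#' downstream metric can be applied to raw counts and normalized values
#' through one code path.
#'
#' @param x Matrix-like expression object.
#' @return Numeric matrix, genes x samples.
#' @export
expr_values <- function(x) {
  if (inherits(x, "expr_matrix")) return(x$values)
  if (is.matrix(x)) return(unclass(x))
  stop_ctx("cannot interpret object of class '", class(x)[1L], "' as expression values")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, transform = %s\n",
              nrow(x$values), ncol(x$values), x$transform))
  if (length(x$metadata)) cat("metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Construct a cell signature set
#'
#' Per-population gene-level TPM-scale abundances for isolated leukocyte
#' populations, the ground truth both for mixture synthesis and marker
#' selection. Columns of every population matrix sum to 1e6 (TPM convention);
#' off-convention inputs are accepted but flagged.
#'
#' @param populations Named list of numeric matrices (genes x samples per
#'   population), identical rownames across populations.
#' @param class_map Named character vector mapping each population name to a
#'   cell class among neutrophil, lymphocyte, monocyte, eosinophil, other.
#' @param markers Optional named list (population -> character vector of
#'   ground-truth marker gene ids), retained for testing generators.
#' @return An object of class `cell_signatures`.
#' @export
cell_signatures <- function(populations, class_map, markers = NULL) {
  assert_that(is.list(populations) && length(populations) >= 1L,
              "need at least one population matrix")
  assert_that(!is.null(names(populations)) && !anyDuplicated(names(populations)),
              "population names must be present and unique")
  gene_ids <- rownames(populations[[1L]])
  assert_that(!is.null(gene_ids), "population matrices need gene rownames")
  for (nm in names(populations)) {
    m <- populations[[nm]]
    assert_that(is.matrix(m) && all(m >= 0), "population '", nm, "' must be a non-negative matrix")
    if (!identical(rownames(m), gene_ids))
      stop_ctx("gene identifiers of population '", nm, "' are not aligned")
  }
  missing_map <- setdiff(names(populations), names(class_map))
  if (length(missing_map))
    stop_ctx("population(s) missing from class map: ", paste(missing_map, collapse = ", "))
  bad_class <- setdiff(unname(class_map[names(populations)]), CELL_CLASSES)
  if (length(bad_class))
    stop_ctx("unknown cell class(es): ", paste(bad_class, collapse = ", "))
  off <- vapply(populations, function(m) {
    any(abs(colSums(m) - 1e6) > 1e-6 * 1e6)
  }, logical(1L))
  if (any(off))
    message("signature columns not on the 1e6 TPM scale in population(s): ",
            paste(names(populations)[off], collapse = ", "))
  structure(list(gene_ids = gene_ids,
                 populations = populations,
                 class_map = class_map[names(populations)],
                 markers = markers),
            class = "cell_signatures")
}

#' @export
print.cell_signatures <- function(x, ...) {
  cat(sprintf("<cell_signatures> %d genes, %d populations\n",
              length(x$gene_ids), length(x$populations)))
  for (nm in names(x$populations))
    cat(sprintf("  %s (%s): %d samples\n", nm, x$class_map[[nm]], ncol(x$populations[[nm]])))
  invisible(x)
}

#' Construct a sample differential table
#'
#' Flow-cytometry-style white blood cell differential: per-sample leukocyte
#' fractions and the derived neutrophil-to-lymphocyte ratio (NLR), the
#' benchmark of each specimen's cellular identity.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param neutrophil,lymphocyte,monocyte,eosinophil Per-sample fractions in
#'   (0, 1); each sample's fractions must sum to at most 1 (any remainder is
#'   unmodeled cell mass).
#' @return A `data.frame` of class `sample_differential` with columns
#'   `sample_id`, the four `frac_*` columns and `nlr`.
#' @export
sample_differential <- function(sample_ids, neutrophil, lymphocyte, monocyte, eosinophil) {
  n <- length(sample_ids)
  assert_that(!anyDuplicated(sample_ids), "sample ids must be unique")
  fr <- cbind(neutrophil, lymphocyte, monocyte, eosinophil)
  assert_that(nrow(fr) == n, "fraction vectors must match sample_ids length")
  assert_that(all(fr >= 0) && all(fr <= 1), "fractions must lie in [0, 1]")
  assert_that(all(rowSums(fr) <= 1 + 1e-8), "per-sample fractions must sum to <= 1")
  assert_that(all(lymphocyte > 0), "lymphocyte fraction must be positive so NLR is finite")
  out <- data.frame(sample_id = as.character(sample_ids),
                    frac_neutrophil = neutrophil,
                    frac_lymphocyte = lymphocyte,
                    frac_monocyte = monocyte,
                    frac_eosinophil = eosinophil,
                    nlr = neutrophil / lymphocyte,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_differential", "data.frame")
  out
}
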