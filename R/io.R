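# Tabular IO. Genes are rows and samples are columns everywhere; tables are
# TSV by default with commas auto-detected. Identifiers are opaque text --
# no gene-id mapping is attempted.

detect_sep <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") return("\t")
  if (dialect == "csv") return(",")
  first <- readLines(path, n = 1L)
  if (!length(first)) stop_ctx("empty input file: ", path)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a gene-level count matrix
#'
#' Expects a delimited table whose first column is `gene_id` and whose
#' remaining columns are per-sample integer counts. Validation errors name
#' the offending gene/sample.
#'
#' @param path File path (TSV or CSV).
#' @param dialect `"auto"` (default; tab preferred), `"tsv"` or `"csv"`.
#' @param round Accept non-integer values by rounding (default off).
#' @return A validated `count_matrix`.
#' @export
read_count_matrix <- function(path, dialect = "auto", round = FALSE) {
  sep <- detect_sep(path, dialect)
  df <- read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop_ctx("no count data found in ", path)
  if (names(df)[1L] != "gene_id")
    stop_ctx("first column must be 'gene_id', found '", names(df)[1L], "'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_ctx("non-numeric entries in count table ", path)
  rownames(m) <- df$gene_id
  count_matrix(m, round = round)
}

#' Write a count or expression matrix as TSV
#'
#' @param x `count_matrix`, `expr_matrix` or plain matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(x, path) {
  m <- expr_values(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an isolated-cell signature table
#'
#' Wide TSV with a two-row header: line 1 gives the population label of each
#' sample column, line 2 the sample label; the first column is `gene_id`.
#' Values are TPM-scale abundances (columns off the 1e6 convention are
#' accepted and flagged by [cell_signatures()]).
#'
#' @param path File path.
#' @param class_map Named character vector mapping every population label in
#'   the header to a cell class; an unmapped label is an error.
#' @return A [cell_signatures()] object.
#' @export
read_signature_table <- function(path, class_map) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L) stop_ctx("signature table needs a two-row header: ", path)
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  pop_row <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]][-1L]
  samp_row <- strsplit(lines[2L], sep, fixed = TRUE)[[1L]][-1L]
  body <- read.delim(path, sep = sep, skip = 2L, header = FALSE,
                     stringsAsFactors = FALSE)
  if (ncol(body) != length(pop_row) + 1L)
    stop_ctx("ragged signature table: header declares ", length(pop_row),
             " sample columns, body has ", ncol(body) - 1L)
  unmapped <- setdiff(unique(pop_row), names(class_map))
  if (length(unmapped))
    stop_ctx("population label(s) absent from class map: ",
             paste(unmapped, collapse = ", "))
  m <- as.matrix(body[, -1L, drop = FALSE])
  rownames(m) <- body[[1L]]
  zero_cols <- colSums(m) == 0
  if (any(zero_cols))
    message("signature column(s) of all zeros retained: ",
            paste(samp_row[zero_cols], collapse = ", "))
  pops <- lapply(split(seq_along(pop_row), pop_row), function(idx) {
    sub <- m[, idx, drop = FALSE]
    colnames(sub) <- samp_row[idx]
    sub
  })
  cell_signatures(pops, class_map[names(pops)])
}

#' Write a signature set as a wide two-header TSV
#'
#' @param signatures A [cell_signatures()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signature_table <- function(signatures, path) {
  mats <- signatures$populations
  pop_row <- unlist(lapply(names(mats), function(nm) rep(nm, ncol(mats[[nm]]))))
  samp_row <- unlist(lapply(mats, colnames))
  body <- do.call(cbind, mats)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(c("population", pop_row), collapse = "\t"),
               paste(c("sample", samp_row), collapse = "\t")), con)
  write.table(data.frame(signatures$gene_ids, body, stringsAsFactors = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a white blood cell differential table
#'
#' Columns: `sample_id`, `pct_neutrophil`, `pct_lymphocyte`, `pct_monocyte`,
#' `pct_eosinophil`, `nlr`; fractions are written as percentages.
#'
#' @param differential A [sample_differential()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_differential <- function(differential, path) {
  df <- data.frame(sample_id = differential$sample_id,
                   pct_neutrophil = 100 * differential$frac_neutrophil,
                   pct_lymphocyte = 100 * differential$frac_lymphocyte,
                   pct_monocyte = 100 * differential$frac_monocyte,
                   pct_eosinophil = 100 * differential$frac_eosinophil,
                   nlr = differential$nlr)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a white blood cell differential table
#'
#' @param path Path to a TSV written by [write_differential()].
#' @return A [sample_differential()].
#' @export
read_differential <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pct_neutrophil", "pct_lymphocyte",
            "pct_monocyte", "pct_eosinophil")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_ctx("differential table missing column(s): ", paste(missing, collapse = ", "))
  sample_differential(df$sample_id,
                      neutrophil = df$pct_neutrophil / 100,
                      lymphocyte = df$pct_lymphocyte / 100,
                      monocyte = df$pct_monocyte / 100,
                      eosinophil = df$pct_eosinophil / 100)
}

#' Construct a marker gene list
#'
#' @param gene_id Character vector of gene identifiers (no duplicates; a gene
#'   belongs to at most one class).
#' @param target_class Cell class each marker represents.
#' @param enrichment_fold Weighted-median fold enrichment of the marker in
#'   its class over the maximal other population (may be `Inf` when no other
#'   population expresses the gene).
#' @param median_tpm Weighted-median abundance in the target class.
#' @return A `data.frame` of class `marker_list`.
#' @export
marker_list <- function(gene_id, target_class, enrichment_fold, median_tpm) {
  if (anyDuplicated(gene_id))
    stop_ctx("gene(s) assigned more than once: ",
             paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  bad <- setdiff(unique(target_class), TARGET_CLASSES)
  if (length(bad)) stop_ctx("unknown target class token(s): ", paste(bad, collapse = ", "))
  out <- data.frame(gene_id = as.character(gene_id),
                    target_class = as.character(target_class),
                    enrichment_fold = as.numeric(enrichment_fold),
                    median_tpm = as.numeric(median_tpm),
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_list", "data.frame")
  out
}

#' Write / read a marker gene list (lossless TSV round-trip)
#'
#' @param markers A [marker_list()].
#' @param path File path.
#' @param fold_threshold Threshold against which `enrichment_fold` is checked
#'   on write; entries below it are written with a warning (reads preserve
#'   them untouched).
#' @return `write_marker_list` invisibly returns `path`;
#'   `read_marker_list` returns a [marker_list()].
#' @export
write_marker_list <- function(markers, path, fold_threshold = 100) {
  stopifnot(inherits(markers, "marker_list"))
  below <- markers$enrichment_fold < fold_threshold
  if (any(below))
    warning(sum(below), " marker(s) below the ", fold_threshold,
            "-fold enrichment threshold", call. = FALSE)
  write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_list
#' @export
read_marker_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "target_class", "enrichment_fold", "median_tpm")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_ctx("marker table missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L)
    return(marker_list(character(0L), character(0L), numeric(0L), numeric(0L)))
  marker_list(df$gene_id, df$target_class, df$enrichment_fold, df$median_tpm)
}
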