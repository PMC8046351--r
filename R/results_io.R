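#' Assemble a gene-level results table
#'
#' Collects `VCResult` objects (or burden-test results with matching
#' fields) into the fixed-schema table written by the command-line tools:
#' `GENE_ID CHROM START END N_SNPS Q PVALUE FDR FLAGS`. FDR is the
#' Benjamini-Hochberg adjustment of the PVALUE column (NA p-values are
#' excluded from adjustment and propagate).
#'
#' @param results List of `VCResult` objects.
#' @param annotation Optional data frame with columns `gene_id`, `chrom`,
#'   `start`, `end` used to fill coordinates; unknown genes get `NA`.
#' @return A data frame in the fixed column schema.
#' @export
results_table <- function(results, annotation = NULL) {
  df <- data.frame(
    GENE_ID = vapply(results, function(r) as.character(r$gene_id), ""),
    CHROM = NA_character_, START = NA_integer_, END = NA_integer_,
    N_SNPS = vapply(results, function(r) as.integer(r$m_snps_used), 0L),
    Q = vapply(results, function(r) as.numeric(r$q_stat), 0),
    PVALUE = vapply(results, function(r) as.numeric(r$p_value), 0),
    FDR = NA_real_,
    FLAGS = vapply(results, function(r)
      if (length(r$method_flags)) paste(r$method_flags, collapse = ";")
      else ".", ""),
    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    i <- match(df$GENE_ID, annotation$gene_id)
    df$CHROM <- as.character(annotation$chrom[i])
    df$START <- as.integer(annotation$start[i])
    df$END <- as.integer(annotation$end[i])
  }
  df$FDR <- bh_fdr(df$PVALUE)
  df
}

.results_schema <- c("GENE_ID", "CHROM", "START", "END", "N_SNPS",
                     "Q", "PVALUE", "FDR", "FLAGS")

#' Write / read the gene-level results table
#'
#' Tab-delimited with the fixed schema
#' `GENE_ID CHROM START END N_SNPS Q PVALUE FDR FLAGS`; numeric fields are
#' serialized at full precision so `read_results(write_results(x))`
#' round-trips to 1e-12. Reading validates the schema and reports the
#' first offending column on mismatch.
#'
#' @param results Data frame from [results_table()].
#' @param path File path.
#' @export
write_results <- function(results, path) {
  miss <- setdiff(.results_schema, names(results))
  if (length(miss)) stop("results table missing column: ", miss[1])
  out <- results[, .results_schema]
  for (col in c("Q", "PVALUE", "FDR"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  miss <- setdiff(.results_schema, names(df))
  if (length(miss)) stop("results file missing column: ", miss[1])
  for (col in c("Q", "PVALUE", "FDR")) df[[col]] <- as.numeric(df[[col]])
  for (col in c("START", "END", "N_SNPS")) df[[col]] <- as.integer(df[[col]])
  df$GENE_ID <- as.character(df$GENE_ID)
  df
}
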