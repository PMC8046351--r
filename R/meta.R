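#' Fisher's method for combining per-cohort p-values
#'
#' `X = -2 sum log(p_i)` referred to a chi-square with `2k` degrees of
#' freedom (upper tail). Exact p-values of zero are clipped to 1e-300 and
#' flagged. With a single study the meta p-value equals the input.
#'
#' @param pvals Vector of p-values in `(0, 1]`.
#' @param gene_id Optional identifier carried through.
#' @return An object of class `MetaResult` with fields `gene_id`,
#'   `per_study_p`, `fisher_stat`, `df`, `meta_p`, `flags`.
#' @export
fisher_meta <- function(pvals, gene_id = NA_character_) {
  pvals <- as.numeric(pvals)
  if (length(pvals) < 1L) stop("need at least one p-value")
  if (any(is.na(pvals) | pvals > 1 | pvals < 0))
    stop("p-values must lie in [0, 1]")
  flags <- character(0)
  if (any(pvals == 0)) {
    pvals[pvals == 0] <- 1e-300
    flags <- "clipped_zero_p"
  }
  stat <- -2 * sum(log(pvals))
  df <- 2L * length(pvals)
  meta_p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(gene_id = gene_id, per_study_p = pvals,
                 fisher_stat = stat, df = df,
                 meta_p = max(meta_p, 1e-300), flags = flags),
            class = "MetaResult")
}

#' @export
print.MetaResult <- function(x, ...) {
  cat(sprintf("MetaResult[%s]: X2 = %.4f (df %d), meta p = %.4g\n",
              x$gene_id, x$fisher_stat, x$df, x$meta_p))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; a thin, schema-stable wrapper over
#' `stats::p.adjust(method = "BH")`. `NA` inputs propagate.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
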