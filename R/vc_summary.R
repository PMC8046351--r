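#' GWAS summary statistics for one gene's SNPs
#'
#' @param snp_info Data frame with `chrom`, `pos`, `ref`, `alt`
#'   (optional `snp_id`).
#' @param beta_hat Per-SNP marginal effect estimates.
#' @param se Per-SNP standard errors (> 0).
#' @param n_gwas Scalar or per-SNP GWAS sample size.
#' @return An object of class `SummaryStats`.
#' @export
summary_stats <- function(snp_info, beta_hat, se, n_gwas) {
  if (is.null(snp_info$snp_id))
    snp_info$snp_id <- paste(snp_info$chrom, snp_info$pos,
                             snp_info$ref, snp_info$alt, sep = ":")
  beta_hat <- as.numeric(beta_hat); se <- as.numeric(se)
  stopifnot(length(beta_hat) == nrow(snp_info), length(se) == length(beta_hat),
            all(is.finite(beta_hat)), all(is.finite(se)), all(se > 0))
  n_gwas <- if (length(n_gwas) == 1L) rep(as.numeric(n_gwas), length(se))
            else as.numeric(n_gwas)
  stopifnot(length(n_gwas) == length(se), all(n_gwas > 1))
  structure(list(snp_ids = snp_info$snp_id, snp_info = snp_info,
                 beta_hat = beta_hat, se = se, n_gwas = n_gwas),
            class = "SummaryStats")
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat(sprintf("SummaryStats: %d SNPs, median n = %g\n",
              length(x$snp_ids), stats::median(x$n_gwas)))
  invisible(x)
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Expected header: `CHROM POS REF ALT SNP_ID BETA SE N`.
#'
#' @param path File path.
#' @return A `SummaryStats` object.
#' @export
read_gwas_summary <- function(path) {
  dt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("CHROM", "POS", "REF", "ALT", "BETA", "SE", "N")
  if (!all(need %in% names(dt)))
    stop("summary file must contain columns: ", paste(need, collapse = " "))
  info <- data.frame(chrom = as.character(dt$CHROM), pos = dt$POS,
                     ref = dt$REF, alt = dt$ALT, stringsAsFactors = FALSE)
  if ("SNP_ID" %in% names(dt)) info$snp_id <- dt$SNP_ID
  summary_stats(info, dt$BETA, dt$SE, dt$N)
}

# Harmonize summary stats to the orientation and SNP set shared by the
# weight set and the LD matrix. Joins by chrom:pos, flips the sign of
# beta_hat on ref/alt swap, drops strand-ambiguous mismatches and SNPs
# absent from weights or LD. Returns list(ss, ws, ld, n_dropped) with all
# three objects on the same ordered SNP set.
harmonize_summary_inputs <- function(ss, ws, ld) {
  key_ld <- ld$snp_ids
  idx_w <- match(key_ld, ws$snp_ids)
  key_ss <- paste(ss$snp_info$chrom, ss$snp_info$pos)
  key_wpos <- paste(ws$snp_info$chrom, ws$snp_info$pos)
  keep <- integer(0); beta <- numeric(0); se <- numeric(0); nn <- numeric(0)
  for (j in seq_along(key_ld)) {
    i <- idx_w[j]
    if (is.na(i)) next
    k <- match(key_wpos[i], key_ss)
    if (is.na(k)) next
    r <- toupper(ss$snp_info$ref[k]); a <- toupper(ss$snp_info$alt[k])
    R <- toupper(ws$snp_info$ref[i]); A <- toupper(ws$snp_info$alt[i])
    b <- ss$beta_hat[k]; ok <- FALSE
    if (r == R && a == A) ok <- TRUE
    else if (r == A && a == R) { b <- -b; ok <- TRUE }
    else if (!.strand_ambiguous(r, a)) {
      rc <- .allele_complement(r); ac <- .allele_complement(a)
      if (rc == R && ac == A) ok <- TRUE
      else if (rc == A && ac == R) { b <- -b; ok <- TRUE }
    }
    if (!ok) next
    keep <- c(keep, j); beta <- c(beta, b); se <- c(se, ss$se[k])
    nn <- c(nn, ss$n_gwas[k])
  }
  ws2 <- weight_set(ws$gene_id,
                    ws$snp_info[idx_w[keep], , drop = FALSE],
                    ws$weights[idx_w[keep]], ws$method_tag,
                    cv_r2 = ws$cv_r2, n_train = ws$n_train)
  ld2 <- structure(list(snp_ids = key_ld[keep],
                        sigma = ld$sigma[keep, keep, drop = FALSE],
                        n_ref = ld$n_ref, ridge = ld$ridge),
                   class = "LDMatrix")
  ss2 <- summary_stats(ws2$snp_info, beta, se, nn)
  list(ss = ss2, ws = ws2, ld = ld2,
       n_dropped = length(ss$snp_ids) - length(keep))
}

#' Estimate the phenotype variance from summary statistics
#'
#' `sigma_Y^2 = median_j( Sigma_jj * se_j^2 * (n_j - 1) + Sigma_jj *
#' beta_j^2 )`, the gene-local median over the gene's SNPs.
#'
#' @param ss A `SummaryStats` object, SNP-matched and ordered to `ld`.
#' @param ld An `LDMatrix` on the same SNPs.
#' @return Positive scalar estimate of `Var(Y)`.
#' @export
estimate_phenotype_variance <- function(ss, ld) {
  m <- length(ss$snp_ids)
  if (m == 0L) stop("empty SNP set")
  if (m != length(ld$snp_ids)) stop("summary/LD SNP sets differ")
  d <- diag(ld$sigma)
  v <- stats::median(d * ss$se^2 * (ss$n_gwas - 1) + d * ss$beta_hat^2)
  if (!is.finite(v) || v <= 0)
    stop("non-positive phenotype-variance estimate; inconsistent inputs")
  v
}

#' Reconstruct single-variant score statistics from summary statistics
#'
#' `s_j = (n_j - 1) * beta_j * Sigma_jj / sigma_Y^2`, the score
#' `G_j' Y / sigma_Y^2` recovered from marginal GWAS results and reference
#' LD diagonals.
#'
#' @inheritParams estimate_phenotype_variance
#' @param sigma2_y Positive phenotype-variance estimate.
#' @return Numeric vector of score statistics, one per SNP.
#' @export
estimate_score_statistics <- function(ss, ld, sigma2_y) {
  if (sigma2_y <= 0) stop("'sigma2_y' must be positive")
  unname((ss$n_gwas - 1) * ss$beta_hat * diag(ld$sigma) / sigma2_y)
}

#' Summary-level VC score statistic
#'
#' `Q = sum_j w_j^2 s_j^2`, the simplified quadratic form obtained when the
#' null phenotype mean is zero (covariate-adjusted summary GWAS).
#'
#' @param ws A `WeightSet`.
#' @param scores Score-statistic vector from
#'   [estimate_score_statistics()], same length and order.
#' @return Non-negative scalar.
#' @export
compute_q_summary <- function(ws, scores) {
  if (length(ws$weights) != length(scores))
    stop("weight/score length mismatch")
  sum((ws$weights * scores)^2)
}

#' Null-mixture eigenvalues for the summary-level VC statistic
#'
#' Under the null, `Cov(s) = ((n - 1) / sigma_Y^2) * Sigma`, so the
#' statistic is distributed as the eigenvalues of
#' `((n - 1) / sigma_Y^2) * W^{1/2} Sigma W^{1/2}` weighting independent
#' 1-df chi-squares. The median of per-SNP sample sizes is used for `n`.
#'
#' @inheritParams compute_q_summary
#' @param ld An `LDMatrix` on the same SNPs.
#' @param n_gwas Scalar or per-SNP sample sizes.
#' @param sigma2_y Positive phenotype-variance estimate.
#' @return Non-negative eigenvalue vector.
#' @export
summary_null_eigenvalues <- function(ws, ld, n_gwas, sigma2_y) {
  if (sigma2_y <= 0) stop("'sigma2_y' must be positive")
  w <- abs(ws$weights)
  nz <- w > 0
  if (!any(nz)) return(numeric(0))
  wv <- w[nz]
  B <- (stats::median(n_gwas) - 1) / sigma2_y *
    (outer(wv, wv) * ld$sigma[nz, nz, drop = FALSE])
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  .clean_eigenvalues(ev)
}

#' Variance-component TWAS test for one gene (summary-level data)
#'
#' Harmonizes GWAS summary statistics, reference LD and SNP weights to a
#' common SNP set and orientation, estimates the phenotype variance,
#' reconstructs single-variant scores, and computes the mixture p-value.
#'
#' As in the individual-level test, the phenotype variance entering the
#' null mixture is estimated from the same data and is positively dependent
#' on the score statistic. `dispersion = "exact"` (the default) refers
#' `Q * sigma2_hat_Y` to the exact finite-sample null of the ratio -
#' a signed chi-square mixture marginalizing a chi-square variance
#' estimator with `n - 1` degrees of freedom - matching the individual-
#' level construction so that the two tests agree on shared data;
#' `"plugin"` uses the classical mixture with `sigma2_hat_Y` plugged in.
#'
#' @param ss A `SummaryStats` object.
#' @param ld An `LDMatrix` (reference panel).
#' @param ws A `WeightSet`.
#' @param gene_id Identifier stored in the result.
#' @param dispersion `"exact"` or `"plugin"` (see Details).
#' @return A `VCResult`. SNPs present in the summary data but absent from
#'   LD or weights are dropped; their count is recorded in the
#'   `method_flags` as `"dropped_k"` when positive.
#' @export
vc_twas_ss_gene <- function(ss, ld, ws, gene_id = ws$gene_id,
                            dispersion = c("exact", "plugin")) {
  dispersion <- match.arg(dispersion)
  h <- harmonize_summary_inputs(ss, ws, ld)
  flags <- character(0)
  if (h$n_dropped > 0) flags <- c(flags, sprintf("dropped_%d", h$n_dropped))
  if (length(h$ss$snp_ids) == 0L || all(h$ws$weights == 0))
    return(vc_result(gene_id, NA_real_, NA_real_, 0L, numeric(0),
                     c(flags, "empty_gene")))
  s2y <- estimate_phenotype_variance(h$ss, h$ld)
  s <- estimate_score_statistics(h$ss, h$ld, s2y)
  q <- compute_q_summary(h$ws, s)
  lam <- summary_null_eigenvalues(h$ws, h$ld, h$ss$n_gwas, s2y)
  if (isTRUE(attr(lam, "indefinite"))) flags <- c(flags, "indefinite_matrix")
  if (dispersion == "exact") {
    # lam * s2y are the unit-variance eigenvalues (n-1) W^1/2 Sigma W^1/2
    N <- stats::median(h$ss$n_gwas) - 1
    p <- .qf_tail_ratio_exact(q * s2y, as.numeric(lam) * s2y, N)
    flags <- c(flags, "exact_dispersion")
  } else {
    p <- pvalue_mixture_chisq(q, lam)
    if (attr(p, "method") == "liu") flags <- c(flags, "liu_fallback")
  }
  res <- vc_result(gene_id, q, as.numeric(p),
                   sum(h$ws$weights != 0), as.numeric(lam), flags)
  res$sigma2_y <- s2y
  res
}
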