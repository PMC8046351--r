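#' Variance-component score statistic from individual-level data
#'
#' `Q = (Y - mu_hat)' G W G' (Y - mu_hat)` with `W = diag(w_j^2)`. The
#' default evaluation is the m-dimensional score form
#' `sum_j w_j^2 (G_j' r)^2`, which never materializes the n-by-n kernel;
#' `use_kernel = TRUE` builds the kernel explicitly (retained for testing).
#'
#' @param geno A `GenotypeMatrix` whose SNPs are matched and ordered to
#'   `ws` (see [match_weights_to_genotype()]).
#' @param ws A `WeightSet` aligned to `geno`.
#' @param null A `NullModel` for the same samples.
#' @param use_kernel Evaluate via the explicit `n x n` kernel instead.
#' @return Non-negative scalar `Q`, or `NA` with attribute
#'   `"empty_gene" = TRUE` when no SNPs are available.
#' @export
compute_q_individual <- function(geno, ws, null, use_kernel = FALSE) {
  al <- .align_test(geno, ws, null)
  if (is.null(al)) {
    out <- NA_real_; attr(out, "empty_gene") <- TRUE
    return(out)
  }
  r <- al$resid
  if (use_kernel) {
    K <- al$G %*% diag(al$w^2, length(al$w)) %*% t(al$G)
    return(as.numeric(r %*% K %*% r))
  }
  s <- as.numeric(crossprod(al$G, r))
  sum((al$w * s)^2)
}

# match ws SNPs into geno columns and samples into the null model order;
# returns NULL as the empty-gene signal
.align_test <- function(geno, ws, null) {
  idx <- match(ws$snp_ids, geno$snp_ids)
  ok <- !is.na(idx)
  if (!any(ok)) return(NULL)
  G <- geno$dosages[, idx[ok], drop = FALSE]
  w <- ws$weights[ok]
  if (!is.null(null$sample_ids) &&
      !identical(geno$sample_ids, null$sample_ids)) {
    pos <- match(null$sample_ids, geno$sample_ids)
    if (anyNA(pos)) stop("sample ids of genotype and null model do not match")
    G <- G[pos, , drop = FALSE]
  } else if (nrow(G) != length(null$resid)) {
    stop("genotype/null-model sample count mismatch")
  }
  list(G = G, w = w, resid = null$resid)
}

#' Eigenvalues of the null distribution of the VC score statistic
#'
#' Under H0 the statistic is distributed as `sum_k lambda_k chisq_1`. With
#' covariates adjusted by the standard variance-component projector:
#' gaussian - `lambda = eig( sigma2_hat * W^{1/2} G'(I - H) G W^{1/2} )`
#' with `H` the covariate hat matrix; binomial -
#' `lambda = eig( W^{1/2} G'(V - VZ(Z'VZ)^{-1}Z'V) G W^{1/2} )`,
#' `V = diag(mu(1-mu))`. The decomposition is taken on the smaller of the
#' m-by-m and n-by-n forms (identical nonzero spectra). Eigenvalues below
#' `1e-8 * max` are dropped; tiny negatives are clamped to zero and a
#' `"indefinite"` attribute is set if any negative exceeds `1e-6 * max` in
#' magnitude.
#'
#' @inheritParams compute_q_individual
#' @return Non-negative eigenvalue vector (possibly empty when all weights
#'   are zero or the gene is empty).
#' @export
null_mixture_eigenvalues <- function(geno, ws, null) {
  al <- .align_test(geno, ws, null)
  if (is.null(al)) return(numeric(0))
  w <- abs(al$w)
  nz <- w > 0
  if (!any(nz)) return(numeric(0))
  G <- al$G[, nz, drop = FALSE]
  Gw <- sweep(G, 2, w[nz], `*`)
  if (null$family == "gaussian") {
    Z <- null$Z
    M <- Gw - Z %*% solve(crossprod(Z), crossprod(Z, Gw))
    scale <- null$dispersion
  } else {
    v <- null$dispersion
    sv <- sqrt(v)
    Xv <- sv * null$Z
    Mv <- sv * Gw
    M <- Mv - Xv %*% solve(crossprod(Xv), crossprod(Xv, Mv))
    scale <- 1
  }
  A <- if (ncol(M) <= nrow(M)) crossprod(M) else tcrossprod(M)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values * scale
  .clean_eigenvalues(ev)
}

.clean_eigenvalues <- function(ev, rel_trunc = 1e-8, neg_flag = 1e-6) {
  if (length(ev) == 0L) return(numeric(0))
  mx <- max(ev)
  if (mx <= 0) return(numeric(0))
  indefinite <- any(ev < -neg_flag * mx)
  ev <- ev[ev > rel_trunc * mx]
  out <- pmax(ev, 0)
  if (indefinite) attr(out, "indefinite") <- TRUE
  out
}

#' Variance-component TWAS test for one gene (individual-level data)
#'
#' Composes the score statistic, the null-mixture eigenvalues, and the
#' mixture-of-chi-square tail probability into a gene-level association
#' test of H0: tau = 0 (equivalently, all SNP effects zero).
#'
#' For a gaussian phenotype the residual variance entering the null mixture
#' is itself estimated from the same residuals, and the score statistic and
#' the variance estimate are positively dependent. `dispersion = "exact"`
#' (the default) refers the ratio `Q / sigma2_hat` to its exact
#' finite-sample null - a signed mixture of chi-squares marginalizing the
#' variance estimate - which stays calibrated even when the number of
#' weighted SNP directions approaches the sample size; it converges to the
#' plug-in mixture as `n` grows. `dispersion = "plugin"` uses the classical
#' construction (eigenvalues scaled by `sigma2_hat`), under which the
#' single-SNP test is algebraically identical to the 1-df score test.
#' Binomial phenotypes have no estimated dispersion and are unaffected.
#'
#' @inheritParams compute_q_individual
#' @param gene_id Identifier stored in the result (default from `ws`).
#' @param dispersion `"exact"` or `"plugin"` handling of the estimated
#'   gaussian residual variance (see Details).
#' @return An object of class `VCResult` with fields `gene_id`, `q_stat`,
#'   `p_value`, `m_snps_used`, `eigenvalues`, `method_flags`. For an empty
#'   gene (no matched SNPs or all weights zero) `p_value` is `NA` and the
#'   flag `"empty_gene"` is recorded.
#' @export
vc_twas_gene <- function(geno, ws, null, gene_id = ws$gene_id,
                         dispersion = c("exact", "plugin")) {
  dispersion <- match.arg(dispersion)
  q <- compute_q_individual(geno, ws, null)
  flags <- character(0)
  if (is.na(q)) {
    return(vc_result(gene_id, NA_real_, NA_real_, 0L, numeric(0),
                     "empty_gene"))
  }
  lam <- null_mixture_eigenvalues(geno, ws, null)
  if (length(lam) == 0L)
    return(vc_result(gene_id, q, NA_real_, 0L, numeric(0), "empty_gene"))
  if (isTRUE(attr(lam, "indefinite"))) flags <- c(flags, "indefinite_matrix")
  if (null$family == "gaussian" && dispersion == "exact") {
    N <- length(null$resid) - ncol(null$Z)
    p <- .qf_tail_ratio_exact(q / null$dispersion,
                              as.numeric(lam) / null$dispersion, N)
    flags <- c(flags, "exact_dispersion")
  } else {
    p <- pvalue_mixture_chisq(q, lam)
    if (attr(p, "method") == "liu") flags <- c(flags, "liu_fallback")
  }
  m_used <- sum(!is.na(match(ws$snp_ids, geno$snp_ids)) & ws$weights != 0)
  vc_result(gene_id, q, as.numeric(p), m_used, as.numeric(lam), flags)
}

vc_result <- function(gene_id, q, p, m, lam, flags = character(0)) {
  structure(list(gene_id = gene_id, q_stat = q, p_value = p,
                 m_snps_used = as.integer(m), eigenvalues = lam,
                 method_flags = flags),
            class = "VCResult")
}

#' @export
print.VCResult <- function(x, ...) {
  cat(sprintf("VCResult[%s]: Q = %s, p = %s, m = %d%s\n", x$gene_id,
              format(x$q_stat, digits = 6), format(x$p_value, digits = 4),
              x$m_snps_used,
              if (length(x$method_flags))
                paste0(" [", paste(x$method_flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
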