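#' Impute genetically regulated expression (GReX)
#'
#' `GReX = G_new %*% w_hat`: the weighted sum of test-cohort dosages by
#' reference eQTL effect-size estimates.
#'
#' @param geno A `GenotypeMatrix` for the test samples.
#' @param ws A `WeightSet`; SNPs are matched by id into `geno`.
#' @return A named numeric vector of class `GReXVector`, or `NA` with
#'   attribute `"empty_gene"` when no SNPs match.
#' @export
impute_grex <- function(geno, ws) {
  idx <- match(ws$snp_ids, geno$snp_ids)
  ok <- !is.na(idx)
  if (!any(ok)) {
    out <- NA_real_; attr(out, "empty_gene") <- TRUE
    return(out)
  }
  vals <- as.numeric(geno$dosages[, idx[ok], drop = FALSE] %*% ws$weights[ok])
  structure(stats::setNames(vals, geno$sample_ids),
            class = c("GReXVector", "numeric"))
}

#' Weighted-burden TWAS test (individual-level data)
#'
#' Regresses the phenotype on imputed GReX plus covariates in a GLM
#' (`gaussian` identity or `binomial` logit link) and reports the Wald
#' test of the GReX coefficient.
#'
#' @param grex A `GReXVector` (or numeric vector).
#' @param y Phenotype vector.
#' @param Z Optional covariate matrix (intercept appended if absent).
#' @param family `"gaussian"` or `"binomial"`.
#' @return List with `p_value`, `beta`, `se`, `zstat`, and `reason`
#'   (`NA_character_` normally; `"constant_grex"` or `"empty_gene"` with an
#'   `NA` p-value otherwise).
#' @export
burden_test_individual <- function(grex, y, Z = NULL,
                                   family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (length(grex) == 1L && is.na(grex))
    return(list(p_value = NA_real_, beta = NA_real_, se = NA_real_,
                zstat = NA_real_, reason = "empty_gene"))
  x <- as.numeric(grex)
  if (stats::var(x) == 0)
    return(list(p_value = NA_real_, beta = NA_real_, se = NA_real_,
                zstat = NA_real_, reason = "constant_grex"))
  n <- length(x)
  if (is.null(Z)) {
    X <- cbind(intercept = 1, grex = x)
  } else {
    Z <- as.matrix(Z)
    if (!any(apply(Z, 2, function(col) all(col == col[1]))))
      Z <- cbind(intercept = 1, Z)
    X <- cbind(grex = x, Z)
  }
  if (family == "gaussian") {
    fit <- stats::lm.fit(X, as.numeric(y))
    k <- which(colnames(X) == "grex")
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (n - ncol(X))
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * XtXinv[k, k])
    b <- fit$coefficients[k]
    z <- b / se
    p <- 2 * stats::pt(-abs(z), df = n - ncol(X))
  } else {
    fit <- stats::glm.fit(X, as.numeric(y), family = stats::binomial())
    if (!fit$converged)
      return(list(p_value = NA_real_, beta = NA_real_, se = NA_real_,
                  zstat = NA_real_, reason = "nonconvergence"))
    k <- which(colnames(X) == "grex")
    v <- fit$weights
    XtVXinv <- chol2inv(chol(crossprod(X * sqrt(v))))
    b <- fit$coefficients[k]
    se <- sqrt(XtVXinv[k, k])
    z <- b / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p_value = as.numeric(p), beta = as.numeric(b), se = as.numeric(se),
       zstat = as.numeric(z), reason = NA_character_)
}

#' Weighted-burden TWAS test (summary-level data)
#'
#' Summary-level analogue of the GReX regression:
#' `Z_burden = sum_j w_j s_j / sqrt(((n - 1) / sigma_Y^2) * w' Sigma w)`,
#' referred to a standard normal (two-sided).
#'
#' @param ws A `WeightSet`.
#' @param ss A `SummaryStats` object.
#' @param ld An `LDMatrix` (reference panel).
#' @param sigma2_y Optional phenotype-variance estimate; computed from the
#'   gene's SNPs when `NULL`.
#' @return List with `p_value`, `zstat`, `reason`.
#' @export
burden_test_summary <- function(ws, ss, ld, sigma2_y = NULL) {
  h <- harmonize_summary_inputs(ss, ws, ld)
  if (length(h$ss$snp_ids) == 0L)
    return(list(p_value = NA_real_, zstat = NA_real_, reason = "empty_gene"))
  if (is.null(sigma2_y)) sigma2_y <- estimate_phenotype_variance(h$ss, h$ld)
  s <- estimate_score_statistics(h$ss, h$ld, sigma2_y)
  w <- h$ws$weights
  denom2 <- (stats::median(h$ss$n_gwas) - 1) / sigma2_y *
    as.numeric(t(w) %*% h$ld$sigma %*% w)
  if (!is.finite(denom2) || denom2 <= 0)
    return(list(p_value = NA_real_, zstat = NA_real_,
                reason = "degenerate_denominator"))
  z <- sum(w * s) / sqrt(denom2)
  list(p_value = 2 * stats::pnorm(-abs(z)), zstat = z,
       reason = NA_character_)
}
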