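#' Fit the covariate-only null model
#'
#' Fits the phenotype on covariates alone (H0 of no genetic effect):
#' ordinary least squares for `family = "gaussian"`, maximum-likelihood
#' logistic regression for `family = "binomial"`. The fitted means, the
#' residuals `Y - mu_hat` and the residual variance structure feed the
#' variance-component score statistic and its null distribution.
#'
#' @param y Phenotype vector (numeric; 0/1 for binomial), optionally named
#'   by sample id.
#' @param Z Covariate matrix (`n x q`); an intercept column is appended if
#'   no constant column is present. `NULL` means intercept only.
#' @param family `"gaussian"` or `"binomial"`.
#' @return An object of class `NullModel` with fields `family`, `mu_hat`,
#'   `alpha_hat`, `resid`, `dispersion` (scalar residual variance for
#'   gaussian, per-sample `mu(1-mu)` for binomial), `Z`, `sample_ids`.
#' @export
fit_null_model <- function(y, Z = NULL, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  sample_ids <- names(y)
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("missing values in phenotype")
  if (is.null(Z)) {
    Z <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  } else {
    Z <- as.matrix(Z)
    if (nrow(Z) != n) stop("covariate/phenotype dimension mismatch")
    if (anyNA(Z)) stop("missing values in covariates")
    if (!any(apply(Z, 2, function(col) all(col == col[1]))))
      Z <- cbind(intercept = 1, Z)
  }
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    drop <- setdiff(seq_len(ncol(Z)), qrz$pivot[seq_len(qrz$rank)])
    warning(sprintf("dropping %d collinear covariate column(s)", length(drop)))
    Z <- Z[, qrz$pivot[seq_len(qrz$rank)], drop = FALSE]
  }
  if (family == "gaussian") {
    fit <- stats::lm.fit(Z, y)
    mu <- as.numeric(fit$fitted.values)
    resid <- y - mu
    disp <- sum(resid^2) / (n - ncol(Z))
    alpha <- fit$coefficients
  } else {
    if (!all(y %in% c(0, 1))) stop("binomial phenotype must be 0/1")
    fit <- stats::glm.fit(Z, y, family = stats::binomial())
    if (!fit$converged)
      stop("logistic null model did not converge (possible separation)")
    mu <- fit$fitted.values
    if (any(mu < 1e-10 | mu > 1 - 1e-10))
      stop("fitted probabilities numerically 0 or 1 (separation)")
    resid <- y - mu
    disp <- mu * (1 - mu)
    alpha <- fit$coefficients
  }
  structure(list(family = family, mu_hat = mu, alpha_hat = alpha,
                 resid = resid, dispersion = disp, Z = Z,
                 sample_ids = sample_ids),
            class = "NullModel")
}

#' @export
print.NullModel <- function(x, ...) {
  cat(sprintf("NullModel: %s, n = %d, q = %d covariates\n",
              x$family, length(x$resid), ncol(x$Z)))
  invisible(x)
}
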