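#' Expression vector for one gene
#'
#' @param values Numeric vector of expression levels.
#' @param sample_ids Character identifiers, same length.
#' @return A named numeric vector of class `ExpressionVector`.
#' @export
expression_vector <- function(values, sample_ids) {
  stopifnot(length(values) == length(sample_ids), all(is.finite(values)))
  structure(stats::setNames(as.numeric(values), as.character(sample_ids)),
            class = c("ExpressionVector", "numeric"))
}

#' Per-gene SNP weight set
#'
#' Holds reference cis-eQTL effect-size estimates (signed weights, one per
#' SNP) plus training metadata. Weights act as variant weights in all tests:
#' the variance-component test uses their squares, the burden test their
#' signed values.
#'
#' @param gene_id Gene identifier.
#' @param snp_info Data frame with `chrom`, `pos`, `ref`, `alt`
#'   (and optional `snp_id`).
#' @param weights Numeric vector, one weight per SNP, finite.
#' @param method_tag One of `"elastic_net"`, `"dpr_external"`,
#'   `"ridge_standin"`, `"bgw_external"`.
#' @param cv_r2 5-fold cross-validated prediction R^2 (may be negative).
#' @param n_train Training sample count (optional).
#' @param base_median Stored median absolute weight of the unfiltered set;
#'   carried through filtering so the per-gene-median filter is idempotent.
#' @return An object of class `WeightSet`.
#' @export
weight_set <- function(gene_id, snp_info, weights,
                       method_tag = c("elastic_net", "dpr_external",
                                      "ridge_standin", "bgw_external"),
                       cv_r2 = NA_real_, n_train = NA_integer_,
                       base_median = NULL) {
  method_tag <- match.arg(method_tag)
  if (is.null(snp_info$snp_id))
    snp_info$snp_id <- paste(snp_info$chrom, snp_info$pos,
                             snp_info$ref, snp_info$alt, sep = ":")
  weights <- as.numeric(weights)
  stopifnot(length(weights) == nrow(snp_info), all(is.finite(weights)))
  structure(list(gene_id = gene_id, snp_ids = snp_info$snp_id,
                 snp_info = snp_info, weights = weights,
                 method_tag = method_tag, cv_r2 = cv_r2,
                 n_train = n_train,
                 base_median = base_median %||% stats::median(abs(weights))),
            class = "WeightSet")
}

#' @export
print.WeightSet <- function(x, ...) {
  cat(sprintf("WeightSet[%s]: %d SNPs (%d nonzero), method = %s, cv_r2 = %s\n",
              x$gene_id, length(x$weights), sum(x$weights != 0),
              x$method_tag,
              if (is.na(x$cv_r2)) "NA" else sprintf("%.4f", x$cv_r2)))
  invisible(x)
}

# align expression sample ids to genotype rows; error on mismatch
.align_training <- function(expr, geno) {
  ids <- names(expr)
  if (is.null(ids)) {
    if (length(expr) != nrow(geno$dosages))
      stop("expression/genotype sample misalignment")
    return(list(y = as.numeric(expr), X = geno$dosages))
  }
  if (!all(ids %in% geno$sample_ids))
    stop("expression/genotype sample misalignment: unknown sample ids")
  list(y = as.numeric(expr), X = geno$dosages[ids, , drop = FALSE])
}

#' Train elastic-net cis-eQTL weights
#'
#' Penalized linear regression of expression on dosages (PrediXcan-style),
#' mixing parameter `alpha` (default 0.5), penalty chosen by seeded k-fold
#' cross-validation minimizing MSE. Genotypes and expression are centered
#' but not scaled, so coefficients apply directly to dosages.
#'
#' @param expr An `ExpressionVector` (or named numeric vector).
#' @param geno A `GenotypeMatrix` for the training samples.
#' @param alpha Elastic-net mixing parameter in `[0, 1]`.
#' @param nfolds Cross-validation fold count (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @param penalty Optional fixed penalty value overriding CV selection.
#' @param gene_id Gene identifier stored in the result.
#' @return A `WeightSet` with `method_tag = "elastic_net"` and `cv_r2` the
#'   cross-validated prediction R^2 (`1 - cv MSE / var(y)`).
#' @export
fit_elastic_net_weights <- function(expr, geno, alpha = 0.5, nfolds = 5,
                                    seed = 1L, penalty = NULL,
                                    gene_id = "gene") {
  al <- .align_training(expr, geno)
  y <- al$y; X <- al$X
  n <- length(y); m <- ncol(X)
  if (n < 2 * nfolds) stop("need at least 2 x nfolds samples")
  if (stats::var(y) == 0)
    return(weight_set(gene_id, geno$snp_info, rep(0, m), "elastic_net",
                      cv_r2 = 0, n_train = n))
  set.seed(as.integer(seed))
  foldid <- sample(rep(seq_len(nfolds), length.out = n))
  cvfit <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                             standardize = FALSE)
  s <- penalty %||% cvfit$lambda.min
  w <- as.numeric(stats::coef(cvfit$glmnet.fit, s = s, exact = FALSE))[-1]
  i <- which.min(abs(cvfit$lambda - cvfit$lambda.min))
  cv_r2 <- 1 - cvfit$cvm[i] / mean((y - mean(y))^2)
  weight_set(gene_id, geno$snp_info, w, "elastic_net",
             cv_r2 = cv_r2, n_train = n)
}

# SVD ridge solution path: X centered n x m, returns m x length(lam) coefs
.ridge_path <- function(Xc, yc, lam) {
  sv <- svd(Xc, nu = min(dim(Xc)), nv = min(dim(Xc)))
  uty <- crossprod(sv$u, yc)
  shrink <- outer(sv$d, lam, function(d, l) d / (d^2 + l))
  sv$v %*% (shrink * as.numeric(uty))
}

#' Train dense shrinkage ("DPR-like") cis-eQTL weights
#'
#' Ridge regression solved by SVD with the penalty chosen by seeded 5-fold
#' cross-validation over a log-spaced grid. Every SNP receives a finite,
#' generally nonzero weight, mimicking the dense weight profiles produced
#' by nonparametric Bayesian eQTL estimators whose weights this package
#' otherwise consumes from files. Centering conventions match the
#' elastic-net trainer.
#'
#' @inheritParams fit_elastic_net_weights
#' @param lambda Optional fixed ridge penalty (objective
#'   `||y - Xb||^2 + lambda ||b||^2`); by default CV-selected.
#' @param nlambda Grid size for the CV search.
#' @return A `WeightSet` with `method_tag = "ridge_standin"`.
#' @export
fit_ridge_standin_weights <- function(expr, geno, nfolds = 5, seed = 1L,
                                      lambda = NULL, nlambda = 25,
                                      gene_id = "gene") {
  al <- .align_training(expr, geno)
  y <- al$y; X <- al$X
  n <- length(y); m <- ncol(X)
  if (n < 2 * nfolds) stop("need at least 2 x nfolds samples")
  if (stats::var(y) == 0)
    return(weight_set(gene_id, geno$snp_info, rep(0, m), "ridge_standin",
                      cv_r2 = 0, n_train = n))
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar); yc <- y - ybar
  sv <- svd(Xc, nu = min(dim(Xc)), nv = min(dim(Xc)))
  grid <- max(sv$d)^2 * 10^seq(-6, 1, length.out = nlambda)
  if (is.null(lambda)) {
    set.seed(as.integer(seed))
    foldid <- sample(rep(seq_len(nfolds), length.out = n))
    cvmse <- matrix(0, nfolds, length(grid))
    for (k in seq_len(nfolds)) {
      tr <- foldid != k
      xb <- colMeans(X[tr, , drop = FALSE]); yb <- mean(y[tr])
      B <- .ridge_path(sweep(X[tr, , drop = FALSE], 2, xb), y[tr] - yb, grid)
      pred <- sweep(X[!tr, , drop = FALSE], 2, xb) %*% B + yb
      cvmse[k, ] <- colMeans((y[!tr] - pred)^2)
    }
    mse <- colMeans(cvmse)
    lambda <- grid[which.min(mse)]
    cv_r2 <- 1 - min(mse) / mean(yc^2)
  } else {
    cv_r2 <- NA_real_
  }
  uty <- crossprod(sv$u, yc)
  w <- as.numeric(sv$v %*% ((sv$d / (sv$d^2 + lambda)) * as.numeric(uty)))
  ws <- weight_set(gene_id, geno$snp_info, w, "ridge_standin",
                   cv_r2 = cv_r2, n_train = n)
  ws$lambda <- lambda
  ws
}

#' Filter a weight set by effect-size magnitude
#'
#' Two modes: `magnitude_threshold` keeps SNPs with `|w| > threshold`
#' (e.g. the 1e-4 rule used to thin dense weight sets);
#' `per_gene_median` keeps SNPs with `|w|` strictly above the median
#' absolute weight of the gene's *unfiltered* set (recorded at
#' construction), so the filter is idempotent and discards about half the
#' SNPs. Retained weights are unchanged and keep their order.
#'
#' @param ws A `WeightSet`.
#' @param mode `"magnitude_threshold"` or `"per_gene_median"`.
#' @param threshold Non-negative threshold for magnitude mode.
#' @return The filtered `WeightSet` (possibly with zero SNPs).
#' @export
filter_weights <- function(ws, mode = c("magnitude_threshold",
                                        "per_gene_median"),
                           threshold = 0) {
  stopifnot(inherits(ws, "WeightSet"))
  mode <- match.arg(mode)
  if (length(ws$weights) == 0L) stop("'ws' is empty")
  thr <- switch(mode,
    magnitude_threshold = {
      if (threshold < 0) stop("'threshold' must be non-negative")
      threshold
    },
    per_gene_median = ws$base_median)
  keep <- abs(ws$weights) > thr
  out <- weight_set(ws$gene_id, ws$snp_info[keep, , drop = FALSE],
                    ws$weights[keep], ws$method_tag,
                    cv_r2 = ws$cv_r2, n_train = ws$n_train,
                    base_median = ws$base_median)
  out$filter <- list(mode = mode, threshold = thr)
  out
}

#' Gene inclusion rule on cross-validated prediction accuracy
#'
#' A gene enters TWAS reporting when any of its trained weight models
#' predicts expression with 5-fold CV `R^2 > 0.005` (strict inequality).
#'
#' @param ws_a A `WeightSet`.
#' @param ws_b Optional second `WeightSet` (e.g. from the other trainer).
#' @param threshold CV R^2 threshold (default 0.005).
#' @return Logical.
#' @export
gene_passes_cv_filter <- function(ws_a, ws_b = NULL, threshold = 0.005) {
  r2 <- c(ws_a$cv_r2, if (!is.null(ws_b)) ws_b$cv_r2)
  any(!is.na(r2) & r2 > threshold)
}

#' Write / read a per-gene weight file
#'
#' Tab-delimited, TIGAR/PrediXcan-compatible columns
#' `CHROM POS REF ALT GENE_ID WEIGHT [CV_R2] [METHOD]`.
#'
#' @param ws A `WeightSet`.
#' @param path File path.
#' @export
write_weight_file <- function(ws, path) {
  stopifnot(inherits(ws, "WeightSet"))
  df <- data.frame(CHROM = ws$snp_info$chrom, POS = ws$snp_info$pos,
                   REF = ws$snp_info$ref, ALT = ws$snp_info$alt,
                   GENE_ID = ws$gene_id,
                   WEIGHT = sprintf("%.17g", ws$weights),
                   CV_R2 = sprintf("%.17g", ws$cv_r2),
                   METHOD = ws$method_tag,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_file
#' @param gene_id Optional gene to extract when the file holds several.
#' @export
read_weight_file <- function(path, gene_id = NULL) {
  dt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("CHROM", "POS", "REF", "ALT", "GENE_ID", "WEIGHT")
  if (!all(need %in% names(dt)))
    stop("weight file must contain columns: ", paste(need, collapse = " "))
  if (!is.null(gene_id)) dt <- dt[dt$GENE_ID == gene_id, , drop = FALSE]
  if (nrow(dt) == 0L) stop("no rows for requested gene")
  gid <- dt$GENE_ID[1]
  method <- if ("METHOD" %in% names(dt)) dt$METHOD[1] else "dpr_external"
  cv_r2 <- if ("CV_R2" %in% names(dt)) as.numeric(dt$CV_R2[1]) else NA_real_
  weight_set(gid,
             data.frame(chrom = as.character(dt$CHROM), pos = dt$POS,
                        ref = dt$REF, alt = dt$ALT, stringsAsFactors = FALSE),
             as.numeric(dt$WEIGHT), method, cv_r2 = cv_r2)
}

.allele_complement <- function(a) chartr("ACGT", "TGCA", toupper(a))
.strand_ambiguous <- function(ref, alt)
  .allele_complement(ref) == toupper(alt)

#' Match a weight set to test genotypes, harmonizing alleles
#'
#' SNPs are joined by chromosome and position. Weights whose ref/alt match
#' the genotype alleles are kept as is; swapped ref/alt flips the weight
#' sign; strand-flipped (complemented) alleles are accepted unless the SNP
#' is strand-ambiguous (A/T or C/G), in which case it is dropped, as are
#' SNPs whose alleles cannot be reconciled.
#'
#' @param ws A `WeightSet` (e.g. read from file).
#' @param geno A `GenotypeMatrix` defining the target orientation.
#' @return A `WeightSet` aligned to (a subset of) `geno`'s SNPs, in
#'   genotype order, with attribute `"n_dropped"`.
#' @export
match_weights_to_genotype <- function(ws, geno) {
  key_g <- paste(geno$snp_info$chrom, geno$snp_info$pos)
  key_w <- paste(ws$snp_info$chrom, ws$snp_info$pos)
  idx_w <- match(key_g, key_w)
  keep <- integer(0); w_out <- numeric(0)
  for (j in which(!is.na(idx_w))) {
    i <- idx_w[j]
    r <- toupper(ws$snp_info$ref[i]); a <- toupper(ws$snp_info$alt[i])
    R <- toupper(geno$snp_info$ref[j]); A <- toupper(geno$snp_info$alt[j])
    w <- ws$weights[i]
    ok <- FALSE
    if (r == R && a == A) ok <- TRUE
    else if (r == A && a == R) { w <- -w; ok <- TRUE }
    else if (!.strand_ambiguous(r, a)) {
      rc <- .allele_complement(r); ac <- .allele_complement(a)
      if (rc == R && ac == A) ok <- TRUE
      else if (rc == A && ac == R) { w <- -w; ok <- TRUE }
    }
    if (ok) { keep <- c(keep, j); w_out <- c(w_out, w) }
  }
  out <- weight_set(ws$gene_id, geno$snp_info[keep, , drop = FALSE], w_out,
                    ws$method_tag, cv_r2 = ws$cv_r2, n_train = ws$n_train)
  attr(out, "n_dropped") <- length(ws$weights) - length(w_out)
  out
}
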