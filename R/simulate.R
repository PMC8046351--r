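#' Simulation scenario configuration
#'
#' Captures one scenario of the simulation design: LD-structured synthetic
#' genotypes (latent-Gaussian AR(1) blocks as a stand-in for a real cis
#' region), expression traits with target heritability `h2_expr` and causal
#' fraction `p_causal`, and phenotypes under Model I (phenotype driven
#' linearly by genetically regulated expression) or Model II (SNP effects
#' random with variance proportional to squared eQTL effects).
#'
#' Defaults mirror the reference design: 499 training and 1,232 test
#' samples, ~2,800 cis-SNPs with MAF above 5%, AR(1) block correlation 0.5
#' in blocks of 100 SNPs, `p_causal = 0.2`, `h2_expr = 0.1`.
#'
#' @param n_train,n_test Training / test sample counts.
#' @param m_snps Number of cis-SNPs.
#' @param p_causal Causal fraction; the causal set has `ceiling(p_causal *
#'   m_snps)` SNPs.
#' @param h2_expr Expression heritability in `[0, 1)`.
#' @param h2_pheno Phenotype variance proportion due to the genetic signal,
#'   in `[0, 1)`.
#' @param model `"I"` or `"II"`.
#' @param ld_rho AR(1) latent correlation within LD blocks.
#' @param block_size SNPs per LD block.
#' @param maf_range Range from which population MAFs are drawn.
#' @param seed Base RNG seed; all stages derive named substreams from it.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(n_train = 499L, n_test = 1232L, m_snps = 2799L,
                       p_causal = 0.2, h2_expr = 0.1, h2_pheno = 0.15,
                       model = c("II", "I"), ld_rho = 0.5,
                       block_size = 100L, maf_range = c(0.05, 0.5),
                       seed = 1L) {
  model <- match.arg(model)
  stopifnot(p_causal >= 0, p_causal <= 1,
            h2_expr >= 0, h2_expr < 1, h2_pheno >= 0, h2_pheno < 1,
            ld_rho > -1, ld_rho < 1, block_size >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 m_snps = as.integer(m_snps), p_causal = p_causal,
                 h2_expr = h2_expr, h2_pheno = h2_pheno, model = model,
                 ld_rho = ld_rho, block_size = as.integer(block_size),
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(paste0("SimConfig: n_train=%d n_test=%d m=%d p_causal=%g ",
                     "h2_expr=%g h2_pheno=%g model=%s rho=%g seed=%d\n"),
              x$n_train, x$n_test, x$m_snps, x$p_causal, x$h2_expr,
              x$h2_pheno, x$model, x$ld_rho, x$seed))
  invisible(x)
}

# named RNG substreams derived from the base seed (kept below 2^31)
.sub_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 + tag) %% 2147483629)
}

#' Simulate LD-structured genotype dosages
#'
#' Two latent standard-normal haplotypes per sample follow an AR(1)
#' correlation `ld_rho^|i-j|` within blocks of `block_size` SNPs
#' (independent across blocks); each haplotype carries the minor allele
#' when its latent value falls below the MAF quantile. Dosages are the
#' haplotype sums, so genotype frequencies satisfy Hardy-Weinberg
#' equilibrium at population MAFs drawn uniformly from `maf_range` (all
#' above the 5% screening threshold by construction).
#'
#' @param cfg A `SimConfig`.
#' @param n Number of samples (default `n_train + n_test`).
#' @param seed RNG seed (default derived from `cfg$seed`).
#' @return A `GenotypeMatrix` with dosages in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(cfg, n = cfg$n_train + cfg$n_test,
                               seed = .sub_seed(cfg$seed, 1L)) {
  set.seed(seed)
  m <- cfg$m_snps
  mafs <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  thr <- stats::qnorm(mafs)
  rho <- cfg$ld_rho
  dos <- matrix(0L, n, m)
  for (h in 1:2) {
    z <- matrix(0, n, m)
    for (b_start in seq(1, m, by = cfg$block_size)) {
      b_end <- min(b_start + cfg$block_size - 1L, m)
      z[, b_start] <- stats::rnorm(n)
      if (b_end > b_start)
        for (j in (b_start + 1L):b_end)
          z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    dos <- dos + (z < rep(thr, each = n))
  }
  info <- data.frame(chrom = "1", pos = 1000000L + (seq_len(m) - 1L) * 500L,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, sprintf("S%05d", seq_len(n)), info)
  g$pop_maf <- mafs
  g
}

#' Restrict a GenotypeMatrix to a subset of samples
#'
#' @param geno A `GenotypeMatrix`.
#' @param idx Integer or character sample index.
#' @return A `GenotypeMatrix` (MAF recomputed on the subset).
#' @export
subset_genotype_samples <- function(geno, idx) {
  g <- genotype_matrix(geno$dosages[idx, , drop = FALSE],
                       geno$sample_ids[idx], geno$snp_info)
  g$pop_maf <- geno$pop_maf
  g
}

#' Simulate expression traits with target heritability
#'
#' `E = G w + eps_E`: the causal eQTL set of size
#' `ceiling(p_causal * m)` is sampled uniformly, raw effects are drawn
#' `N(0, 1)` and rescaled so the realized variance of the genetic component
#' `G w` equals `h2_expr`; `eps_E ~ N(0, 1 - h2_expr)`, so total expression
#' variance is approximately 1. `h2_expr = 0` yields all-zero weights and
#' pure-noise expression.
#'
#' @param geno A `GenotypeMatrix` (training panel, or full panel when the
#'   same true weights must apply to test samples).
#' @param cfg A `SimConfig`.
#' @param seed RNG seed.
#' @return List with `expr` (an `ExpressionVector` over `geno`'s samples),
#'   `true_w` (length-m vector, zero off the causal set), `causal_idx`.
#' @export
simulate_expression <- function(geno, cfg, seed = .sub_seed(cfg$seed, 2L)) {
  set.seed(seed)
  m <- n_snps(geno)
  n <- nrow(geno$dosages)
  n_causal <- max(1L, as.integer(ceiling(cfg$p_causal * m)))
  causal <- sort(sample.int(m, n_causal))
  w <- rep(0, m)
  if (cfg$h2_expr > 0) {
    w_raw <- stats::rnorm(n_causal)
    g <- as.numeric(geno$dosages[, causal, drop = FALSE] %*% w_raw)
    vg <- stats::var(g)
    if (vg > 0) w[causal] <- w_raw * sqrt(cfg$h2_expr / vg)
  }
  genetic <- as.numeric(geno$dosages %*% w)
  e <- genetic + stats::rnorm(n, 0, sqrt(1 - cfg$h2_expr))
  list(expr = expression_vector(e, geno$sample_ids),
       true_w = w, causal_idx = causal)
}

#' Simulate a phenotype under Model I or Model II
#'
#' Model I: `Y = r * E_g + eps_Y` with `r` calibrated so the realized
#' variance of `r * E_g` equals `h2_pheno` and `eps_Y ~ N(0, 1 -
#' h2_pheno)` - SNP effects on the phenotype are exactly proportional to
#' their eQTL effects (the burden-test assumption). The genetic expression
#' component on `geno`'s samples is re-simulated here (fresh `eps_E`).
#'
#' Model II: `Y = G beta + eps_Y` with `beta_i ~ N(0, r * w_i^2)` on the
#' causal eQTL set and `r` calibrated so the realized variance of
#' `G beta` equals `h2_pheno` - effect magnitudes are no longer a linear
#' function of the eQTL effects, only their variances are.
#'
#' @param geno A `GenotypeMatrix` (test panel).
#' @param expr_bundle Result of [simulate_expression()] (true weights and
#'   causal set; sample-level expression values are re-simulated for
#'   `geno`'s samples under Model I).
#' @param cfg A `SimConfig`.
#' @param seed RNG seed.
#' @return Named numeric phenotype vector with attribute `"genetic"` (the
#'   genetic component).
#' @export
simulate_phenotype <- function(geno, expr_bundle, cfg,
                               seed = .sub_seed(cfg$seed, 3L)) {
  set.seed(seed)
  n <- nrow(geno$dosages)
  h2p <- cfg$h2_pheno
  if (h2p == 0) {
    y <- stats::rnorm(n)
    genetic <- rep(0, n)
  } else if (cfg$model == "I") {
    if (all(expr_bundle$true_w == 0))
      warning("Model I phenotype with zero expression heritability: ",
              "phenotype carries no genetic signal")
    eg <- as.numeric(geno$dosages %*% expr_bundle$true_w) +
      stats::rnorm(n, 0, sqrt(1 - cfg$h2_expr))
    ve <- stats::var(eg)
    r <- if (ve > 0) sqrt(h2p / ve) else 0
    genetic <- r * eg
    y <- genetic + stats::rnorm(n, 0, sqrt(1 - h2p))
  } else {
    causal <- expr_bundle$causal_idx
    wc <- expr_bundle$true_w[causal]
    beta_raw <- stats::rnorm(length(causal), 0, abs(wc))
    g <- as.numeric(geno$dosages[, causal, drop = FALSE] %*% beta_raw)
    vg <- stats::var(g)
    beta <- if (vg > 0) beta_raw * sqrt(h2p / vg) else beta_raw * 0
    genetic <- as.numeric(geno$dosages[, causal, drop = FALSE] %*% beta)
    y <- genetic + stats::rnorm(n, 0, sqrt(1 - h2p))
  }
  structure(stats::setNames(y, geno$sample_ids), genetic = genetic)
}

#' Marginal single-variant GWAS on simulated data
#'
#' Per-SNP simple linear regression of the phenotype on each dosage column
#' (with intercept), vectorized. Produces the effect estimates, standard
#' errors and sample size consumed by the summary-level tests.
#'
#' @param geno A `GenotypeMatrix`.
#' @param y Phenotype vector aligned to `geno`'s samples.
#' @return A `SummaryStats` object.
#' @export
simulate_gwas_summary <- function(geno, y) {
  X <- geno$dosages
  n <- nrow(X)
  xc <- sweep(X, 2, colMeans(X))
  yc <- as.numeric(y) - mean(y)
  sxx <- colSums(xc^2)
  sxy <- as.numeric(crossprod(xc, yc))
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta * sxy
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  summary_stats(geno$snp_info, beta, se, n)
}

# Train the weight sets used by the study harnesses on the training panel.
.train_weight_sets <- function(expr, geno_train, weight_types, seed) {
  out <- list()
  if (any(c("dense", "filtered") %in% weight_types)) {
    dense <- fit_ridge_standin_weights(expr, geno_train, seed = seed,
                                       gene_id = "simgene")
    if ("dense" %in% weight_types) out$dense <- dense
    if ("filtered" %in% weight_types)
      out$filtered <- filter_weights(dense, "per_gene_median")
  }
  if ("sparse" %in% weight_types)
    out$sparse <- fit_elastic_net_weights(expr, geno_train, seed = seed,
                                          gene_id = "simgene")
  out
}

# Per-weight-set precomputation on the test panel for the fast harness:
# weighted genotype columns, unit-dispersion null eigenvalues
# (intercept-only projector), and critical values on the t = Q/sigma2_hat
# scale at the requested upper-tail levels, from the exact finite-sample
# null of the gaussian VC test (the harness default). p < alpha is then
# exactly Q > sigma2_hat * crit.
.vc_precompute <- function(geno_test, ws, alpha_levels) {
  idx <- match(ws$snp_ids, geno_test$snp_ids)
  ok <- !is.na(idx) & ws$weights != 0
  if (!any(ok)) return(NULL)
  Gw <- sweep(geno_test$dosages[, idx[ok], drop = FALSE], 2,
              abs(ws$weights[ok]), `*`)
  Gwc <- sweep(Gw, 2, colMeans(Gw))
  A <- if (ncol(Gwc) <= nrow(Gwc)) crossprod(Gwc) else tcrossprod(Gwc)
  lam0 <- .clean_eigenvalues(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  crit <- vapply(alpha_levels, .qf_ratio_crit, numeric(1),
                 lam0 = as.numeric(lam0), N = nrow(Gwc) - 1L)
  list(Gwc = Gwc, lam0 = as.numeric(lam0), crit = crit,
       grex = as.numeric(geno_test$dosages[, idx[ok], drop = FALSE] %*%
                           ws$weights[ok]))
}

#' Type-I-error study under the null
#'
#' Simulates a training panel, trains the requested weight sets on
#' expression with the scenario's `p_causal` and `h2_expr`, then draws
#' `n_reps` null phenotypes `Y ~ N(0, 1)` for the test samples and records
#' the proportion of replicates significant at each `alpha` for the
#' variance-component and burden tests. Eigen-decompositions and mixture
#' critical values are computed once per weight set and reused across
#' replicates: with an intercept-only Gaussian null, `p < alpha` is
#' equivalent to `Q / sigma2_hat > q_alpha`, an exact reformulation of the
#' per-replicate test.
#'
#' @param cfg A `SimConfig`.
#' @param methods Subset of `c("vc", "burden")`.
#' @param weight_types Subset of `c("dense", "filtered", "sparse")`
#'   (dense ridge stand-in, its median-filtered version, elastic net).
#' @param n_reps Number of null replicates.
#' @param alpha_levels Significance levels evaluated.
#' @param batch_size Replicates per internal batch (memory control).
#' @param seed Base seed (default from `cfg`).
#' @return Data frame with columns `method`, `weights`, `alpha`, `rate`,
#'   `n_reps`, `mc_se`; the trained weight sets are attached as attribute
#'   `"weight_sets"`.
#' @export
run_type1_study <- function(cfg, methods = c("vc", "burden"),
                            weight_types = c("dense", "filtered", "sparse"),
                            n_reps = 1e5, alpha_levels = c(1e-2, 1e-4),
                            batch_size = 5000L, seed = cfg$seed) {
  if (n_reps < 1) stop("'n_reps' must be positive")
  methods <- match.arg(methods, several.ok = TRUE)
  geno <- simulate_genotypes(cfg, seed = .sub_seed(seed, 1L))
  tr <- seq_len(cfg$n_train)
  geno_train <- subset_genotype_samples(geno, tr)
  geno_test <- subset_genotype_samples(geno, cfg$n_train + seq_len(cfg$n_test))
  bundle <- simulate_expression(geno_train, cfg, seed = .sub_seed(seed, 2L))
  wsets <- .train_weight_sets(bundle$expr, geno_train, weight_types,
                              seed = .sub_seed(seed, 3L))
  n <- cfg$n_test
  pre <- lapply(wsets, .vc_precompute, geno_test = geno_test,
                alpha_levels = alpha_levels)
  tcrit <- stats::qt(1 - alpha_levels / 2, df = n - 2)

  counts <- list()
  for (wt in names(wsets)) for (meth in methods)
    counts[[paste(meth, wt, sep = ".")]] <- numeric(length(alpha_levels))

  set.seed(.sub_seed(seed, 4L))
  done <- 0L
  while (done < n_reps) {
    B <- min(batch_size, n_reps - done)
    Y <- matrix(stats::rnorm(n * B), n, B)
    Yc <- sweep(Y, 2, colMeans(Y))
    s2 <- colSums(Yc^2) / (n - 1)
    for (wt in names(wsets)) {
      pc <- pre[[wt]]
      if (is.null(pc)) next
      if ("vc" %in% methods) {
        Q <- colSums(crossprod(pc$Gwc, Yc)^2)
        for (a in seq_along(alpha_levels))
          counts[[paste("vc", wt, sep = ".")]][a] <-
            counts[[paste("vc", wt, sep = ".")]][a] +
            sum(Q > s2 * pc$crit[a])
      }
      if ("burden" %in% methods && stats::var(pc$grex) > 0) {
        xc <- pc$grex - mean(pc$grex)
        sxx <- sum(xc^2)
        b <- as.numeric(crossprod(Yc, xc)) / sxx
        rss <- colSums(Yc^2) - b^2 * sxx
        tt <- b / sqrt(rss / ((n - 2) * sxx))
        for (a in seq_along(alpha_levels))
          counts[[paste("burden", wt, sep = ".")]][a] <-
            counts[[paste("burden", wt, sep = ".")]][a] +
            sum(abs(tt) > tcrit[a])
      }
    }
    done <- done + B
  }

  rows <- list()
  for (wt in names(wsets)) for (meth in methods) {
    key <- paste(meth, wt, sep = ".")
    empty <- is.null(pre[[wt]]) ||
      (meth == "burden" && stats::var(pre[[wt]]$grex) == 0)
    rate <- if (empty) rep(NA_real_, length(alpha_levels))
            else counts[[key]] / n_reps
    rows[[key]] <- data.frame(method = meth, weights = wt,
                              alpha = alpha_levels, rate = rate,
                              n_reps = n_reps,
                              mc_se = sqrt(rate * (1 - rate) / n_reps))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "weight_sets") <- wsets
  out
}

#' Power study under Model I or Model II
#'
#' Uses a fixed genotype panel per scenario. Training expression (and hence
#' the trained weight sets, eigenvalues and critical values) are refreshed
#' every `reps_per_fit` replicates; the phenotype (and, under Model I, the
#' test-sample expression noise) is re-simulated every replicate. Power is
#' the proportion of replicates with p-value below `threshold`.
#'
#' @inheritParams run_type1_study
#' @param n_reps Replicates per scenario.
#' @param reps_per_fit Replicates sharing one weight-training fit.
#' @param test_n Test sample size (default `cfg$n_test`).
#' @param threshold Gene-based genome-wide significance threshold.
#' @return Data frame with `method`, `weights`, `power`, `n_reps`, `mc_se`;
#'   per-replicate significance indicators are attached as attribute
#'   `"indicators"` (replicates x method.weights matrix) for paired
#'   comparisons.
#' @export
run_power_study <- function(cfg, methods = c("vc", "burden"),
                            weight_types = c("dense", "filtered"),
                            n_reps = 1000L, reps_per_fit = 25L,
                            test_n = cfg$n_test, threshold = 2.5e-6,
                            seed = cfg$seed) {
  if (n_reps < 1) stop("'n_reps' must be positive")
  methods <- match.arg(methods, several.ok = TRUE)
  geno <- simulate_genotypes(cfg, seed = .sub_seed(seed, 1L))
  geno_train <- subset_genotype_samples(geno, seq_len(cfg$n_train))
  geno_test <- subset_genotype_samples(geno,
                                       cfg$n_train + seq_len(as.integer(test_n)))
  n <- as.integer(test_n)
  tcrit <- stats::qt(1 - threshold / 2, df = n - 2)

  keys <- as.vector(outer(methods, weight_types, paste, sep = "."))
  hits <- matrix(NA, n_reps, length(keys), dimnames = list(NULL, keys))

  done <- 0L; batch_i <- 0L
  while (done < n_reps) {
    batch_i <- batch_i + 1L
    B <- min(reps_per_fit, n_reps - done)
    bundle <- simulate_expression(geno_train, cfg,
                                  seed = .sub_seed(seed, 100L + batch_i))
    wsets <- .train_weight_sets(bundle$expr, geno_train, weight_types,
                                seed = .sub_seed(seed, 500L + batch_i))
    pre <- lapply(wsets, .vc_precompute, geno_test = geno_test,
                  alpha_levels = threshold)
    Y <- matrix(0, n, B)
    for (b in seq_len(B))
      Y[, b] <- simulate_phenotype(geno_test, bundle, cfg,
                                   seed = .sub_seed(seed,
                                                    1000L + (done + b) * 7L))
    Yc <- sweep(Y, 2, colMeans(Y))
    s2 <- colSums(Yc^2) / (n - 1)
    for (wt in names(wsets)) {
      pc <- pre[[wt]]
      for (meth in methods) {
        key <- paste(meth, wt, sep = ".")
        if (is.null(pc)) { hits[done + seq_len(B), key] <- FALSE; next }
        if (meth == "vc") {
          Q <- colSums(crossprod(pc$Gwc, Yc)^2)
          hits[done + seq_len(B), key] <- Q > s2 * pc$crit[1]
        } else {
          if (stats::var(pc$grex) == 0) {
            hits[done + seq_len(B), key] <- FALSE
          } else {
            xc <- pc$grex - mean(pc$grex)
            sxx <- sum(xc^2)
            bb <- as.numeric(crossprod(Yc, xc)) / sxx
            rss <- colSums(Yc^2) - bb^2 * sxx
            tt <- bb / sqrt(rss / ((n - 2) * sxx))
            hits[done + seq_len(B), key] <- abs(tt) > tcrit
          }
        }
      }
    }
    done <- done + B
  }
  pw <- colMeans(hits)
  out <- data.frame(method = sub("\\..*$", "", keys),
                    weights = sub("^[^.]*\\.", "", keys),
                    power = as.numeric(pw), n_reps = n_reps,
                    mc_se = sqrt(pw * (1 - pw) / n_reps))
  attr(out, "indicators") <- hits
  out
}

#' Paired one-sided power comparison
#'
#' McNemar-style exact binomial test that method `a` is more powerful than
#' method `b`, based on replicates where exactly one of the two is
#' significant.
#'
#' @param hit_a,hit_b Logical significance indicators over the same
#'   replicates.
#' @return List with `n_a_only`, `n_b_only`, `p_value` (one-sided, H1:
#'   a more powerful than b).
#' @export
compare_power_paired <- function(hit_a, hit_b) {
  n10 <- sum(hit_a & !hit_b)
  n01 <- sum(!hit_a & hit_b)
  p <- if (n10 + n01 == 0) 1
       else stats::binom.test(n10, n10 + n01, 0.5,
                              alternative = "greater")$p.value
  list(n_a_only = n10, n_b_only = n01, p_value = p)
}
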