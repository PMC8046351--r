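# Weight training, filtering, and file round-trips.

test_that("elastic net recovers a single causal SNP and stays null on noise", {
  n <- 500; m <- 100
  hits_causal <- 0; null_zero_frac <- 0; null_r2_ok <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    g <- random_geno(n, m, seed = 1000 + r)
    set.seed(2000 + r)
    # pure-noise expression: weights should be (almost) all zero
    e0 <- expression_vector(rnorm(n), g$sample_ids)
    w0 <- fit_elastic_net_weights(e0, g, seed = r)
    null_zero_frac <- null_zero_frac + mean(w0$weights == 0)
    if (w0$cv_r2 <= 0.01) null_r2_ok <- null_r2_ok + 1
    # single causal SNP, effect 1.0, noise sd 0.5
    e1 <- expression_vector(g$dosages[, 17] + rnorm(n, 0, 0.5),
                            g$sample_ids)
    w1 <- fit_elastic_net_weights(e1, g, seed = r)
    if (w1$weights[17] > 0) hits_causal <- hits_causal + 1
  }
  expect_gte(hits_causal / n_rep, 0.95)
  expect_gte(null_zero_frac / n_rep, 0.95)  # >=95% zero weights on average
  expect_gte(null_r2_ok / n_rep, 0.9)
})

test_that("elastic net edge cases: full shrinkage, constant expression, misalignment", {
  g <- random_geno(100, 20, seed = 5)
  set.seed(6)
  e <- expression_vector(g$dosages[, 3] + rnorm(100), g$sample_ids)
  ws <- fit_elastic_net_weights(e, g, seed = 1, penalty = 1e9)
  expect_true(all(ws$weights == 0))
  e_const <- expression_vector(rep(2, 100), g$sample_ids)
  ws0 <- fit_elastic_net_weights(e_const, g, seed = 1)
  expect_true(all(ws0$weights == 0))
  expect_equal(ws0$cv_r2, 0)
  e_bad <- expression_vector(rnorm(100), sprintf("other%03d", 1:100))
  expect_error(fit_elastic_net_weights(e_bad, g), "misalignment")
})

test_that("elastic-net training loss at the fit is below the zero-vector loss", {
  g <- random_geno(200, 30, seed = 8)
  set.seed(9)
  y <- g$dosages[, 5] - 0.5 * g$dosages[, 12] + rnorm(200)
  e <- expression_vector(y, g$sample_ids)
  ws <- fit_elastic_net_weights(e, g, alpha = 0.5, seed = 2)
  X <- sweep(g$dosages, 2, colMeans(g$dosages))
  yc <- y - mean(y)
  enet_loss <- function(b, lam, alpha = 0.5) {
    n <- length(yc)
    sum((yc - X %*% b)^2) / (2 * n) +
      lam * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
  }
  # the CV-selected penalty is not exposed; objective decrease must hold for
  # the penalty at which the coefficients are optimal, so scan the path
  lams <- 10^seq(-4, 1, length.out = 60)
  dec <- vapply(lams, function(l)
    enet_loss(ws$weights, l) <= enet_loss(rep(0, 30), l), logical(1))
  expect_true(any(dec))
})

test_that("ridge stand-in matches closed forms", {
  # m = 1: univariate shrinkage computed by hand
  n <- 80
  set.seed(11)
  x <- rbinom(n, 2, 0.4)
  y <- 0.7 * x + rnorm(n)
  g <- toy_geno(matrix(as.double(x)))
  ws <- fit_ridge_standin_weights(expression_vector(y, g$sample_ids), g,
                                  seed = 1)
  xc <- x - mean(x); yc <- y - mean(y)
  expect_equal(ws$weights,
               sum(xc * yc) / (sum(xc^2) + ws$lambda), tolerance = 1e-10)
  expect_equal(ws$method_tag, "ridge_standin")

  # orthogonal design: each weight strictly between 0 and OLS, same sign
  Xo <- cbind(rep(c(0, 2), each = 20), rep(c(0, 2), times = 20))
  set.seed(12)
  yo <- Xo[, 1] - Xo[, 2] + rnorm(40, 0, 0.3)
  go <- toy_geno(Xo)
  wso <- fit_ridge_standin_weights(expression_vector(yo, go$sample_ids), go,
                                   seed = 1)
  Xc <- sweep(Xo, 2, colMeans(Xo)); yc2 <- yo - mean(yo)
  ols <- as.numeric(solve(crossprod(Xc), crossprod(Xc, yc2)))
  expect_true(all(sign(wso$weights) == sign(ols)))
  expect_true(all(abs(wso$weights) < abs(ols)))
  expect_true(all(abs(wso$weights) > 0))
})

test_that("ridge weights are dense and shrink under null expression", {
  n <- 300; m <- 50
  g <- random_geno(n, m, seed = 21)
  set.seed(22)
  e_null <- expression_vector(rnorm(n), g$sample_ids)
  w_null <- fit_ridge_standin_weights(e_null, g, seed = 1)
  e_sig <- expression_vector(g$dosages[, 25] + rnorm(n, 0, 0.5),
                             g$sample_ids)
  w_sig <- fit_ridge_standin_weights(e_sig, g, seed = 1)
  expect_true(all(is.finite(w_null$weights)))
  expect_gte(mean(w_sig$weights != 0), 0.9)  # dense
  expect_gte(max(abs(w_sig$weights)), 5 * max(abs(w_null$weights)))
})

test_that("weight filtering follows the stated rules", {
  g <- toy_geno(matrix(rbinom(4 * 10, 2, 0.3), 10, 4))
  ws <- toy_weight_set(g, c(2e-4, 5e-5, 1e-3, 0))
  f <- filter_weights(ws, "magnitude_threshold", 1e-4)
  expect_equal(f$snp_ids, ws$snp_ids[c(1, 3)])
  expect_identical(f$weights, ws$weights[c(1, 3)])  # values untouched

  ws2 <- toy_weight_set(g, c(1, 2, 3, 4))
  f2 <- filter_weights(ws2, "per_gene_median")
  expect_equal(f2$weights, c(3, 4))
  expect_error(filter_weights(ws, "magnitude_threshold", -1), "non-negative")
})

test_that("filtering is idempotent and median mode keeps at most ceiling(m/2)", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- sample(3:40, 1)
    g <- toy_geno(matrix(rbinom(m * 10, 2, 0.3), 10, m))
    ws <- toy_weight_set(g, rnorm(m))
    for (mode in c("per_gene_median", "magnitude_threshold")) {
      f1 <- filter_weights(ws, mode, threshold = 0.3)
      if (length(f1$weights) == 0) next
      f2 <- filter_weights(f1, mode, threshold = 0.3)
      expect_identical(f2$weights, f1$weights)
      expect_identical(f2$snp_ids, f1$snp_ids)
    }
    fm <- filter_weights(ws, "per_gene_median")
    expect_lte(length(fm$weights), ceiling(m / 2))
  }
})

test_that("CV R^2 gene-inclusion rule uses strict > 0.005 on either model", {
  g <- toy_geno(matrix(0:1, 2, 1))
  mk <- function(r2) weight_set("g", g$snp_info, 0.1, "elastic_net",
                                cv_r2 = r2)
  expect_true(gene_passes_cv_filter(mk(0.006)))
  expect_false(gene_passes_cv_filter(mk(0.005)))
  expect_true(gene_passes_cv_filter(mk(-0.02), mk(0.2)))
  expect_false(gene_passes_cv_filter(mk(-0.02), mk(0.001)))
})

test_that("weight files round-trip and harmonize alleles on read", {
  g <- random_geno(20, 6, seed = 31)
  set.seed(32)
  ws <- weight_set("geneX", g$snp_info, rnorm(6), "ridge_standin",
                   cv_r2 = 0.123, n_train = 20L)
  path <- tempfile(fileext = ".tsv")
  write_weight_file(ws, path)
  ws2 <- read_weight_file(path)
  expect_equal(ws2$snp_ids, ws$snp_ids)
  expect_equal(ws2$weights, ws$weights, tolerance = 1e-12)
  expect_equal(ws2$cv_r2, ws$cv_r2, tolerance = 1e-12)
  expect_equal(ws2$method_tag, ws$method_tag)

  # allele harmonization: swapped ref/alt flips sign; ambiguous dropped
  info <- data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                     ref = c("A", "G", "A", "C"),
                     alt = c("G", "A", "T", "T"), stringsAsFactors = FALSE)
  gt <- genotype_matrix(matrix(rbinom(4 * 10, 2, 0.3), 10, 4),
                        sprintf("s%03d", 1:10),
                        data.frame(chrom = "1",
                                   pos = c(100L, 200L, 300L, 400L),
                                   ref = "A", alt = "G",
                                   stringsAsFactors = FALSE))
  wsrc <- weight_set("geneY", info, c(0.5, 0.25, 0.1, 0.7), "dpr_external")
  matched <- match_weights_to_genotype(wsrc, gt)
  # SNP1 exact match; SNP2 swapped (flip); SNP3 A/T strand-ambiguous
  # mismatch (dropped); SNP4 C/T complement G/A = swap of A/G (flip)
  expect_equal(matched$weights, c(0.5, -0.25, -0.7))
  expect_equal(attr(matched, "n_dropped"), 1L)
})
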