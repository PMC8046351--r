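# Shared fixture builders. Everything is generated in code; no binary data.

# small GenotypeMatrix from a plain dosage matrix
toy_geno <- function(dos, pos = NULL, ref = "A", alt = "G", chrom = "1") {
  dos <- as.matrix(dos)
  m <- ncol(dos)
  genotype_matrix(dos, sprintf("s%03d", seq_len(nrow(dos))),
                  data.frame(chrom = chrom,
                             pos = pos %||% (100L * seq_len(m)),
                             ref = rep_len(ref, m), alt = rep_len(alt, m),
                             stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random GenotypeMatrix with binomial dosages
random_geno <- function(n, m, seed = 1, maf = NULL) {
  set.seed(seed)
  maf <- maf %||% runif(m, 0.1, 0.5)
  dos <- sapply(seq_len(m), function(j) rbinom(n, 2, maf[j]))
  toy_geno(dos)
}

toy_weight_set <- function(geno, w, gene_id = "g1",
                           method = "dpr_external") {
  weight_set(gene_id, geno$snp_info, w, method)
}

# write a minimal VCF with GT genotypes; genos is an n x m matrix of 0/1/2
# with NA for missing
write_toy_vcf <- function(path, genos, pos = NULL, chrom = "1") {
  n <- nrow(genos); m <- ncol(genos)
  pos <- pos %||% (1000L * seq_len(m))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sprintf("s%03d", seq_len(n))),
                   collapse = "\t"))
  for (j in seq_len(m)) {
    gts <- ifelse(is.na(genos[, j]), "./.", gt_code[as.character(genos[, j])])
    lines <- c(lines, paste(c(chrom, pos[j], sprintf("rs%d", j), "A", "G",
                              ".", "PASS", ".", "GT", gts), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# write a dosage table in the package's tab-delimited format
write_dosage_table <- function(path, geno) {
  df <- data.frame(CHROM = geno$snp_info$chrom, POS = geno$snp_info$pos,
                   REF = geno$snp_info$ref, ALT = geno$snp_info$alt,
                   SNP_ID = geno$snp_ids, stringsAsFactors = FALSE)
  dos <- t(geno$dosages)
  colnames(dos) <- geno$sample_ids
  utils::write.table(cbind(df, dos), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Monte-Carlo mixture tail oracle
mc_mixture_tail <- function(q, lambdas, n_draws = 1e6, seed = 1) {
  set.seed(seed)
  draws <- rep(0, n_draws)
  for (l in lambdas) draws <- draws + l * rchisq(n_draws, df = 1)
  mean(draws > q)
}
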