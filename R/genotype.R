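#' Genotype dosage matrix with SNP metadata
#'
#' Container for a samples-by-SNPs dosage matrix (entries in `[0, 2]`,
#' mean-imputed) together with SNP metadata and per-SNP minor-allele
#' frequencies. This is the `G` of both the weight-training regression and
#' the association tests.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns.
#' @param sample_ids Character vector of row identifiers.
#' @param snp_info Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (and optionally `snp_id`; default `chrom:pos:ref:alt`).
#' @return An object of class `GenotypeMatrix` with fields `dosages`,
#'   `sample_ids`, `snp_ids`, `snp_info`, `positions`, `maf`.
#' @export
genotype_matrix <- function(dosages, sample_ids, snp_info) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  stopifnot(nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(snp_info))
  if (is.null(snp_info$snp_id))
    snp_info$snp_id <- paste(snp_info$chrom, snp_info$pos,
                             snp_info$ref, snp_info$alt, sep = ":")
  if (anyDuplicated(snp_info$snp_id))
    stop("duplicate SNP identifiers")
  if (ncol(dosages) > 0L) {
    if (anyNA(dosages)) stop("dosages must be imputed before construction")
    if (min(dosages) < 0 || max(dosages) > 2)
      stop("dosages must lie in [0, 2]")
  }
  dimnames(dosages) <- list(sample_ids, snp_info$snp_id)
  pbar <- if (ncol(dosages)) colMeans(dosages) / 2 else numeric(0)
  structure(list(
    dosages = dosages,
    sample_ids = as.character(sample_ids),
    snp_ids = snp_info$snp_id,
    snp_info = snp_info,
    positions = as.integer(snp_info$pos),
    maf = pmin(pbar, 1 - pbar)
  ), class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d SNPs\n",
              length(x$sample_ids), length(x$snp_ids)))
  if (length(x$maf))
    cat(sprintf("  MAF range: %.4f - %.4f\n", min(x$maf), max(x$maf)))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosages)

#' Number of SNPs in a GenotypeMatrix
#' @param geno A `GenotypeMatrix`.
#' @export
n_snps <- function(geno) length(geno$snp_ids)

#' Load and QC genotypes from a VCF or dosage table
#'
#' Reads a VCF (`GT` or `DS` field; requires the VariantAnnotation package)
#' or a tab-delimited dosage table with header
#' `CHROM POS REF ALT SNP_ID <sample...>`. SNPs are restricted to the cis
#' window `[start - flank, end + flank]`, screened on minor-allele frequency
#' and (for hard-call genotypes) a Hardy-Weinberg chi-square test, and
#' missing dosages are replaced by the SNP mean so the allele frequency is
#' preserved. SNPs are ordered by position, then alleles.
#'
#' A file from which no SNP survives QC yields a `GenotypeMatrix` with zero
#' SNPs (an empty-result signal, not an error); downstream tests treat such
#' genes as untestable.
#'
#' @param path Path to a `.vcf` file or a dosage table.
#' @param chrom,start,end Optional cis-window restriction (1-based,
#'   inclusive; gene body coordinates).
#' @param flank Window flank in base pairs (default 1 Mb each side).
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param hwe_p_min Minimum Hardy-Weinberg exact-fit p-value (default 1e-5);
#'   applied only when all observed dosages are hard calls (0/1/2).
#' @return A `GenotypeMatrix`.
#' @export
load_genotype_matrix <- function(path, chrom = NULL, start = NULL, end = NULL,
                                 flank = 1e6, maf_min = 0.05,
                                 hwe_p_min = 1e-5) {
  if (!file.exists(path)) stop("cannot read genotype file: ", path)
  if (flank < 0) stop("'flank' must be non-negative")
  raw <- if (grepl("\\.vcf(\\.gz)?$", path)) .read_vcf_dosages(path)
         else .read_dosage_table(path)
  info <- raw$snp_info
  dos <- raw$dosages

  keep <- rep(TRUE, nrow(info))
  if (!is.null(chrom)) {
    keep <- keep & (as.character(info$chrom) == as.character(chrom))
    if (!is.null(start)) keep <- keep & info$pos >= start - flank
    if (!is.null(end))   keep <- keep & info$pos <= end + flank
  }
  info <- info[keep, , drop = FALSE]
  dos <- dos[, keep, drop = FALSE]

  # mean imputation, then QC
  if (ncol(dos) > 0L) {
    na_idx <- which(colSums(is.na(dos)) > 0L)
    for (j in na_idx) {
      m <- mean(dos[, j], na.rm = TRUE)
      dos[is.na(dos[, j]), j] <- m
    }
    pbar <- colMeans(dos) / 2
    maf <- pmin(pbar, 1 - pbar)
    ok <- maf > maf_min
    hard <- vapply(seq_len(ncol(dos)), function(j)
      all(dos[, j] %in% c(0, 1, 2)), logical(1))
    hwe <- rep(NA_real_, ncol(dos))
    hwe[hard] <- vapply(which(hard), function(j) .hwe_pvalue(dos[, j]),
                        numeric(1))
    ok <- ok & (is.na(hwe) | hwe > hwe_p_min)
    info <- info[ok, , drop = FALSE]
    dos <- dos[, ok, drop = FALSE]
  }
  ord <- order(info$pos, info$ref, info$alt)
  genotype_matrix(dos[, ord, drop = FALSE], raw$sample_ids,
                  info[ord, , drop = FALSE])
}

# chi-square goodness-of-fit HWE test on hard genotype counts
.hwe_pvalue <- function(g) {
  n0 <- sum(g == 0); n1 <- sum(g == 1); n2 <- sum(g == 2)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

.read_dosage_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          na.strings = c("NA", ".", ""))
  need <- c("CHROM", "POS", "REF", "ALT", "SNP_ID")
  if (!all(need %in% names(dt)))
    stop("dosage table must start with columns: ", paste(need, collapse = " "))
  samp <- setdiff(names(dt), need)
  dos <- t(as.matrix(dt[, samp, with = FALSE]))
  storage.mode(dos) <- "double"
  list(dosages = dos, sample_ids = samp,
       snp_info = data.frame(chrom = as.character(dt$CHROM), pos = dt$POS,
                             ref = dt$REF, alt = dt$ALT, snp_id = dt$SNP_ID,
                             stringsAsFactors = FALSE))
}

.read_vcf_dosages <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  # reject multiallelic records
  alt <- VariantAnnotation::alt(vcf)
  biallelic <- lengths(alt) == 1L
  vcf <- vcf[biallelic, ]
  rr <- SummarizedExperiment::rowRanges(vcf)
  gg <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gg)) {
    dos <- t(gg$DS)
  } else if ("GT" %in% names(gg)) {
    gt <- gg$GT
    conv <- function(x) {
      x[x %in% c(".", "./.", ".|.")] <- NA
      vapply(strsplit(x, "[/|]"), function(a)
        if (anyNA(suppressWarnings(as.numeric(a)))) NA_real_
        else sum(as.numeric(a) > 0), numeric(1))
    }
    dos <- matrix(conv(as.character(t(gt))), nrow = ncol(gt),
                  dimnames = list(colnames(gt), rownames(gt)))
  } else stop("VCF has neither DS nor GT genotype field")
  storage.mode(dos) <- "double"
  list(dosages = dos,
       sample_ids = colnames(gg$GT %||% gg$DS),
       snp_info = data.frame(
         chrom = as.character(GenomicRanges::seqnames(rr)),
         pos = GenomicRanges::start(rr),
         ref = as.character(VariantAnnotation::ref(vcf)),
         alt = as.character(unlist(alt)),
         stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference LD covariance matrix
#'
#' Sample covariance of the dosage columns (divisor `n - 1`) plus a small
#' ridge on the diagonal guaranteeing positive semi-definiteness. This is
#' the reference `Sigma` consumed by the summary-level tests.
#'
#' @param geno A `GenotypeMatrix` with at least 2 samples.
#' @param ridge Non-negative ridge added to the diagonal; default
#'   `1e-6 * mean(diag)`.
#' @return An object of class `LDMatrix` with fields `snp_ids`, `sigma`,
#'   `n_ref`, `ridge`.
#' @export
compute_ld_covariance <- function(geno, ridge = NULL) {
  stopifnot(inherits(geno, "GenotypeMatrix"))
  n <- nrow(geno$dosages)
  if (n < 2L) stop("LD covariance requires at least 2 samples")
  sigma <- stats::cov(geno$dosages)
  if (is.null(ridge)) {
    md <- mean(diag(sigma))
    ridge <- if (is.finite(md) && md > 0) 1e-6 * md else 1e-6
  }
  if (ridge < 0) stop("'ridge' must be non-negative")
  diag(sigma) <- diag(sigma) + ridge
  sigma <- (sigma + t(sigma)) / 2
  structure(list(snp_ids = geno$snp_ids, sigma = sigma,
                 n_ref = n, ridge = ridge),
            class = "LDMatrix")
}

#' @export
print.LDMatrix <- function(x, ...) {
  cat(sprintf("LDMatrix: %d SNPs, n_ref = %d, ridge = %g\n",
              length(x$snp_ids), x$n_ref, x$ridge))
  invisible(x)
}

#' Write / read a per-gene LD matrix as tab-delimited text
#'
#' The format is a square matrix with a SNP-id header row (and first
#' column), values tab-delimited.
#'
#' @param ld An `LDMatrix`.
#' @param path Output path.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "LDMatrix"))
  m <- as.data.frame(ld$sigma)
  names(m) <- ld$snp_ids
  out <- cbind(data.frame(SNP_ID = ld$snp_ids, stringsAsFactors = FALSE), m)
  attr_line <- sprintf("#n_ref=%d ridge=%.12g", ld$n_ref, ld$ridge)
  writeLines(attr_line, path)
  suppressWarnings(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  n_ref <- 0L; ridge <- 0
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("#n_ref=(\\d+) ridge=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 3L) { n_ref <- as.integer(m[2]); ridge <- as.numeric(m[3]) }
    skip <- 1L
  }
  dt <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE)
  snp_ids <- dt$SNP_ID
  sigma <- as.matrix(dt[, -1, drop = FALSE])
  dimnames(sigma) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, sigma = (sigma + t(sigma)) / 2,
                 n_ref = n_ref, ridge = ridge),
            class = "LDMatrix")
}
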