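# Genotype container, readers/writers, SNP quality control and the genomic
# relationship matrix.

#' Genotype dosage matrix
#'
#' Container for an n x p matrix of reference-allele dosages coded 0/1/2
#' (copies of the reference allele) with `NA` for missing calls.
#'
#' @param dosages n x p numeric/integer matrix; non-missing entries must be
#'   0, 1 or 2.
#' @param line_ids,snp_ids Identifiers; default to existing dimnames or
#'   generated labels.
#' @return An object of class `genotype_matrix`: the dosage matrix with
#'   `line_ids` as rownames and `snp_ids` as colnames.
#' @export
genotype_matrix <- function(dosages, line_ids = rownames(dosages),
                            snp_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(line_ids)) line_ids <- sprintf("L%03d", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- sprintf("S%05d", seq_len(ncol(dosages)))
  if (length(line_ids) != nrow(dosages) ||
      length(snp_ids) != ncol(dosages)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  obs <- dosages[!is.na(dosages)]
  if (length(obs) && !all(obs %in% c(0, 1, 2))) {
    stop("non-missing dosages must be 0, 1 or 2", call. = FALSE)
  }
  dimnames(dosages) <- list(line_ids, snp_ids)
  structure(dosages, class = c("genotype_matrix", class(dosages)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x), "lines x", ncol(x), "SNPs;",
      sum(is.na(x)), "missing calls\n")
  invisible(x)
}

#' Read / write a genotype dosage matrix as CSV/TSV
#'
#' Layout: first column holds line identifiers, remaining header names are
#' SNP identifiers, cells are dosages 0/1/2 with `NA` for missing.
#'
#' @param path File path (delimiter auto-detected by `data.table::fread`).
#' @param gm A `genotype_matrix`.
#' @return `read_genotypes` returns a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  dt <- data.table::fread(path, na.strings = c("NA", ""))
  ids <- as.character(dt[[1L]])
  dos <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(dos) <- "double"
  genotype_matrix(dos, line_ids = ids, snp_ids = colnames(dos))
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(gm, path) {
  df <- data.frame(line_id = rownames(gm), unclass(gm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Biallelic sites only; the GT field is converted to the dosage of the
#' REF allele (`0/0` -> 2, `0/1` -> 1, `1/1` -> 0, `./.` -> missing).
#' Requires the `VariantAnnotation` package.
#'
#' @param path Path to a (possibly compressed) VCF file.
#' @return A [genotype_matrix()] with samples as lines and variant IDs as
#'   SNP identifiers.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  biallelic <- lengths(VariantAnnotation::alt(vcf)) == 1L
  gt <- gt[biallelic, , drop = FALSE]
  ref_dose <- function(g) {
    a <- strsplit(g, "[/|]")[[1L]]
    if (any(a == ".")) return(NA_real_)
    sum(a == "0")
  }
  dos <- apply(gt, c(1, 2), ref_dose)
  genotype_matrix(t(dos), line_ids = colnames(gt), snp_ids = rownames(gt))
}

#' Per-SNP reference-allele and minor-allele frequencies
#'
#' Frequencies are computed on observed (non-missing) calls only:
#' `f = sum(dosages) / (2 * n_observed)`, `MAF = min(f, 1 - f)`. A SNP with
#' no observed calls gets `NA` (it cannot pass the missingness filter).
#'
#' @param gm A [genotype_matrix()].
#' @return Named numeric vector of minor allele frequencies, with the
#'   reference-allele frequency attached as attribute `"ref_freq"`.
#' @export
compute_maf <- function(gm) {
  f <- colMeans(gm, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  maf <- pmin(f, 1 - f)
  attr(maf, "ref_freq") <- f
  maf
}

#' Filter SNPs on minor allele frequency and missingness
#'
#' Retains SNPs with `MAF > maf_min` and missing fraction `< miss_max`
#' (both strict inequalities), preserving SNP order.
#'
#' @param gm A [genotype_matrix()].
#' @param maf_min MAF threshold in `[0, 0.5]` (default 0.05).
#' @param miss_max Missing-fraction threshold in `[0, 1]` (default 0.15).
#' @return A list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report` (a `qc_report` data.frame with one row
#'   per input SNP: `snp_id, maf, missing_frac, kept, reason`).
#' @export
filter_snps <- function(gm, maf_min = 0.05, miss_max = 0.15) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1)
  maf <- as.numeric(compute_maf(gm))
  missf <- colMeans(is.na(gm))
  ok_maf <- !is.na(maf) & maf > maf_min
  ok_miss <- missf < miss_max
  keep <- ok_maf & ok_miss
  reason <- rep(NA_character_, ncol(gm))
  reason[!ok_miss] <- "missingness"
  reason[!ok_maf & ok_miss] <- "maf"
  reason[!ok_maf & !ok_miss] <- "maf+missingness"
  report <- data.frame(snp_id = colnames(gm), maf = maf,
                       missing_frac = missf, kept = keep, reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  class(report) <- c("qc_report", "data.frame")
  if (!any(keep)) {
    stop("no SNP passed QC (MAF > ", maf_min, ", missing < ", miss_max, ")",
         call. = FALSE)
  }
  kept <- genotype_matrix(unclass(gm)[, keep, drop = FALSE],
                          line_ids = rownames(gm),
                          snp_ids = colnames(gm)[keep])
  list(genotypes = kept, report = report)
}

#' Marginal-mean imputation of missing dosages
#'
#' Replaces each missing call by the sample mean of the observed dosages at
#' that locus; observed calls are unchanged. Output entries are real-valued.
#'
#' @param gm A [genotype_matrix()].
#' @return A numeric matrix (lines x SNPs) with no missing values, dimnames
#'   preserved.
#' @export
impute_mean <- function(gm) {
  X <- unclass(as.matrix(gm))
  storage.mode(X) <- "double"
  nmiss <- colSums(is.na(X))
  if (any(nmiss == nrow(X))) {
    stop("SNP(s) with no observed calls cannot be imputed: ",
         paste(utils::head(colnames(X)[nmiss == nrow(X)], 5),
               collapse = ", "), call. = FALSE)
  }
  if (any(nmiss > 0)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  X
}

#' Build the genomic relationship matrix
#'
#' `G = Z Z' / (trace(Z Z') / n)` where `Z` is the dosage matrix with each
#' SNP column centered on its mean (lines in rows, SNPs in columns). The
#' scaling makes `trace(G) = n`, so the mean diagonal is 1 and genetic
#' variances estimated against `G` are on the per-line scale.
#'
#' @param X Imputed dosage matrix (no missing values), e.g. from
#'   [impute_mean()].
#' @return n x n symmetric PSD matrix with line ids as dimnames and
#'   `trace = n`.
#' @export
build_grm <- function(X) {
  X <- unclass(as.matrix(X))
  if (anyNA(X)) stop("dosage matrix still contains missing values; impute first",
                     call. = FALSE)
  n <- nrow(X)
  if (n < 2L) stop("need at least two lines to build a GRM", call. = FALSE)
  Z <- scale(X, center = TRUE, scale = FALSE)
  ZZt <- tcrossprod(Z)
  tr <- sum(diag(ZZt))
  if (tr <= 0) {
    stop("all SNPs are constant; the genomic relationship matrix is degenerate",
         call. = FALSE)
  }
  G <- ZZt / (tr / n)
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(X), rownames(X))
  G
}

#' Write / read a GRM as square CSV
#'
#' @param G Square relationship matrix with line-id dimnames.
#' @param path File path.
#' @return `read_grm` returns the matrix with dimnames restored.
#' @export
write_grm <- function(G, path) {
  df <- data.frame(line_id = rownames(G), G, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  dt <- data.table::fread(path)
  ids <- as.character(dt[[1L]])
  G <- as.matrix(dt[, -1L, drop = FALSE])
  dimnames(G) <- list(ids, colnames(G))
  G
}

#' Write a QC report to CSV
#' @param report A `qc_report` from [filter_snps()].
#' @param path File path.
#' @export
write_qc_report <- function(report, path) {
  data.table::fwrite(report, path, na = "NA", quote = FALSE)
  invisible(path)
}
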