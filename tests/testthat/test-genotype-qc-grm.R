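# SNP quality control and the genomic relationship matrix: hand-computed
# oracles, threshold boundaries, and the coding/ordering invariances that the
# centered cross-product construction must satisfy.

test_that("minor allele frequency is computed on observed calls only", {
  gm <- genotype_matrix(cbind(s1 = c(0, 0, 0, 0, 0),
                              s2 = c(0, 1, 2, 2, NA),
                              s3 = c(1, 1, 1, 1, 1)),
                        line_ids = paste0("l", 1:5))
  maf <- compute_maf(gm)
  f <- attr(maf, "ref_freq")
  expect_equal(as.numeric(maf), c(0, 0.375, 0.5))
  expect_equal(as.numeric(f), c(0, 5 / 8, 0.5))

  gm_allmiss <- genotype_matrix(cbind(s1 = c(NA, NA, NA), s2 = c(0, 1, 2)))
  expect_true(is.na(compute_maf(gm_allmiss)[1]))
})

test_that("SNP filters use strict inequalities at both thresholds", {
  # MAF exactly at the threshold must be dropped ("> 0.05")
  n <- 100
  dos_at <- c(rep(1, 10), rep(0, 90))          # f = 0.05 exactly
  dos_ok <- c(rep(1, 12), rep(0, 88))          # f = 0.06
  # missingness exactly at the threshold must be dropped ("< 0.15")
  miss_at <- c(rep(NA, 15), rep(1, 45), rep(0, 40))
  miss_ok <- c(rep(NA, 14), rep(1, 46), rep(0, 40))
  gm <- genotype_matrix(cbind(at_maf = dos_at, ok_maf = dos_ok,
                              at_miss = miss_at, ok_miss = miss_ok))
  res <- filter_snps(gm, maf_min = 0.05, miss_max = 0.15)
  expect_identical(colnames(res$genotypes), c("ok_maf", "ok_miss"))
  expect_identical(res$report$reason[res$report$snp_id == "at_maf"], "maf")
  expect_identical(res$report$reason[res$report$snp_id == "at_miss"],
                   "missingness")
  expect_setequal(res$report$snp_id, colnames(gm))
  expect_false(any(res$report$kept & !is.na(res$report$reason)))
})

test_that("a toy panel with known MAFs keeps exactly the passing SNPs", {
  # MAFs 0.0, 0.04, 0.05, 0.2, 0.5 with no missingness -> 2 kept
  n <- 50
  col_for_maf <- function(m) c(rep(1, round(2 * n * m)),
                               rep(0, n - round(2 * n * m)))
  gm <- genotype_matrix(cbind(a = col_for_maf(0), b = col_for_maf(0.04),
                              c = col_for_maf(0.05), d = col_for_maf(0.2),
                              e = col_for_maf(0.5)))
  expect_equal(as.numeric(compute_maf(gm)), c(0, 0.04, 0.05, 0.2, 0.5))
  res <- filter_snps(gm)
  expect_identical(colnames(res$genotypes), c("d", "e"))
  expect_error(filter_snps(gm, maf_min = 0.5), "no SNP passed")
})

test_that("marginal-mean imputation fills missing cells and nothing else", {
  gm <- genotype_matrix(cbind(s1 = c(0, 2, NA), s2 = c(1, 0, 2),
                              s3 = c(2, 2, NA)))
  X <- impute_mean(gm)
  expect_equal(X[3, "s1"], 1.0)
  expect_equal(X[3, "s3"], 2.0)
  expect_equal(X[, "s2"], c(1, 0, 2), ignore_attr = TRUE)
  expect_false(anyNA(X))

  gm_clean <- genotype_matrix(matrix(c(0, 1, 2, 2), 2, 2))
  expect_equal(impute_mean(gm_clean), unclass(gm_clean),
               ignore_attr = TRUE)
  gm_bad <- genotype_matrix(cbind(s1 = c(NA_real_, NA), s2 = c(0, 1)))
  expect_error(impute_mean(gm_bad), "no observed calls")
})

test_that("the GRM reproduces the hand-computed example and its identities", {
  X <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), NULL))
  G <- build_grm(X)
  expect_equal(unname(G), matrix(c(1, -1, -1, 1), 2, 2))

  set.seed(7)
  Xr <- matrix(rbinom(40 * 30, 2, 0.3), 40, 30)
  Gr <- build_grm(Xr)
  expect_equal(sum(diag(Gr)), 40, tolerance = 1e-8)
  expect_equal(Gr, t(Gr))
  ev <- eigen(Gr, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))

  # duplicated line rows give identical G rows/columns and equal diagonals
  Xd <- rbind(Xr, Xr[1, ])
  Gd <- build_grm(Xd)
  expect_equal(Gd[41, ], Gd[1, ], ignore_attr = TRUE)
  expect_equal(Gd[41, 41], Gd[1, 1])

  expect_error(build_grm(matrix(1, 5, 3)), "constant")
  expect_error(build_grm(cbind(c(0, 1, NA), c(1, 1, 0))), "impute")
})

test_that("the QC -> impute -> GRM pipeline is invariant to SNP order and allele coding", {
  cfg <- sim_config(n_lines = 40, n_snps = 120, seed = 13,
                    missing_rate = 0.08)
  gm <- simulate_genotypes(cfg)
  run <- function(g) build_grm(impute_mean(filter_snps(g)$genotypes))
  G1 <- run(gm)

  perm <- sample(ncol(gm))
  gm_perm <- genotype_matrix(unclass(gm)[, perm], line_ids = rownames(gm),
                             snp_ids = colnames(gm)[perm])
  expect_lt(max(abs(run(gm_perm) - G1)), 1e-12)

  flip <- rbinom(ncol(gm), 1, 0.5) == 1
  dos <- unclass(gm)
  dos[, flip] <- 2 - dos[, flip]
  gm_flip <- genotype_matrix(dos, line_ids = rownames(gm),
                             snp_ids = colnames(gm))
  expect_lt(max(abs(run(gm_flip) - G1)), 1e-12)
})

test_that("on many independent SNPs the GRM concentrates near the identity", {
  cfg <- sim_config(n_lines = 200, n_snps = 5000, seed = 17,
                    missing_rate = 0)
  gm <- simulate_genotypes(cfg)
  G <- build_grm(impute_mean(gm))
  expect_equal(mean(diag(G)), 1, tolerance = 1e-12)
  off <- G[upper.tri(G)]
  expect_lt(mean(abs(off)), 0.05)
  expect_lt(max(abs(off)), 0.25)
})

test_that("genotype matrices round-trip through CSV and VCF", {
  cfg <- sim_config(n_lines = 8, n_snps = 6, seed = 5, missing_rate = 0.1)
  gm <- simulate_genotypes(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(gm, f)
  back <- read_genotypes(f)
  expect_equal(unclass(back), unclass(gm), ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(gm))

  # minimal VCF with the same dosages: REF-allele dosage must match
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gt_of <- function(d) {
    if (is.na(d)) "./." else c("1/1", "0/1", "0/0")[d + 1]
  }
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##contig=<ID=1>",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(gm)), collapse = "\t"))
  rows <- vapply(seq_len(ncol(gm)), function(j) {
    paste(c("1", j, colnames(gm)[j], "A", "G", ".", "PASS", ".", "GT",
            vapply(unclass(gm)[, j], gt_of, character(1))), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), vcf)
  gv <- read_genotypes_vcf(vcf)
  expect_equal(unclass(gv)[rownames(gm), colnames(gm)], unclass(gm),
               ignore_attr = TRUE)

  g <- build_grm(impute_mean(gm))
  fg <- withr::local_tempfile(fileext = ".csv")
  write_grm(g, fg)
  expect_equal(read_grm(fg), g, tolerance = 1e-12)
})
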