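test_that("a hand-built bed file decodes to the expected dosages", {
  # 2 individuals x 2 SNPs, written byte by byte:
  # SNP1: ind1 hom allele1 (code 00 -> dosage 2), ind2 missing (01)
  # SNP2: ind1 het (10 -> 1), ind2 hom allele2 (11 -> 0)
  prefix <- file.path(tempdir(), "hand")
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01,
                    0x04,     # 01 00 -> ind2 missing, ind1 code 00
                    0x0e)),   # 11 10 -> ind2 code 11, ind1 code 10
           con)
  close(con)
  writeLines(c("1\trs1\t0\t100\tA\tG", "1\trs2\t0\t200\tC\tT"),
             paste0(prefix, ".bim"))
  writeLines(c("f1\ti1\t0\t0\t0\t-9", "f2\ti2\t0\t0\t0\t-9"),
             paste0(prefix, ".fam"))
  gm <- read_plink(prefix)
  expect_equal(gm$dosages, matrix(c(2, NA, 1, 0), 2, 2))
  expect_equal(gm$snps$id, c("rs1", "rs2"))
  expect_equal(gm$sample_ids, c("i1", "i2"))
  expect_true(is.na(gm$dosages[2, 1]))  # exactly one missing call
  expect_equal(sum(is.na(gm$dosages)), 1)
})

test_that("bad magic bytes and truncation are format errors", {
  prefix <- file.path(tempdir(), "bad")
  writeLines("1\trs1\t0\t1\tA\tG", paste0(prefix, ".bim"))
  writeLines("f\ti\t0\t0\t0\t-9", paste0(prefix, ".fam"))
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), con); close(con)
  expect_error(read_plink(prefix), "magic")
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con); close(con)
  expect_error(read_plink(prefix), "truncated")
  expect_error(read_plink(file.path(tempdir(), "nonexistent")), "not found")
})

test_that("PLINK and BIMBAM round trips are lossless", {
  set.seed(61)
  for (rep_i in 1:100) {
    n <- sample(2:9, 1); p <- sample(1:7, 1)
    D <- matrix(rbinom(n * p, 2, 0.4), n, p)
    D[runif(n * p) < 0.15] <- NA
    gm <- genotype_matrix(D)
    prefix <- file.path(tempdir(), paste0("rt", rep_i))
    write_plink(gm, prefix)
    back <- read_plink(prefix)
    expect_equal(back$dosages, unname(gm$dosages))
    expect_equal(back$snps$id, gm$snps$id)

    bb <- file.path(tempdir(), paste0("rt", rep_i, ".bimbam"))
    write_bimbam(gm, bb)
    back2 <- read_bimbam(bb)
    expect_equal(back2$dosages, unname(gm$dosages))
  }
})

test_that("BIMBAM accepts fractional dosages and flags ragged rows", {
  path <- file.path(tempdir(), "frac.bimbam")
  writeLines(c("rs1 A G 0.12 1.9 NA", "rs2 C T 2 0 1"), path)
  gm <- read_bimbam(path)
  expect_equal(gm$dosages[, 1], c(0.12, 1.9, NA))
  expect_equal(gm$dosages[, 2], c(2, 0, 1))
  writeLines(c("rs1 A G 1 2", "rs2 C T 1"), path)
  expect_error(read_bimbam(path), "inconsistent")
})

test_that("the HWE chi-square test matches independent arithmetic", {
  expect_equal(hwe_test(c(25, 50, 25)), 1)
  # all-heterozygous: chi-square = 100 on 1 df
  p_het <- hwe_test(c(0, 100, 0))
  expect_equal(p_het, pchisq(100, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(p_het, 1e-4)
  expect_equal(hwe_test(c(10, 0, 0)), 1)  # monomorphic convention
  expect_error(hwe_test(c(-1, 2, 3)), "nonnegative")
  expect_error(hwe_test(c(0, 0, 0)), ">= 1")
})

test_that("QC removes exactly the planted failures", {
  set.seed(62)
  gm <- make_qc_panel(n = 200)
  qc <- apply_qc(gm)
  expect_equal(qc$genotypes$snps$id, c("snp1", "snp5"))
  expect_setequal(qc$report$id, c("snp2", "snp3", "snp4"))
  expect_equal(qc$report$rule[qc$report$id == "snp2"], "hwe")
  expect_equal(qc$report$rule[qc$report$id == "snp3"], "call_rate")
  expect_equal(qc$report$rule[qc$report$id == "snp4"], "maf")

  # zero thresholds disable all filters
  qc0 <- apply_qc(gm, hwe_thresh = 0, call_thresh = 0, maf_thresh = 0)
  expect_equal(ncol(qc0$genotypes$dosages), 5)
  expect_equal(nrow(qc0$report), 0)
})

test_that("QC filtering is order independent", {
  set.seed(63)
  gm <- make_qc_panel(n = 150)
  survivors <- apply_qc(gm)$genotypes$snps$id
  # apply the three filters sequentially in every order
  filters <- list(
    hwe = function(g) apply_qc(g, 1e-4, 0, 0)$genotypes,
    call = function(g) apply_qc(g, 0, 0.95, 0)$genotypes,
    maf = function(g) apply_qc(g, 0, 0, 0.01)$genotypes)
  for (ord in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    g <- gm
    for (k in ord) g <- filters[[k]](g)
    expect_equal(g$snps$id, survivors)
  }
})

test_that("MAF arithmetic keeps a common SNP", {
  gm <- genotype_matrix(matrix(c(0, 0, 1, 2), 4, 1))
  st <- genotype_stats(gm)
  expect_equal(st$maf, 3 / 8)
  expect_equal(nrow(apply_qc(gm)$report), 0)
})

test_that("mean imputation fills with observed column means", {
  gm <- genotype_matrix(cbind(c(0, NA, 2), c(1, 1, 0)))
  out <- mean_impute(gm)
  expect_equal(out$dosages[, 1], c(0, 1, 2))
  expect_equal(out$dosages[, 2], c(1, 1, 0))  # untouched

  gm2 <- genotype_matrix(cbind(c(2, 2, NA, 0)))
  expect_equal(mean_impute(gm2)$dosages[3, 1], 4 / 3)

  gm3 <- genotype_matrix(cbind(c(NA, NA, NA), c(1, 1, 0)))
  expect_error(mean_impute(gm3), "fully missing")
})

test_that("quantile normalization maps ranks to normal scores", {
  out <- quantile_normalize(c(5, 1, 9))
  expect_equal(out, qnorm(c(1.5, 0.5, 2.5) / 3), tolerance = 1e-12)
  expect_equal(round(out, 4), c(0, -0.9674, 0.9674))

  set.seed(64)
  v <- rexp(300)
  qn <- quantile_normalize(v)
  expect_true(all(diff(qn[order(v)]) >= 0))       # monotone in ranks
  expect_equal(quantile_normalize(qn), qn)        # idempotent
  expect_error(quantile_normalize(rep(2, 10)), "degenerate")

  ks <- ks.test(quantile_normalize(rnorm(10000, 5, 3)), pnorm)
  expect_gt(ks$p.value, 0.01)
})

test_that("centering stores and reuses training means", {
  ctr <- center_genotypes(matrix(c(0, 1, 2), 3, 1))
  expect_equal(ctr$X[, 1], c(-1, 0, 1))
  expect_equal(ctr$means, 1)
  Xte <- matrix(c(2, 2, 0), 3, 1)
  cte <- center_genotypes(Xte, means = ctr$means)
  expect_equal(cte$X[, 1], c(1, 1, -1))
  expect_false(abs(mean(cte$X)) < 1e-12)  # test means generally nonzero
  expect_equal(sweep(cte$X, 2, -cte$means), Xte)  # uncentering restores input
  expect_error(center_genotypes(Xte, means = c(1, 2)), "one entry per SNP")
})
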