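test_that("MAF and call-rate filters remove exactly the offending entries", {
  ## 10x10 toy: individual 1 has 30% missing calls; SNP 2 drops to 90% call
  ## rate once individual 1 is gone; SNP 3 has MAF 0.05 < 0.10 threshold...
  set.seed(1)
  v <- matrix(1L, 10, 10)
  v[, 1] <- rep(c(0L, 2L), 5)                 # polymorphic, clean
  v[1, c(2, 3, 4)] <- NA                      # individual 1: 70% called
  v[2, 2] <- NA                               # SNP 2: 8/9 called after removal
  low <- rep(0L, 10); low[2] <- 1L            # SNP 5: MAF 0.05 (on 9 kept: 1/18)
  v[, 5] <- low
  g <- toy_geno(v)
  res <- apply_qc(g, qc_thresholds(min_individual_call_rate = 0.80,
                                   min_locus_call_rate = 0.95,
                                   min_maf = 0.10))
  expect_equal(res$report$individuals_removed$id, g$individual_ids[1])
  expect_setequal(res$report$snps_removed$id, g$snp_ids[c(2, 5)])
  expect_equal(sort(res$report$snps_removed$reason), c("call_rate", "maf"))
  expect_equal(dim(res$genotypes$values), c(9L, 8L))
})

test_that("a SNP below 1% MAF is removed with reason maf", {
  v <- matrix(rep(c(0L, 1L, 2L), length.out = 400), 200, 2)
  v[, 2] <- c(1L, rep(0L, 199))               # MAF 1/400 = 0.0025
  g <- toy_geno(v)
  res <- apply_qc(g)
  expect_equal(res$report$snps_removed$id, g$snp_ids[2])
  expect_equal(res$report$snps_removed$reason, "maf")
})

test_that("a clean matrix passes QC unchanged and QC is idempotent", {
  s <- sim_small(seed = 3, n = 40, sires = 20, m = 60)
  res <- apply_qc(s$geno)
  expect_identical(res$genotypes$values, s$geno$values)
  expect_equal(nrow(res$report$individuals_removed), 0L)
  expect_equal(nrow(res$report$snps_removed), 0L)
  s2 <- sim_small(seed = 3, n = 60, sires = 30, m = 300,
                  missing_rate = 0.1, monomorphic_rate = 0.1, low_maf_rate = 0.1)
  once <- apply_qc(s2$geno)
  twice <- apply_qc(once$genotypes)
  expect_identical(once$genotypes$values, twice$genotypes$values)
  expect_equal(nrow(twice$report$snps_removed), 0L)
  ## removal counts consistent with shapes
  expect_equal(once$report$n_snps_before - nrow(once$report$snps_removed),
               once$report$n_snps_after)
  expect_equal(once$report$n_individuals_before -
                 nrow(once$report$individuals_removed),
               once$report$n_individuals_after)
})

test_that("QC errors when everything is removed", {
  v <- matrix(0L, 5, 5)                        # all monomorphic
  expect_error(apply_qc(toy_geno(v)), "all SNPs")
})

test_that("centering imputes to the SNP mean and zeroes column sums", {
  g <- toy_geno(matrix(c(0L, 1L, 2L), 3, 1))
  cd <- center_genotypes(g)
  expect_equal(unname(cd$Z[, 1]), c(-1, 0, 1))
  expect_equal(unname(cd$allele_freqs), 0.5)

  g2 <- toy_geno(matrix(c(2L, 2L, 2L, 0L), 4, 1))
  cd2 <- center_genotypes(g2)
  expect_equal(unname(cd2$Z[, 1]), c(0.5, 0.5, 0.5, -1.5))
  expect_equal(sum(cd2$Z[, 1]), 0)

  g3 <- toy_geno(matrix(c(0L, NA, 2L), 3, 1))
  cd3 <- center_genotypes(g3)
  expect_equal(unname(cd3$Z[, 1]), c(-1, 0, 1))

  s <- sim_small(seed = 4, n = 50, sires = 25, m = 100, missing_rate = 0.05)
  cd4 <- center_genotypes(apply_qc(s$geno)$genotypes)
  expect_lt(max(abs(colSums(cd4$Z))), 1e-9 * nrow(cd4$Z))
  expect_gt(cd4$scaling_denominator, 0)
})

test_that("centering rejects monomorphic columns", {
  expect_error(center_genotypes(toy_geno(matrix(c(2L, 2L, 2L), 3, 1))),
               "monomorphic")
})
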