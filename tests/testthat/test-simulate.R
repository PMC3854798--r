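test_that("configuration invariants are enforced", {
  expect_error(sim_config(missing_rate = 1.2), class = "snpherit_config_error")
  expect_error(sim_config(n_sires = 500, n_individuals = 100),
               class = "snpherit_config_error")
  expect_error(sim_config(n_individuals = 100, n_herds = 3,
                          herd_size_range = c(3, 10)),
               class = "snpherit_config_error")
  expect_error(sim_config(monomorphic_rate = 0.6, low_maf_rate = 0.5),
               class = "snpherit_config_error")
  expect_error(trait_spec("x", true_h2 = 1.3), class = "snpherit_config_error")
  expect_error(multi_trait_spec(list(trait_spec("a", .2), trait_spec("b", .2)),
                                genomic_correlations = matrix(c(1, 2, 2, 1), 2)),
               class = "snpherit_config_error")
})

test_that("genotypes are allele counts with seeded determinism", {
  cfg <- sim_config(n_individuals = 4, n_sires = 2, n_snps = 10,
                    n_chromosomes = 2, n_herds = 1, herd_size_range = c(1, 4),
                    seed = 1)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g), c(4L, 10L))
  expect_true(all(g$values %in% 0:2))
  expect_false(anyNA(g$values))
  g2 <- simulate_genotypes(cfg)
  expect_identical(g$values, g2$values)
  expect_identical(g$sire_ids, g2$sire_ids)
})

test_that("monomorphic, low-MAF and missing fractions are honoured", {
  cfg <- sim_config(n_individuals = 200, n_sires = 100, n_snps = 1000,
                    n_herds = 4, herd_size_range = c(20, 100),
                    monomorphic_rate = 0.1, low_maf_rate = 0.05,
                    missing_rate = 0.05, seed = 3)
  g <- simulate_genotypes(cfg)
  n_mono <- sum(apply(g$complete_values, 2, function(x) length(unique(x)) == 1))
  expect_gt(n_mono, 70)   # ~100 expected, binomial + sampling tolerance
  expect_lt(n_mono, 130)
  maf <- pmin(colMeans(g$complete_values) / 2, 1 - colMeans(g$complete_values) / 2)
  expect_gt(sum(maf < 0.01), 100)  # low-MAF + monomorphic columns
  expect_equal(mean(is.na(g$values)), 0.05, tolerance = 0.15)
})

test_that("phenotype generator honours null and degenerate correlations", {
  s <- sim_small(seed = 2, traits = list(trait_spec("null", 0)))
  expect_equal(unname(s$truth$realized_var_zu), 0)
  expect_equal(unname(s$truth$realized_h2), 0)
  expect_true(all(s$truth$genetic_values == 0))

  Rg <- matrix(c(1, 1, 1, 1), 2)
  s2 <- sim_small(seed = 2, traits = list(trait_spec("a", 0.3),
                                          trait_spec("b", 0.3)), Rg = Rg)
  expect_equal(s2$truth$snp_effects[, 1], s2$truth$snp_effects[, 2],
               tolerance = 1e-12)
})

test_that("recorded truth satisfies the h2 identity exactly", {
  s <- sim_small(seed = 5, traits = list(trait_spec("a", 0.25),
                                         trait_spec("b", 0.1)),
                 Rg = matrix(c(1, .4, .4, 1), 2))
  h2 <- s$truth$realized_var_zu / (s$truth$realized_var_zu + s$truth$realized_var_e)
  expect_equal(unname(s$truth$realized_h2), unname(h2))
})

test_that("realized heritability is near its target at moderate size", {
  s <- sim_small(seed = 7, n = 500, sires = 250, m = 2000, herds = 10,
                 herd_size_range = c(30, 80),
                 traits = list(trait_spec("a", 0.3)))
  ## recompute from the generator's own outputs
  g <- s$truth$genetic_values[, 1]
  e_var <- s$truth$realized_var_e[1]
  h2 <- stats::var(g) * (length(g) - 1) / length(g)
  h2 <- h2 / (h2 + e_var)
  expect_equal(unname(h2), unname(s$truth$realized_h2[1]), tolerance = 1e-10)
  expect_equal(unname(s$truth$realized_h2[1]), 0.3, tolerance = 0.05)
})

test_that("expected Var(Zu) matches the target over replicates", {
  ## mean realized Var(Zu) over replicates within 3 standard errors of target
  vz <- vapply(1:50, function(s) {
    sim <- sim_small(seed = s, n = 500, sires = 250, m = 300, herds = 10,
                     herd_size_range = c(30, 80),
                     traits = list(trait_spec("a", 0.3)))
    unname(sim$truth$realized_var_zu)
  }, 0)
  se <- stats::sd(vz) / sqrt(length(vz))
  expect_lt(abs(mean(vz) - 0.3), 3 * se)
})

test_that("study-like preset matches the sampling design", {
  ds <- make_study_like_dataset(seed = 1, n_snps = 2000)
  expect_equal(nrow(ds$phenotypes), 371L)
  expect_equal(length(unique(ds$phenotypes$herd)), 19L)
  sizes <- table(ds$phenotypes$herd)
  expect_true(all(sizes >= 3 & sizes <= 24))
  expect_true(all(ds$phenotypes$parity %in% 1:3))
  expect_equal(length(unique(ds$genotypes$sire_ids)) <= 200, TRUE)
  h2 <- ds$truth$target_h2
  expect_equal(unname(range(h2)), c(0.07, 0.35))
  rg <- ds$truth$genomic_correlations_target
  expect_equal(min(rg), -0.60)
  expect_equal(max(rg[upper.tri(rg)]), 0.91)
})
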