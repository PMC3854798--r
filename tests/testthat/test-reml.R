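## shared well-identified dataset: strong family structure so the genomic
## components are separable at moderate n
make_reml_dataset <- function(seed = 1, h2 = 0.4, rg = 0.6, re = -0.3) {
  cfg <- sim_config(n_individuals = 400, n_sires = 40, n_snps = 1000,
                    n_herds = 8, herd_size_range = c(20, 80), seed = seed)
  geno <- simulate_genotypes(cfg)
  spec <- multi_trait_spec(list(trait_spec("a", h2), trait_spec("b", h2)),
                           matrix(c(1, rg, rg, 1), 2),
                           matrix(c(1, re, re, 1), 2))
  ph <- simulate_phenotypes(geno, spec, cfg)
  qc <- apply_qc(geno)$genotypes
  list(pheno = ph$phenotypes, truth = ph$truth, grm = compute_grm(qc),
       design = center_genotypes(qc))
}

test_that("univariate REML recovers heritability on well-identified data", {
  d <- make_reml_dataset(seed = 1)
  r <- reml_univariate(d$pheno$a, d$pheno$herd, d$pheno$parity, d$grm)
  expect_true(r$converged)
  expect_lt(abs(r$h2 - d$truth$realized_h2[["a"]]), 2 * r$se_h2)
  expect_gte(r$sigma_a2, 0)
  expect_gte(r$sigma_e2, 0)
})

test_that("bivariate REML recovers the genomic correlation", {
  d <- make_reml_dataset(seed = 2)
  r <- reml_bivariate(d$pheno$a, d$pheno$b, d$pheno$herd, d$pheno$parity,
                      d$grm)
  expect_true(r$converged)
  expect_lt(abs(r$genomic_correlation -
                  d$truth$realized_genomic_correlations[1, 2]),
            2 * r$se_genomic_correlation)
  expect_lt(abs(r$environmental_correlation), 1)
})

test_that("restricted log-likelihood never decreases across iterations", {
  d <- make_reml_dataset(seed = 3)
  r <- reml_bivariate(d$pheno$a, d$pheno$b, d$pheno$herd, d$pheno$parity,
                      d$grm)
  expect_true(all(diff(r$loglik_trace) >= -1e-6))
  r2 <- reml_univariate(d$pheno$a, d$pheno$herd, d$pheno$parity, d$grm)
  expect_true(all(diff(r2$loglik_trace) >= -1e-6))
})

test_that("a duplicated trait pins the genomic correlation at the boundary", {
  d <- make_reml_dataset(seed = 4)
  r <- reml_bivariate(d$pheno$a, d$pheno$a, d$pheno$herd, d$pheno$parity,
                      d$grm)
  expect_gt(abs(r$genomic_correlation), 0.999 - 1e-6)
  expect_true(r$boundary_flag)
})

test_that("an identity covariance makes the model unidentifiable", {
  d <- make_reml_dataset(seed = 5)
  expect_error(reml_univariate(d$pheno$a, d$pheno$herd, d$pheno$parity,
                               diag(nrow(d$pheno))),
               "identity")
})

test_that("a null-heritability trait lands at or near the zero bound", {
  cfg <- sim_config(n_individuals = 400, n_sires = 40, n_snps = 1000,
                    n_herds = 8, herd_size_range = c(20, 80), seed = 6)
  geno <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(geno, multi_trait_spec(list(trait_spec("z", 0))),
                            cfg)
  grm <- compute_grm(apply_qc(geno)$genotypes)
  r <- reml_univariate(ph$phenotypes$z, ph$phenotypes$herd,
                       ph$phenotypes$parity, grm)
  ## the REML solution under a zero true variance is either pinned at the
  ## bound (flagged) or a small positive estimate within its sampling noise
  expect_true(r$boundary_flag || r$h2 < 2 * r$se_h2 + 0.05)
})

test_that("weak small-n signal produces flagged boundary correlations", {
  flags <- logical(0); at_one <- logical(0)
  for (s in 1:5) {
    cfg <- sim_config(n_individuals = 50, n_sires = 25, n_snps = 400,
                      n_herds = 3, herd_size_range = c(5, 30), seed = s)
    geno <- simulate_genotypes(cfg)
    spec <- multi_trait_spec(list(trait_spec("a", 0.1), trait_spec("b", 0.1)),
                             matrix(c(1, .3, .3, 1), 2),
                             matrix(c(1, .2, .2, 1), 2))
    ph <- simulate_phenotypes(geno, spec, cfg)
    grm <- compute_grm(apply_qc(geno)$genotypes)
    r <- reml_bivariate(ph$phenotypes$a, ph$phenotypes$b, ph$phenotypes$herd,
                        ph$phenotypes$parity, grm)
    flags <- c(flags, r$boundary_flag)
    at_one <- c(at_one, abs(r$genomic_correlation) > 0.95)
  }
  expect_gte(sum(flags), 1)
  expect_gte(sum(at_one), 2)
})

test_that("method comparison pairs estimates and excludes boundary runs", {
  d <- make_reml_dataset(seed = 7)
  fr <- model_frame(as.matrix(d$pheno[, c("a", "b")]), d$pheno$herd,
                    d$pheno$parity, d$design)
  bv <- run_bivariate_chain(fr, mcmc_config(6000, 1500, 10, seed = 7))
  rr <- reml_bivariate(d$pheno$a, d$pheno$b, d$pheno$herd, d$pheno$parity,
                       d$grm)
  tab <- compare_bayes_reml(list(bv$summary), list(rr), phenotypes = d$pheno)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$abs_difference,
               abs(tab$r_bayes - tab$r_reml))
  expect_false(is.na(tab$phenotypic_correlation))

  ## a boundary-flagged REML run is kept in the table, not in the statistic
  rflag <- rr
  rflag$boundary_flag <- TRUE
  tab2 <- compare_bayes_reml(list(bv$summary, bv$summary), list(rr, rflag))
  expect_equal(nrow(tab2), 2L)
  expect_equal(attr(tab2, "mean_abs_difference"), tab2$abs_difference[1])
})
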