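test_that("schedule configuration is validated", {
  expect_error(mcmc_config(n_iterations = 100, burn_in = 100),
               class = "snpherit_config_error")
  expect_error(mcmc_config(n_iterations = 100, burn_in = 50, thin = 60),
               class = "snpherit_config_error")
  expect_error(mcmc_config(variance_upper_bound = -1),
               class = "snpherit_config_error")
  cfg <- mcmc_config()
  expect_equal((cfg$n_iterations - cfg$burn_in) / cfg$thin, 900)
})

test_that("model_frame drops missing phenotypes and keeps shapes aligned", {
  s <- sim_small(seed = 1, n = 30, sires = 15, m = 40)
  y <- s$pheno$a
  y[c(3, 7)] <- NA
  cd <- center_genotypes(apply_qc(s$geno)$genotypes)
  expect_message(fr <- model_frame(matrix(y, ncol = 1), s$pheno$herd,
                                   s$pheno$parity, cd),
                 "dropping 2")
  expect_equal(nrow(fr$y), 28L)
  expect_equal(nrow(fr$Z), 28L)
  expect_true(all(fr$W[, 1] == 1))
  expect_error(run_univariate_chain(
    model_frame(matrix(rep(1, 30), ncol = 1), s$pheno$herd, s$pheno$parity, cd),
    mcmc_config(200, 50, 1)), class = "snpherit_config_error")
})

test_that("genomic_variance uses the population denominator", {
  Z <- diag(2)
  expect_equal(genomic_variance(Z, c(1, -1)), 1)   # n-denominator Var{1,-1}
  expect_equal(genomic_variance(Z, c(0, 0)), 0)
  expect_equal(genomic_variance(Z, c(2, -2)), 4 * genomic_variance(Z, c(1, -1)))
  U <- cbind(c(1, -1), c(1, 1))
  V <- genomic_variance(Z, U)
  expect_equal(dim(V), c(2L, 2L))
  expect_error(genomic_variance(matrix(1, 1, 2), c(1, 1)), "at least 2")
})

test_that("chain summaries follow the frozen SD conventions", {
  ch <- fake_uni_chain(c(0.3, 0.3, 0.3))
  s <- summarize_chain(ch)
  expect_equal(s$h2_mean, 0.3)
  expect_equal(s$h2_psd, 0)
  ch2 <- fake_uni_chain(c(0.1, 0.3))
  s2 <- summarize_chain(ch2)
  expect_equal(s2$h2_mean, 0.2)
  expect_equal(s2$h2_psd, sqrt(0.02), tolerance = 1e-12)  # ~0.1414, n-1 SD
  expect_error(summarize_chain(fake_uni_chain(0.3)), "at least 2")
})

test_that("fixed-variance Gibbs matches the closed-form ridge posterior", {
  set.seed(42)
  n <- 8; m <- 3
  Z <- scale(matrix(rnorm(n * m), n, m), scale = FALSE)
  y <- rnorm(n)
  su <- 0.5; se <- 1.0
  fr <- model_frame(matrix(y, ncol = 1), rep("h1", n), rep(1, n), Z)
  res <- run_univariate_chain(fr, mcmc_config(60000, 5000, 10, seed = 7),
                              update_variances = FALSE,
                              sigma_u2 = su, sigma_e2 = se,
                              save_effects = TRUE)
  A <- crossprod(Z) + diag(se / su, m)
  closed_mean <- solve(A, crossprod(Z, y - mean(y)))
  closed_cov <- se * solve(A)
  ud <- res$chain$u_draws
  mcse <- apply(ud, 2, function(x) sd(x) / sqrt(effective_size(x)))
  expect_true(all(abs(res$chain$u_mean - closed_mean) < 3 * mcse))
  expect_lt(max(abs(cov(ud) - closed_cov)), 0.05 * max(abs(closed_cov)))
})

test_that("pure-noise phenotypes give a heritability posterior near zero", {
  set.seed(11)
  cfg <- sim_config(n_individuals = 500, n_sires = 250, n_snps = 1000,
                    n_herds = 10, herd_size_range = c(30, 80), seed = 12)
  geno <- simulate_genotypes(cfg)
  cd <- center_genotypes(apply_qc(geno)$genotypes)
  y <- rnorm(500)
  fr <- model_frame(matrix(y, ncol = 1), rep("h1", 500),
                    sample(1:3, 500, replace = TRUE), cd)
  res <- run_univariate_chain(fr, mcmc_config(4000, 1000, 5, seed = 13))
  expect_lt(res$summary$h2_mean, 0.15)
  expect_lt(unname(quantile(res$chain$draws$h2, 0.05)), 0.08)
})

test_that("derived posterior draws respect their analytic bounds", {
  s <- sim_small(seed = 6, n = 60, sires = 30, m = 100,
                 traits = list(trait_spec("a", 0.4), trait_spec("b", 0.4)),
                 Rg = matrix(c(1, .5, .5, 1), 2))
  cd <- center_genotypes(apply_qc(s$geno)$genotypes)
  fr <- model_frame(as.matrix(s$pheno[, c("a", "b")]), s$pheno$herd,
                    s$pheno$parity, cd)
  res <- run_bivariate_chain(fr, mcmc_config(3000, 500, 5, seed = 6))
  d <- res$chain$draws
  expect_true(all(d$h2_1 >= 0 & d$h2_1 <= 1))
  expect_true(all(d$h2_2 >= 0 & d$h2_2 <= 1))
  expect_true(all(abs(d$r_genomic) <= 1 + 1e-12))     # Cauchy-Schwarz per cycle
  expect_true(all(abs(d$r_environmental) <= 1 + 1e-12))
  expect_true(all(d$cov_zu12^2 <= d$var_zu1 * d$var_zu2 + 1e-12))
})

test_that("an identical trait pair has genomic and residual correlation one", {
  s <- sim_small(seed = 2, n = 100, sires = 50, m = 200)
  cd <- center_genotypes(apply_qc(s$geno)$genotypes)
  Y <- cbind(t1 = s$pheno$a, t2 = s$pheno$a)
  fr <- model_frame(Y, s$pheno$herd, s$pheno$parity, cd)
  res <- run_bivariate_chain(fr, mcmc_config(3000, 500, 5, seed = 3))
  expect_gt(res$summary$genomic_correlation_mean, 0.98)
  expect_gt(res$summary$environmental_correlation_mean, 0.98)
})

test_that("trait order does not change the genomic correlation", {
  s <- sim_small(seed = 8, n = 150, sires = 75, m = 300,
                 traits = list(trait_spec("a", 0.4), trait_spec("b", 0.4)),
                 Rg = matrix(c(1, .5, .5, 1), 2))
  cd <- center_genotypes(apply_qc(s$geno)$genotypes)
  fr12 <- model_frame(as.matrix(s$pheno[, c("a", "b")]), s$pheno$herd,
                      s$pheno$parity, cd)
  fr21 <- model_frame(as.matrix(s$pheno[, c("b", "a")]), s$pheno$herd,
                      s$pheno$parity, cd)
  r12 <- run_bivariate_chain(fr12, mcmc_config(8000, 2000, 10, seed = 4))
  r21 <- run_bivariate_chain(fr21, mcmc_config(8000, 2000, 10, seed = 5))
  mc <- r12$summary$genomic_correlation_psd /
    sqrt(effective_size(r12$chain$draws$r_genomic)) +
    r21$summary$genomic_correlation_psd /
    sqrt(effective_size(r21$chain$draws$r_genomic))
  expect_lt(abs(r12$summary$genomic_correlation_mean -
                  r21$summary$genomic_correlation_mean), 4 * mc)
})

test_that("Gibbs and Metropolis-Hastings modes agree on a shared problem", {
  cfgs <- sim_config(n_individuals = 150, n_sires = 75, n_snps = 100,
                     n_herds = 4, herd_size_range = c(20, 60), seed = 6)
  geno <- simulate_genotypes(cfgs)
  sp <- multi_trait_spec(list(trait_spec("a", 0.4)))
  sm <- simulate_phenotypes(geno, sp, cfgs)
  cd <- center_genotypes(apply_qc(geno)$genotypes)
  fr <- model_frame(sm$phenotypes[, "a", drop = FALSE], sm$phenotypes$herd,
                    sm$phenotypes$parity, cd)
  rg <- run_univariate_chain(fr, mcmc_config(40000, 5000, 10, seed = 1))
  rm <- run_univariate_chain(fr, mcmc_config(80000, 20000, 20, seed = 2,
                                             sampler = "metropolis_hastings",
                                             mh_block_size = 20))
  expect_gt(rm$chain$acceptance_rate, 0.1)
  expect_lt(rm$chain$acceptance_rate, 0.5)
  mcse <- rg$summary$h2_psd / sqrt(rg$summary$ess_h2) +
    rm$summary$h2_psd / sqrt(rm$summary$ess_h2)
  expect_lt(abs(rg$summary$h2_mean - rm$summary$h2_mean), 4 * mcse)
})
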