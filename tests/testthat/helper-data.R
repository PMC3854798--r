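## shared fixture builders; everything is generated in code at test time

## small half-sib dataset with one or more traits
sim_small <- function(seed = 1, n = 80, sires = 40, m = 200, herds = 4,
                      herd_size_range = c(1, n), traits = list(trait_spec("a", 0.3)),
                      Rg = NULL, Re = NULL, ...) {
  cfg <- sim_config(n_individuals = n, n_sires = sires, n_snps = m,
                    n_herds = herds, herd_size_range = herd_size_range,
                    seed = seed, ...)
  geno <- simulate_genotypes(cfg)
  spec <- multi_trait_spec(traits, Rg, Re)
  ph <- simulate_phenotypes(geno, spec, cfg)
  list(geno = geno, pheno = ph$phenotypes, truth = ph$truth, cfg = cfg,
       spec = spec)
}

## geno_matrix from an explicit small matrix
toy_geno <- function(values, chromosome = NULL) {
  geno_matrix(as.matrix(values), chromosome = chromosome)
}

## minimal chain_result wrapper around given h2 draws (for summary arithmetic)
fake_uni_chain <- function(h2, var_zu = h2, sigma_e2 = 1 - h2) {
  structure(list(draws = data.frame(sigma_u2 = h2, sigma_e2 = sigma_e2,
                                    var_zu = var_zu, h2 = h2),
                 config = mcmc_config(n_iterations = 200, burn_in = 0,
                                      thin = 1, seed = 1),
                 trait = "t"),
            class = "chain_result")
}

## random per-cow fatty-acid table on the measured panel
random_fa_table <- function(n = 20, seed = 99) {
  set.seed(seed)
  means <- table1_means()
  fa <- fa_trait_definitions()$fatty_acids
  tbl <- as.data.frame(lapply(means[fa], function(m)
    pmax(0, stats::rnorm(n, m, 0.1 * m))), check.names = FALSE)
  names(tbl) <- fa
  cbind(data.frame(id = sprintf("cow%02d", seq_len(n))), tbl)
}
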