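#' MCMC schedule configuration
#'
#' Defaults reproduce the study schedule: 100000 iterations, the first 10000
#' discarded as burn-in, every 100th cycle saved (900 saved draws).
#'
#' @param n_iterations total Gibbs/MH cycles.
#' @param burn_in cycles discarded before saving.
#' @param thin save every `thin`-th post-burn-in cycle.
#' @param seed integer seed for the chain.
#' @param sampler `"gibbs"` (exact single-site, the correctness reference)
#'   or `"metropolis_hastings"` (blocked random-walk on the SNP effects with
#'   step size adapted during burn-in).
#' @param variance_upper_bound optional truncation of the flat variance
#'   priors; draws above the bound are rejected and redrawn.
#' @param mh_block_size SNPs per MH proposal block.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_iterations = 100000, burn_in = 10000, thin = 100,
                        seed = 1, sampler = c("gibbs", "metropolis_hastings"),
                        variance_upper_bound = Inf, mh_block_size = 50) {
  n_iterations <- assert_count(n_iterations, "n_iterations")
  burn_in <- assert_count(burn_in, "burn_in", min = 0L)
  thin <- assert_count(thin, "thin")
  if (burn_in >= n_iterations)
    stop_config("burn_in must be smaller than n_iterations")
  if ((n_iterations - burn_in) < thin)
    stop_config("no draws would be saved: (n_iterations - burn_in) < thin")
  sampler <- match.arg(sampler)
  if (!is.numeric(variance_upper_bound) || variance_upper_bound <= 0)
    stop_config("variance_upper_bound must be positive (or Inf)")
  structure(list(n_iterations = n_iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), sampler = sampler,
                 variance_upper_bound = variance_upper_bound,
                 mh_block_size = assert_count(mh_block_size, "mh_block_size")),
            class = "mcmc_config")
}

#' Model frame for the SNP-BLUP mixed model
#'
#' Assembles `y = mu + X1 b1 + X2 b2 + Z u + e`: an intercept plus herd and
#' parity incidence (first level of each factor absorbed into the intercept
#' to keep the fixed-effect design full rank) and the centered SNP
#' covariates. Rows with a missing phenotype (either trait, bivariate) are
#' dropped with a message.
#'
#' @param y numeric vector (univariate) or 2-column matrix/data.frame
#'   (bivariate) of phenotypes.
#' @param herd,parity factors (or coercible) per individual.
#' @param Z centered SNP design: a [center_genotypes()] result or a plain
#'   numeric matrix.
#' @return a `model_frame` list with `y`, `W` (fixed design), `Z`,
#'   `n_traits`, `trait_names`, `kept` (row index into the input).
#' @export
model_frame <- function(y, herd, parity, Z) {
  if (inherits(Z, "centered_design")) Z <- Z$Z
  Z <- as.matrix(Z)
  y <- as.matrix(y)
  if (!ncol(y) %in% 1:2) stop_config("y must have one or two trait columns")
  if (nrow(y) != nrow(Z) || length(herd) != nrow(Z) || length(parity) != nrow(Z))
    stop_config("y, herd, parity and Z must agree on the number of individuals")
  keep <- stats::complete.cases(y)
  if (!all(keep))
    message("dropping ", sum(!keep), " individual(s) with missing phenotype")
  if (sum(keep) < 2L) stop_config("fewer than 2 individuals with phenotypes")
  y <- y[keep, , drop = FALSE]
  herd <- droplevels(factor(herd[keep]))
  parity <- droplevels(factor(parity[keep]))
  W <- fixed_design(herd, parity)
  structure(list(y = y, W = W, Z = Z[keep, , drop = FALSE],
                 herd = herd, parity = parity,
                 n_traits = ncol(y),
                 trait_names = colnames(y) %||% paste0("trait", seq_len(ncol(y))),
                 kept = which(keep)),
            class = "model_frame")
}

#' Empirical SNP-explained (co)variance Var(Zu)
#'
#' The per-cycle genomic variance of the model: the population (n
#' denominator) variance over individuals of the genomic values `g = Z u`,
#' or their 2x2 covariance matrix for a two-trait effect matrix.
#'
#' @param Z centered SNP design matrix.
#' @param u effect vector, or matrix with one column per trait.
#' @return scalar (one trait) or t x t covariance matrix.
#' @export
genomic_variance <- function(Z, u) {
  Z <- as.matrix(Z)
  u <- as.matrix(u)
  if (nrow(u) != ncol(Z)) stop("Z and u are not conformable")
  if (nrow(Z) < 2L) stop("need at least 2 individuals")
  pop_var(Z %*% u)
}

new_chain_result <- function(draws, config, extra = list()) {
  structure(c(list(draws = as.data.frame(draws), config = config), extra),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("chain_result: %d saved draws (%s sampler, seed %d)\n",
              nrow(x$draws), x$config$sampler, x$config$seed))
  invisible(x)
}

#' Univariate Bayesian SNP-BLUP chain
#'
#' Single-site Gibbs sampling of the random-regression SNP model: fixed
#' effects from their normal full conditionals (flat priors), SNP effects
#' from single-site normal full conditionals, residual and SNP-effect
#' variances from scaled inverse-chi-square full conditionals under flat
#' priors on the variance scale (df `n-2` and `m-2`). Each saved cycle
#' records the SNP-explained variance `Var(Zu)` and the heritability draw
#' `h2 = Var(Zu) / (Var(Zu) + sigma_e2)`.
#'
#' @param frame a [model_frame()] with one trait.
#' @param config an [mcmc_config()].
#' @param update_variances set `FALSE` to keep the variances fixed at
#'   `sigma_u2`/`sigma_e2` (used for closed-form validation).
#' @param sigma_u2,sigma_e2 initial (or fixed) variance values.
#' @param save_effects keep the per-cycle SNP-effect draws (memory heavy for
#'   large panels; intended for small validation problems).
#' @return list with `chain` (a `chain_result`) and `summary`
#'   (a `posterior_summary`, see [summarize_chain()]).
#' @export
run_univariate_chain <- function(frame, config = mcmc_config(),
                                 update_variances = TRUE,
                                 sigma_u2 = NULL, sigma_e2 = NULL,
                                 save_effects = FALSE) {
  stopifnot(inherits(frame, "model_frame"), inherits(config, "mcmc_config"))
  if (frame$n_traits != 1L) stop_config("frame has two traits; use run_bivariate_chain()")
  y <- frame$y[, 1L]
  if (stats::var(y) == 0) stop_config("phenotype has zero variance")
  vy <- stats::var(y)
  m <- ncol(frame$Z)
  sigma_e2 <- sigma_e2 %||% (vy / 2)
  ## half the phenotypic variance spread over the panel: sigma_u2 such that
  ## sigma_u2 * sum_j Var(Z_j) ~ vy/2
  sigma_u2 <- sigma_u2 %||% (vy / 2 / max(sum(frame$Z^2) / nrow(frame$Z), 1e-8))
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  res <- gibbs_univariate_cpp(y, frame$W, frame$Z,
                              config$n_iterations, config$burn_in, config$thin,
                              sigma_u2, sigma_e2, update_variances,
                              config$variance_upper_bound,
                              config$sampler == "metropolis_hastings",
                              config$mh_block_size, save_effects)
  draws <- res$draws
  colnames(draws) <- c("sigma_u2", "sigma_e2", "var_zu", "h2")
  fixed <- res$fixed_draws
  colnames(fixed) <- colnames(frame$W)
  chain <- new_chain_result(draws, config, list(
    fixed_draws = as.data.frame(fixed),
    u_mean = as.numeric(res$u_mean),
    u_draws = if (save_effects) res$u_draws,
    acceptance_rate = res$acceptance_rate,
    trait = frame$trait_names[1L],
    n = length(y), m = m,
    runtime = proc.time()[["elapsed"]] - t0))
  list(chain = chain, summary = summarize_chain(chain))
}

#' Bivariate Bayesian SNP-BLUP chain
#'
#' Two-trait extension: per-SNP effect 2-vectors sampled jointly from their
#' bivariate normal full conditionals given a 2x2 SNP-effect covariance, and
#' the residual 2x2 covariance sampled from its inverse-Wishart full
#' conditional under a flat prior (df `n-3`; SNP-effect covariance df
#' `m-3`). Each saved cycle evaluates `Var(Zu1)`, `Var(Zu2)` and
#' `Cov(Zu1, Zu2)` and the genomic correlation
#' `r = Cov(Zu1, Zu2) / sqrt(Var(Zu1) * Var(Zu2))`; the environmental
#' correlation comes from the residual covariance draws.
#'
#' @inheritParams run_univariate_chain
#' @param frame a [model_frame()] with two traits.
#' @param Sigma_u,Sigma_e optional initial (or fixed) 2x2 covariances.
#' @return list with `chain` and `summary` (a `bivariate_posterior`).
#' @export
run_bivariate_chain <- function(frame, config = mcmc_config(),
                                update_variances = TRUE,
                                Sigma_u = NULL, Sigma_e = NULL) {
  stopifnot(inherits(frame, "model_frame"), inherits(config, "mcmc_config"))
  if (frame$n_traits != 2L) stop_config("frame must contain two traits")
  Y <- frame$y
  if (any(apply(Y, 2L, stats::var) == 0))
    stop_config("a phenotype column has zero variance")
  vy <- apply(Y, 2L, stats::var)
  m <- ncol(frame$Z)
  mean_diag <- mean(colSums(frame$Z^2)) * m / nrow(Y)
  Sigma_e <- Sigma_e %||% diag(vy / 2)
  Sigma_u <- Sigma_u %||% diag(vy / 2 / mean_diag)
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  res <- gibbs_bivariate_cpp(Y, frame$W, frame$Z,
                             config$n_iterations, config$burn_in, config$thin,
                             Sigma_u, Sigma_e, update_variances,
                             config$variance_upper_bound,
                             config$sampler == "metropolis_hastings",
                             config$mh_block_size)
  draws <- res$draws
  colnames(draws) <- c("sigma_u2_1", "sigma_u2_2", "sigma_u_12",
                       "sigma_e2_1", "sigma_e2_2", "sigma_e_12",
                       "var_zu1", "var_zu2", "cov_zu12",
                       "r_genomic", "r_environmental", "h2_1", "h2_2")
  chain <- new_chain_result(draws, config, list(
    acceptance_rate = res$acceptance_rate,
    traits = frame$trait_names,
    n = nrow(Y), m = m,
    runtime = proc.time()[["elapsed"]] - t0))
  list(chain = chain, summary = summarize_chain(chain))
}

#' Posterior summaries of a chain
#'
#' Posterior means and posterior standard deviations (sample SD, n-1
#' denominator, over the saved draws) of the derived quantities, with
#' effective sample sizes and Geweke diagnostics attached.
#'
#' @param chain a `chain_result`.
#' @return a `posterior_summary` (univariate chain) or
#'   `bivariate_posterior` (bivariate chain).
#' @export
summarize_chain <- function(chain) {
  stopifnot(inherits(chain, "chain_result"))
  d <- chain$draws
  if (nrow(d) < 2L) stop("need at least 2 saved draws to summarize")
  if ("h2" %in% names(d)) {
    structure(list(
      trait = chain$trait,
      h2_mean = mean(d$h2), h2_psd = stats::sd(d$h2),
      var_zu_mean = mean(d$var_zu), var_zu_psd = stats::sd(d$var_zu),
      sigma_e2_mean = mean(d$sigma_e2), sigma_e2_psd = stats::sd(d$sigma_e2),
      sigma_u2_mean = mean(d$sigma_u2),
      ess_h2 = effective_size(d$h2),
      geweke_z_h2 = geweke_z(d$h2),
      n_draws = nrow(d)), class = "posterior_summary")
  } else {
    per_trait <- lapply(1:2, function(t) {
      h2 <- d[[paste0("h2_", t)]]
      structure(list(
        trait = chain$traits[t],
        h2_mean = mean(h2), h2_psd = stats::sd(h2),
        var_zu_mean = mean(d[[paste0("var_zu", t)]]),
        var_zu_psd = stats::sd(d[[paste0("var_zu", t)]]),
        sigma_e2_mean = mean(d[[paste0("sigma_e2_", t)]]),
        sigma_e2_psd = stats::sd(d[[paste0("sigma_e2_", t)]]),
        sigma_u2_mean = mean(d[[paste0("sigma_u2_", t)]]),
        ess_h2 = effective_size(h2),
        geweke_z_h2 = geweke_z(h2),
        n_draws = nrow(d)), class = "posterior_summary")
    })
    structure(list(
      traits = chain$traits,
      genomic_correlation_mean = mean(d$r_genomic),
      genomic_correlation_psd = stats::sd(d$r_genomic),
      environmental_correlation_mean = mean(d$r_environmental),
      environmental_correlation_psd = stats::sd(d$r_environmental),
      ess_r = effective_size(d$r_genomic),
      geweke_z_r = geweke_z(d$r_genomic),
      per_trait = per_trait,
      n_draws = nrow(d)), class = "bivariate_posterior")
  }
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("%s: h2 = %.3f (psd %.3f), Var(Zu) = %.4f, sigma_e2 = %.4f [ESS %.0f]\n",
              x$trait %||% "trait", x$h2_mean, x$h2_psd, x$var_zu_mean,
              x$sigma_e2_mean, x$ess_h2))
  invisible(x)
}

#' @export
print.bivariate_posterior <- function(x, ...) {
  cat(sprintf("%s ~ %s: r_genomic = %.3f (psd %.3f), r_environmental = %.3f (psd %.3f)\n",
              x$traits[1], x$traits[2],
              x$genomic_correlation_mean, x$genomic_correlation_psd,
              x$environmental_correlation_mean, x$environmental_correlation_psd))
  for (s in x$per_trait) print(s)
  invisible(x)
}
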