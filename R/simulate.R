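#' Simulation configuration
#'
#' Parameters of the half-sib genotype/phenotype generator. Defaults follow
#' the Danish Holstein sampling design this package targets: many sires each
#' with few daughter cows, herds of 3-24 cows, parities 1-3.
#'
#' @param n_individuals number of genotyped/phenotyped cows.
#' @param n_sires number of sires to gene-drop from (`<= n_individuals`).
#' @param n_snps number of SNP markers.
#' @param n_chromosomes SNPs are assigned to this many contiguous blocks.
#' @param allele_freq_range range of the uniform law for base allele
#'   frequencies of ordinary (polymorphic) SNPs.
#' @param n_herds number of herds.
#' @param herd_size_range (min, max) admissible herd sizes; sizes are drawn
#'   by constrained multinomial rejection so they sum to `n_individuals`.
#' @param parity_levels number of parity classes (cows assigned uniformly).
#' @param missing_rate completely-at-random missing genotype call rate.
#' @param monomorphic_rate fraction of SNPs forced monomorphic (QC fodder).
#' @param low_maf_rate fraction of SNPs with MAF below 0.01 (QC fodder).
#' @param seed integer seed; every simulation is reproducible from it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_individuals = 371, n_sires = 200, n_snps = 2000,
                       n_chromosomes = 10,
                       allele_freq_range = c(0.05, 0.95),
                       n_herds = 19, herd_size_range = c(3, 24),
                       parity_levels = 3, missing_rate = 0,
                       monomorphic_rate = 0, low_maf_rate = 0, seed = 1) {
  n_individuals <- assert_count(n_individuals, "n_individuals", 2L)
  n_sires <- assert_count(n_sires, "n_sires")
  n_snps <- assert_count(n_snps, "n_snps")
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes")
  n_herds <- assert_count(n_herds, "n_herds")
  parity_levels <- assert_count(parity_levels, "parity_levels")
  assert_prop(missing_rate, "missing_rate", allow_one = FALSE)
  assert_prop(monomorphic_rate, "monomorphic_rate", allow_one = FALSE)
  assert_prop(low_maf_rate, "low_maf_rate", allow_one = FALSE)
  if (monomorphic_rate + low_maf_rate >= 1)
    stop_config("monomorphic_rate + low_maf_rate must be < 1")
  if (n_sires > n_individuals)
    stop_config("n_sires must be <= n_individuals")
  if (n_chromosomes > n_snps)
    stop_config("n_chromosomes must be <= n_snps")
  if (length(allele_freq_range) != 2 || any(allele_freq_range <= 0) ||
      any(allele_freq_range >= 1) || diff(allele_freq_range) < 0)
    stop_config("allele_freq_range must be an increasing pair in (0,1)")
  if (length(herd_size_range) != 2 || herd_size_range[1] < 1 ||
      diff(herd_size_range) < 0)
    stop_config("herd_size_range must be an increasing pair of counts >= 1")
  if (n_herds * herd_size_range[1] > n_individuals ||
      n_herds * herd_size_range[2] < n_individuals)
    stop_config("herd sizes in the given range cannot sum to n_individuals")
  structure(as.list(environment()), class = "sim_config")
}

#' Single-trait generating parameters
#'
#' @param name trait label.
#' @param true_h2 target genomic heritability in `[0,1]`; the per-SNP effect
#'   variance is scaled so the expected `Var(Zu)` equals `true_h2` on a unit
#'   genetic-plus-residual variance scale.
#' @param herd_effect_sd SD of random herd effects (trait units).
#' @param parity_effects fixed effect per parity class (trait units).
#' @param mean overall trait mean.
#' @return a `trait_spec` list.
#' @export
trait_spec <- function(name, true_h2, herd_effect_sd = 0.3,
                       parity_effects = c(0, 0.2, 0.3), mean = 0) {
  assert_prop(true_h2, "true_h2")
  if (herd_effect_sd < 0) stop_config("herd_effect_sd must be >= 0")
  structure(list(name = as.character(name), true_h2 = true_h2,
                 herd_effect_sd = herd_effect_sd,
                 parity_effects = parity_effects, mean = mean),
            class = "trait_spec")
}

#' Multi-trait generating parameters
#'
#' @param traits list of [trait_spec()] objects.
#' @param genomic_correlations,residual_correlations symmetric PSD
#'   correlation matrices (unit diagonal) across traits; defaults identity.
#' @return a `multi_trait_spec` list.
#' @export
multi_trait_spec <- function(traits, genomic_correlations = NULL,
                             residual_correlations = NULL) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  k <- length(traits)
  if (k < 1L) stop_config("at least one trait is required")
  Rg <- genomic_correlations %||% diag(k)
  Re <- residual_correlations %||% diag(k)
  check_corr_matrix(Rg, "genomic_correlations")
  check_corr_matrix(Re, "residual_correlations")
  if (nrow(Rg) != k || nrow(Re) != k)
    stop_config("correlation matrices must be ", k, " x ", k)
  nms <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(nms)) stop_config("trait names must be unique")
  dimnames(Rg) <- dimnames(Re) <- list(nms, nms)
  structure(list(traits = traits, genomic_correlations = Rg,
                 residual_correlations = Re),
            class = "multi_trait_spec")
}

## Herd sizes by constrained multinomial rejection: multinomial draws of the
## exact total, rejected until every herd size lies in the admissible range.
draw_herd_sizes <- function(n, n_herds, range, max_tries = 10000L) {
  for (t in seq_len(max_tries)) {
    s <- as.vector(stats::rmultinom(1L, n, rep(1 / n_herds, n_herds)))
    if (all(s >= range[1] & s <= range[2])) return(s)
  }
  stop_config("could not draw herd sizes in [", range[1], ",", range[2],
              "] summing to ", n, " after ", max_tries, " tries")
}

#' Simulate half-sib genotypes
#'
#' Gene-dropping from a set of sires: each cow receives one gamete sampled
#' from a sire's genotype and one gamete from an unrelated dam drawn from the
#' base allele-frequency law. A configurable fraction of SNPs is made
#' monomorphic or low-MAF to exercise downstream quality control, and calls
#' are masked completely at random at `missing_rate`. SNPs are assigned to
#' `n_chromosomes` contiguous blocks; no within-chromosome linkage is
#' simulated.
#'
#' @param config a [sim_config()].
#' @return a [geno_matrix()] carrying `sire_ids` and the pre-masking
#'   `complete_values`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_snps
  n_mono <- round(config$monomorphic_rate * m)
  n_low <- round(config$low_maf_rate * m)

  p <- stats::runif(m, config$allele_freq_range[1], config$allele_freq_range[2])
  special <- sample.int(m, n_mono + n_low)
  mono_idx <- special[seq_len(n_mono)]
  low_idx <- special[setdiff(seq_len(n_mono + n_low), seq_len(n_mono))]
  if (n_mono) p[mono_idx] <- sample(c(0, 1), n_mono, replace = TRUE)
  if (n_low) p[low_idx] <- stats::runif(n_low, 0.001, 0.009)

  ## sire genotypes under HWE at the base frequencies
  sire_g <- matrix(stats::rbinom(config$n_sires * m, 2L, rep(p, each = config$n_sires)),
                   config$n_sires, m)
  sire_of <- sample.int(config$n_sires, n, replace = TRUE)
  ## paternal gamete: transmit one of the sire's two alleles
  sg <- sire_g[sire_of, , drop = FALSE]
  pat <- matrix(stats::rbinom(n * m, 1L, as.vector(sg) / 2), n, m)
  mat <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
  g <- pat + mat

  values <- g
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    values[mask] <- NA_integer_
  }
  chrom <- as.character(sort(rep_len(seq_len(config$n_chromosomes), m)))
  geno_matrix(values,
              individual_ids = sprintf("cow%03d", seq_len(n)),
              snp_ids = sprintf("snp%05d", seq_len(m)),
              chromosome = chrom,
              sire_ids = sprintf("sire%03d", sire_of),
              complete_values = g)
}

#' Simulate correlated phenotypes on given genotypes
#'
#' Generating model mirrors the fitted mixed model: per-SNP allele
#' substitution effects drawn jointly across traits from a zero-mean
#' multivariate normal (covariance scaled so the expected SNP-explained
#' variance `Var(Zu)` per trait equals `true_h2` on a unit
#' genetic-plus-residual scale), correlated residuals, random herd effects
#' and fixed parity effects added via incidence. Monomorphic SNPs receive a
#' zero effect (they cannot carry genomic variance).
#'
#' The realized -- not the target -- variance components are recorded as
#' truth: `Var(Zu)` and residual variances are recomputed from the emitted
#' genetic values and residuals with the population (n) denominator, so
#' `h2 = Var(Zu) / (Var(Zu) + Var(e))` holds exactly for the recorded values.
#'
#' @param genotypes a [geno_matrix()] (phenotypes use its pre-masking
#'   complete genotypes when present; otherwise mean-imputed calls).
#' @param spec a [multi_trait_spec()].
#' @param config the [sim_config()] used (herd structure, parities, seed).
#' @return list with `phenotypes` (data.frame: id, sire_id, herd, parity,
#'   one column per trait) and `truth` (a `sim_truth` list).
#' @export
simulate_phenotypes <- function(genotypes, spec, config) {
  stopifnot(inherits(genotypes, "geno_matrix"),
            inherits(spec, "multi_trait_spec"),
            inherits(config, "sim_config"))
  G <- genotypes$complete_values
  if (is.null(G)) {
    G <- genotypes$values
    if (anyNA(G)) {
      mu <- colMeans(G, na.rm = TRUE)
      idx <- which(is.na(G), arr.ind = TRUE)
      G[idx] <- mu[idx[, 2L]]
    }
  }
  n <- nrow(G); m <- ncol(G)
  if (n != config$n_individuals)
    stop_config("genotypes and config disagree on the number of individuals")
  k <- length(spec$traits)
  set.seed(config$seed + 1L)

  p <- colMeans(G) / 2
  poly <- p > 0 & p < 1
  Z <- sweep(G, 2L, 2 * p)                      # centered covariates
  denom <- 2 * sum(p[poly] * (1 - p[poly]))

  h2 <- vapply(spec$traits, `[[`, 0, "true_h2")
  sigma_a2 <- h2                                 # unit genetic+residual scale
  sigma_e2 <- 1 - h2
  ## per-SNP effect covariance: scale so E[Var(Zu)] hits sigma_a2
  sd_u <- sqrt(sigma_a2 / denom)
  Sigma_u <- spec$genomic_correlations * tcrossprod(sd_u)
  U <- matrix(0, m, k)
  U[poly, ] <- rmvn_psd(sum(poly), Sigma_u)

  Gval <- Z %*% U                                # genetic values, n x k
  sd_e <- sqrt(sigma_e2)
  Sigma_e <- spec$residual_correlations * tcrossprod(sd_e)
  E <- rmvn_psd(n, Sigma_e)

  herd_sizes <- draw_herd_sizes(n, config$n_herds, config$herd_size_range)
  herd <- rep(seq_len(config$n_herds), herd_sizes)[sample.int(n)]
  parity <- sample.int(config$parity_levels, n, replace = TRUE)
  herd_eff <- vapply(spec$traits, function(tr)
    stats::rnorm(config$n_herds, 0, tr$herd_effect_sd), numeric(config$n_herds))
  herd_eff <- matrix(herd_eff, config$n_herds, k)
  par_eff <- vapply(spec$traits, function(tr)
    rep_len(tr$parity_effects, config$parity_levels), numeric(config$parity_levels))
  par_eff <- matrix(par_eff, config$parity_levels, k)
  mu <- vapply(spec$traits, `[[`, 0, "mean")

  Y <- sweep(Gval + E + herd_eff[herd, , drop = FALSE] +
               par_eff[parity, , drop = FALSE], 2L, mu, `+`)
  nms <- vapply(spec$traits, `[[`, "", "name")
  colnames(Y) <- nms

  var_zu <- apply(Gval, 2L, function(g) pop_var(g))
  var_e <- apply(E, 2L, function(e) pop_var(e))
  realized_h2 <- ifelse(var_zu + var_e > 0, var_zu / (var_zu + var_e), 0)
  rg <- if (k > 1 && all(var_zu > 0)) stats::cov2cor(pop_var(Gval)) else
    diag(1, k)
  re <- if (k > 1) stats::cov2cor(pop_var(E)) else diag(1, k)
  dimnames(rg) <- dimnames(re) <- list(nms, nms)

  pheno <- data.frame(id = genotypes$individual_ids,
                      sire_id = genotypes$sire_ids %||% NA_character_,
                      herd = sprintf("herd%02d", herd),
                      parity = parity,
                      check.names = FALSE,
                      stringsAsFactors = FALSE)
  pheno <- cbind(pheno, as.data.frame(Y, check.names = FALSE))

  truth <- structure(list(
    trait_names = nms,
    target_h2 = stats::setNames(h2, nms),
    sigma_a2_target = stats::setNames(sigma_a2, nms),
    sigma_e2_target = stats::setNames(sigma_e2, nms),
    realized_var_zu = stats::setNames(var_zu, nms),
    realized_var_e = stats::setNames(var_e, nms),
    realized_h2 = stats::setNames(realized_h2, nms),
    genomic_correlations_target = spec$genomic_correlations,
    residual_correlations_target = spec$residual_correlations,
    realized_genomic_correlations = rg,
    realized_residual_correlations = re,
    snp_effects = U,
    genetic_values = Gval,
    herd_effects = herd_eff,
    parity_effects = par_eff,
    scaling_denominator = denom), class = "sim_truth")
  list(phenotypes = pheno, truth = truth)
}

#' One-call study-like dataset
#'
#' Preset emulating the target study design: 371 cows sired by 200 bulls,
#' 19 herds with 3-24 cows each, parities 1-3, 2400 SNPs on 12 chromosomes,
#' and four traits whose generating heritabilities span 0.07-0.35 with
#' genomic correlations spanning -0.60 to 0.91.
#'
#' @param seed integer seed.
#' @param n_snps marker panel size (default 2400).
#' @return list with `genotypes`, `phenotypes`, `truth`, `config`, `spec`.
#' @export
make_study_like_dataset <- function(seed = 1, n_snps = 2400) {
  config <- sim_config(n_individuals = 371, n_sires = 200, n_snps = n_snps,
                       n_chromosomes = 12, n_herds = 19,
                       herd_size_range = c(3, 24), parity_levels = 3,
                       missing_rate = 0.01, monomorphic_rate = 0.02,
                       low_maf_rate = 0.02, seed = seed)
  traits <- list(trait_spec("FA1", 0.07, mean = 10),
                 trait_spec("FA2", 0.14, mean = 20),
                 trait_spec("FA3", 0.25, mean = 5),
                 trait_spec("FA4", 0.35, mean = 2))
  Rg <- matrix(c(1, 0.91, 0.40, -0.60,
                 0.91, 1, 0.42, -0.53,
                 0.40, 0.42, 1, -0.22,
                 -0.60, -0.53, -0.22, 1), 4, 4)
  Re <- matrix(c(1, 0.90, 0.45, -0.65,
                 0.90, 1, 0.50, -0.60,
                 0.45, 0.50, 1, -0.20,
                 -0.65, -0.60, -0.20, 1), 4, 4)
  spec <- multi_trait_spec(traits, Rg, Re)
  geno <- simulate_genotypes(config)
  ph <- simulate_phenotypes(geno, spec, config)
  list(genotypes = geno, phenotypes = ph$phenotypes, truth = ph$truth,
       config = config, spec = spec)
}
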