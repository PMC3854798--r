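#' Full-analysis run configuration
#'
#' Either a simulation preset (self-contained run) or paths to genotype and
#' phenotype files, plus the QC, MCMC and REML settings, the traits to
#' analyse and the pairs to correlate.
#'
#' @param simulation optional [sim_config()] for a self-contained run.
#' @param trait_spec optional [multi_trait_spec()] (required with
#'   `simulation`).
#' @param genotype_file,phenotype_file input TSVs (ignored with
#'   `simulation`); genotype files ending in `.ped` are read as PLINK text.
#' @param traits character vector of trait columns to analyse (default: all
#'   trait columns).
#' @param pairs list of 2-vectors of trait names (default: all pairs).
#' @param qc a [qc_thresholds()].
#' @param mcmc an [mcmc_config()].
#' @param reml_ridge ridge added to the GRM diagonal before REML.
#' @param run_reml run the REML verification path (TRUE by default).
#' @param output_dir optional directory; when given, every stage's artifacts
#'   and a run log (seeds, dimensions, runtimes) are written there.
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = NULL, trait_spec = NULL,
                       genotype_file = NULL, phenotype_file = NULL,
                       traits = NULL, pairs = NULL,
                       qc = qc_thresholds(), mcmc = mcmc_config(),
                       reml_ridge = 0, run_reml = TRUE, output_dir = NULL) {
  if (is.null(simulation) && (is.null(genotype_file) || is.null(phenotype_file)))
    stop_config("either a simulation config or genotype+phenotype files are required")
  if (!is.null(simulation) && is.null(trait_spec))
    stop_config("a multi_trait_spec is required for a simulated run")
  structure(list(simulation = simulation, trait_spec = trait_spec,
                 genotype_file = genotype_file, phenotype_file = phenotype_file,
                 traits = traits, pairs = pairs, qc = qc, mcmc = mcmc,
                 reml_ridge = reml_ridge, run_reml = run_reml,
                 output_dir = output_dir), class = "run_config")
}

#' Raw phenotypic correlation
#'
#' Pearson correlation of two unadjusted trait columns (no fixed-effect
#' correction). Set `adjusted = TRUE` to correlate herd/parity-adjusted
#' residuals instead.
#'
#' @param pheno phenotype data.frame (needs herd and parity columns for the
#'   adjusted variant).
#' @param pair character 2-vector of trait names.
#' @param adjusted correlate fixed-effect residuals instead of raw values.
#' @return correlation value (`NA` with a message for a constant column).
#' @export
phenotypic_correlation <- function(pheno, pair, adjusted = FALSE) {
  stopifnot(length(pair) == 2L, all(pair %in% names(pheno)))
  x <- pheno[[pair[1]]]; y <- pheno[[pair[2]]]
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) stop("need at least 3 jointly observed cows")
  x <- x[ok]; y <- y[ok]
  if (adjusted) {
    f <- data.frame(herd = factor(pheno$herd[ok]),
                    parity = factor(pheno$parity[ok]))
    x <- stats::residuals(stats::lm(x ~ herd + parity, data = f))
    y <- stats::residuals(stats::lm(y ~ herd + parity, data = f))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("constant trait column in pair ", paste(pair, collapse = "~"),
            "; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> QC -> centering -> per-trait univariate
#' chains -> per-pair bivariate chains -> GRM -> REML per trait and pair ->
#' method comparison. Returns (and optionally writes) a report bundle:
#' a per-trait summary table (mean, SD, CV, median, h2, psd), correlation
#' matrices with environmental correlations below and genomic correlations
#' above the diagonal, and the comparison scatter data.
#'
#' @param config a [run_config()].
#' @return a `report_bundle` list: `trait_table`, `correlation_matrix`,
#'   `comparison`, `univariate`, `bivariate`, `reml_univariate`,
#'   `reml_bivariate`, `qc_report`, `grm`, `truth` (simulated runs), `log`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  truth <- NULL
  if (!is.null(config$simulation)) {
    geno <- stage("simulate_genotypes", simulate_genotypes(config$simulation))
    sim <- stage("simulate_phenotypes",
                 simulate_phenotypes(geno, config$trait_spec, config$simulation))
    pheno <- sim$phenotypes; truth <- sim$truth
    log$seed <- config$simulation$seed
  } else {
    geno <- stage("read_genotypes",
                  if (grepl("\\.ped$", config$genotype_file))
                    read_genotypes_plink(sub("\\.ped$", "", config$genotype_file))
                  else read_genotypes_tsv(config$genotype_file))
    pheno <- stage("read_phenotypes", read_phenotypes_tsv(config$phenotype_file))
  }

  qcres <- stage("qc", apply_qc(geno, config$qc))
  geno_qc <- qcres$genotypes
  keep <- match(geno_qc$individual_ids, pheno$id)
  if (anyNA(keep)) stop("phenotype table lacks some genotyped individuals")
  pheno <- pheno[keep, , drop = FALSE]
  design <- stage("center", center_genotypes(geno_qc))

  non_trait <- c("id", "sire_id", "herd", "parity")
  traits <- config$traits %||% setdiff(names(pheno), non_trait)
  if (!all(traits %in% names(pheno)))
    stop_config("traits not in the phenotype table: ",
                paste(setdiff(traits, names(pheno)), collapse = ", "))
  pairs <- config$pairs %||% utils::combn(traits, 2L, simplify = FALSE)
  for (p in pairs)
    if (!all(p %in% traits)) stop_config("pair refers to unknown trait")

  mcfg <- config$mcmc
  uni <- list()
  for (i in seq_along(traits)) {
    tr <- traits[i]
    cfg_t <- mcfg; cfg_t$seed <- mcfg$seed + i  # deterministic child seeds
    fr <- model_frame(stats::setNames(pheno[, tr, drop = FALSE], tr),
                      pheno$herd, pheno$parity, design)
    uni[[tr]] <- stage(paste0("univariate_", tr),
                       run_univariate_chain(fr, cfg_t))
    log[[paste0("seed_univariate_", tr)]] <- cfg_t$seed
  }

  biv <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    key <- paste(p, collapse = "~")
    cfg_p <- mcfg; cfg_p$seed <- mcfg$seed + 1000L + i
    fr <- model_frame(pheno[, p], pheno$herd, pheno$parity, design)
    biv[[key]] <- stage(paste0("bivariate_", key),
                        run_bivariate_chain(fr, cfg_p))
    log[[paste0("seed_bivariate_", key)]] <- cfg_p$seed
  }

  grm <- stage("grm", compute_grm(geno_qc))
  reml_uni <- list(); reml_biv <- list(); comparison <- NULL
  if (config$run_reml) {
    for (tr in traits)
      reml_uni[[tr]] <- stage(paste0("reml_", tr),
                              reml_univariate(pheno[[tr]], pheno$herd,
                                              pheno$parity, grm,
                                              ridge = config$reml_ridge))
    for (p in pairs) {
      key <- paste(p, collapse = "~")
      reml_biv[[key]] <- stage(paste0("reml_", key),
                               reml_bivariate(pheno[[p[1]]], pheno[[p[2]]],
                                              pheno$herd, pheno$parity, grm,
                                              ridge = config$reml_ridge))
    }
    comparison <- compare_bayes_reml(lapply(biv, `[[`, "summary"),
                                     reml_biv, phenotypes = pheno)
  }

  ## Table-1 style per-trait summary
  tt <- summarize_traits(pheno, traits)
  tt$h2 <- vapply(uni[traits], function(u) u$summary$h2_mean, 0)
  tt$psd <- vapply(uni[traits], function(u) u$summary$h2_psd, 0)

  ## correlation matrix: environmental below, genomic above the diagonal
  k <- length(traits)
  cm <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(cm) <- 1
  for (key in names(biv)) {
    p <- strsplit(key, "~", fixed = TRUE)[[1]]
    i <- match(p[1], traits); j <- match(p[2], traits)
    s <- biv[[key]]$summary
    cm[min(i, j), max(i, j)] <- s$genomic_correlation_mean
    cm[max(i, j), min(i, j)] <- s$environmental_correlation_mean
  }

  bundle <- structure(list(
    trait_table = tt, correlation_matrix = cm, comparison = comparison,
    univariate = uni, bivariate = biv,
    reml_univariate = reml_uni, reml_bivariate = reml_biv,
    qc_report = qcres$report, grm = grm, truth = truth, log = log),
    class = "report_bundle")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    utils::write.table(tt, file.path(od, "trait_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(cbind(trait = rownames(cm), as.data.frame(cm)),
                       file.path(od, "correlation_matrix.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(comparison))
      utils::write.table(comparison, file.path(od, "method_comparison.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    write_grm_tsv(grm, file.path(od, "grm.tsv"))
    for (tr in names(uni)) write_chain(uni[[tr]]$chain,
                                       file.path(od, paste0("chain_", gsub("[^A-Za-z0-9]", "_", tr))))
    if (!is.null(truth)) write_truth_json(truth, file.path(od, "truth.json"))
    jsonlite::write_json(log, file.path(od, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n")
  print(x$trait_table, digits = 3)
  cat("\ncorrelation matrix (environmental below / genomic above diagonal):\n")
  print(round(x$correlation_matrix, 3))
  invisible(x)
}
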