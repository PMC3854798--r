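#' Marker / individual quality-control thresholds
#'
#' Defaults follow common genotyping-panel practice for this kind of study:
#' individuals kept at call rate >= 80%, loci at call rate >= 95%, and loci
#' with minor allele frequency below 1% excluded (which necessarily removes
#' monomorphic loci).
#'
#' @param min_individual_call_rate,min_locus_call_rate,min_maf proportions.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_individual_call_rate = 0.80,
                          min_locus_call_rate = 0.95,
                          min_maf = 0.01) {
  assert_prop(min_individual_call_rate, "min_individual_call_rate")
  assert_prop(min_locus_call_rate, "min_locus_call_rate")
  assert_prop(min_maf, "min_maf")
  structure(list(min_individual_call_rate = min_individual_call_rate,
                 min_locus_call_rate = min_locus_call_rate,
                 min_maf = min_maf), class = "qc_thresholds")
}

#' Apply genotype quality control
#'
#' Filter order is frozen for reproducibility: (1) individuals below the
#' individual call-rate threshold, then (2) loci below the locus call-rate
#' threshold with call rates recomputed on the retained individuals, then
#' (3) loci with MAF below `min_maf` computed on non-missing calls of the
#' retained individuals. The report itemizes every removal with its reason.
#'
#' @param genotypes a [geno_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (filtered [geno_matrix()]) and `report`
#'   (class `qc_report`).
#' @export
apply_qc <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  v <- genotypes$values
  if (nrow(v) == 0L || ncol(v) == 0L) stop("empty genotype matrix")

  ind_cr <- rowMeans(!is.na(v))
  keep_ind <- ind_cr >= thresholds$min_individual_call_rate
  ind_removed <- data.frame(
    id = genotypes$individual_ids[!keep_ind],
    reason = rep("call_rate", sum(!keep_ind)),
    value = ind_cr[!keep_ind], stringsAsFactors = FALSE)
  if (!any(keep_ind)) stop("QC removed all individuals")
  v2 <- v[keep_ind, , drop = FALSE]

  loc_cr <- colMeans(!is.na(v2))
  bad_cr <- loc_cr < thresholds$min_locus_call_rate
  p <- colMeans(v2, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0                       # all-missing locus
  bad_maf <- !bad_cr & maf < thresholds$min_maf
  snp_removed <- rbind(
    data.frame(id = genotypes$snp_ids[bad_cr],
               reason = rep("call_rate", sum(bad_cr)),
               value = loc_cr[bad_cr], stringsAsFactors = FALSE),
    data.frame(id = genotypes$snp_ids[bad_maf],
               reason = ifelse(maf[bad_maf] == 0, "monomorphic", "maf"),
               value = maf[bad_maf], stringsAsFactors = FALSE))
  keep_snp <- !(bad_cr | bad_maf)
  if (!any(keep_snp)) stop("QC removed all SNPs")

  out <- subset_geno(genotypes, which(keep_ind), which(keep_snp))
  report <- structure(list(
    individuals_removed = ind_removed,
    snps_removed = snp_removed,
    n_individuals_before = nrow(v), n_individuals_after = nrow(out$values),
    n_snps_before = ncol(v), n_snps_after = ncol(out$values),
    thresholds = thresholds), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: individuals %d -> %d, SNPs %d -> %d\n",
              x$n_individuals_before, x$n_individuals_after,
              x$n_snps_before, x$n_snps_after))
  if (nrow(x$snps_removed))
    print(table(x$snps_removed$reason))
  invisible(x)
}

#' Centered SNP design matrix
#'
#' Builds the covariate matrix of the random-regression SNP model: missing
#' calls imputed to the per-SNP mean `2*p`, then each column centered on its
#' observed mean, so every column sums to zero and imputed entries carry no
#' genomic signal. Records the observed allele frequencies and the scaling
#' denominator `2 * sum(p * (1 - p))`.
#'
#' @param genotypes a QC'd [geno_matrix()] (no monomorphic columns).
#' @return a `centered_design` list with `Z`, `allele_freqs`,
#'   `scaling_denominator`, `individual_ids`, `snp_ids`, `chromosome`.
#' @export
center_genotypes <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  v <- genotypes$values
  p <- colMeans(v, na.rm = TRUE) / 2
  if (any(is.nan(p) | p <= 0 | p >= 1))
    stop("monomorphic or all-missing column present; run apply_qc() first")
  Z <- sweep(v, 2L, 2 * p)
  Z[is.na(Z)] <- 0                            # mean imputation after centering
  storage.mode(Z) <- "double"
  structure(list(Z = Z,
                 allele_freqs = stats::setNames(p, genotypes$snp_ids),
                 scaling_denominator = 2 * sum(p * (1 - p)),
                 individual_ids = genotypes$individual_ids,
                 snp_ids = genotypes$snp_ids,
                 chromosome = genotypes$chromosome),
            class = "centered_design")
}
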