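#' Genomic relationship matrix (VanRaden method 1)
#'
#' Codes genotypes in `M` as -1/0/1 for the two homozygotes and the
#' heterozygote, subtracts `P` (column i equal to `2 * (p_i - 0.5)`, with
#' `p_i` the observed frequency of the counted allele) to give `Z`, and
#' returns `G = Z Z' / (2 * sum(p_i * (1 - p_i)))`. Missing calls are
#' imputed to the locus mean (a zero row entry of `Z`). This is numerically
#' identical to the cross-product of the centered 0/1/2 design divided by
#' the same denominator.
#'
#' @param genotypes a QC'd [geno_matrix()] with no monomorphic columns.
#' @param ridge optional non-negative value added to the diagonal (logged
#'   via a message when positive); useful before REML inversion.
#' @return a `grm` object: `values` (symmetric n x n matrix),
#'   `scaling_denominator`, `individual_ids`, `n_snps`.
#' @export
compute_grm <- function(genotypes, ridge = 0) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  v <- genotypes$values
  if (nrow(v) == 0L || ncol(v) == 0L) stop("empty genotype matrix")
  p <- colMeans(v, na.rm = TRUE) / 2
  if (any(is.nan(p) | p <= 0 | p >= 1))
    stop("monomorphic or all-missing column present; run apply_qc() first")
  M <- v - 1                                   # -1/0/1 coding
  Z <- sweep(M, 2L, 2 * (p - 0.5))
  Z[is.na(Z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  if (ridge > 0) {
    message("adding ridge ", format(ridge), " to the GRM diagonal")
    G <- G + diag(ridge, nrow(G))
  }
  structure(list(values = G, scaling_denominator = denom,
                 individual_ids = genotypes$individual_ids,
                 n_snps = ncol(v)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d individuals, %d SNPs, denominator %.3f\n",
              nrow(x$values), x$n_snps, x$scaling_denominator))
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.4f\n",
              mean(diag(x$values)),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Per-chromosome genomic relationship matrices
#'
#' @param genotypes a QC'd [geno_matrix()].
#' @return named list of `grm` objects, one per chromosome.
#' @export
compute_grm_by_chromosome <- function(genotypes) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  chroms <- unique(genotypes$chromosome)
  out <- lapply(chroms, function(ch)
    compute_grm(subset_geno(genotypes, snps = which(genotypes$chromosome == ch))))
  stats::setNames(out, chroms)
}

#' Combine per-chromosome GRMs
#'
#' Denominator-weighted average `G = sum(d_c * G_c) / sum(d_c)`, which
#' reproduces the whole-genome GRM on the concatenated SNP set exactly.
#' Chromosomes with a zero denominator are excluded from both sums.
#'
#' @param per_chromosome list of `grm` objects over identical individuals.
#' @return a combined `grm`.
#' @export
combine_chromosome_grms <- function(per_chromosome) {
  stopifnot(length(per_chromosome) >= 1L,
            all(vapply(per_chromosome, inherits, TRUE, "grm")))
  ids <- per_chromosome[[1L]]$individual_ids
  for (g in per_chromosome)
    if (!identical(g$individual_ids, ids))
      stop("all GRMs must cover the same individuals in the same order")
  d <- vapply(per_chromosome, `[[`, 0, "scaling_denominator")
  keep <- d > 0
  if (!any(keep)) stop("all chromosome denominators are zero")
  per <- per_chromosome[keep]; d <- d[keep]
  G <- Reduce(`+`, Map(function(g, w) g$values * w, per, d)) / sum(d)
  structure(list(values = G, scaling_denominator = sum(d),
                 individual_ids = ids,
                 n_snps = sum(vapply(per, `[[`, 0L, "n_snps"))),
            class = "grm")
}

#' Mean genomic relationship within sire families
#'
#' Diagnostic used by the half-sib simulation checks: average off-diagonal
#' entry of `G` among paternal half-sib pairs and among pairs with different
#' sires.
#'
#' @param grm a `grm` object.
#' @param sire_ids sire label per individual (same order as the GRM).
#' @return list with `halfsib_mean` and `unrelated_mean`.
#' @export
halfsib_relationship <- function(grm, sire_ids) {
  stopifnot(inherits(grm, "grm"), length(sire_ids) == nrow(grm$values))
  same <- outer(sire_ids, sire_ids, `==`)
  ut <- upper.tri(grm$values)
  list(halfsib_mean = mean(grm$values[ut & same]),
       unrelated_mean = mean(grm$values[ut & !same]))
}
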