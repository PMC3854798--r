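#' Genotype matrix container
#'
#' Holds an individuals x SNPs matrix of allele counts (0/1/2, `NA` for
#' missing calls) together with SNP chromosome assignments and, for
#' simulated data, the sire of each individual and the pre-masking complete
#' genotypes used to generate phenotypes.
#'
#' @param values integer matrix, individuals in rows, SNPs in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param individual_ids,snp_ids unique labels; default to row/col names.
#' @param chromosome character/integer vector, one label per SNP.
#' @param sire_ids optional sire label per individual (simulated data).
#' @param complete_values optional complete (no missing) genotype matrix of
#'   the same shape, kept by the simulator so phenotypes are defined
#'   independently of the missingness mask.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(values, individual_ids = rownames(values),
                        snp_ids = colnames(values), chromosome = NULL,
                        sire_ids = NULL, complete_values = NULL) {
  values <- as.matrix(values)
  if (is.null(individual_ids)) individual_ids <- paste0("id", seq_len(nrow(values)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(values)))
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  if (anyDuplicated(snp_ids)) stop("SNP ids must be unique")
  ok <- values[!is.na(values)]
  if (length(ok) && !all(ok %in% 0:2))
    stop("non-missing genotype entries must be allele counts in {0,1,2}")
  if (is.null(chromosome)) chromosome <- rep("1", ncol(values))
  if (length(chromosome) != ncol(values))
    stop("chromosome must have one entry per SNP")
  dimnames(values) <- list(individual_ids, snp_ids)
  structure(list(values = values,
                 individual_ids = individual_ids,
                 snp_ids = snp_ids,
                 chromosome = as.character(chromosome),
                 sire_ids = sire_ids,
                 complete_values = complete_values),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs on %d chromosome(s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$chromosome))))
  miss <- mean(is.na(x$values))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$values)

## Per-SNP frequency of the counted ("second") allele, from non-missing calls.
allele_freqs <- function(geno) {
  colMeans(geno$values, na.rm = TRUE) / 2
}

## Minor allele frequency per SNP.
snp_maf <- function(geno) {
  p <- allele_freqs(geno)
  pmin(p, 1 - p)
}

subset_geno <- function(geno, individuals = NULL, snps = NULL) {
  i <- individuals %||% seq_len(nrow(geno$values))
  j <- snps %||% seq_len(ncol(geno$values))
  geno_matrix(geno$values[i, j, drop = FALSE],
              chromosome = geno$chromosome[j],
              sire_ids = geno$sire_ids[i],
              complete_values = if (!is.null(geno$complete_values))
                geno$complete_values[i, j, drop = FALSE])
}
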