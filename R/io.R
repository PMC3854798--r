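## Plain-text readers/writers for the package's data exchange formats:
## genotype TSV (rows = individuals, 0/1/2, NA missing), PLINK .ped/.map
## text, phenotype TSV (id, sire_id, herd, parity, traits), GRM TSV with id
## header, simulation-truth JSON and chain TSV + JSON summary.

#' Write / read genotypes as TSV
#'
#' First column `id`, then one 0/1/2 column per SNP (`NA` for missing);
#' chromosome assignments go to a sidecar `<file>.chrom.tsv`.
#'
#' @param geno a [geno_matrix()].
#' @param file path to the TSV.
#' @return `read_genotypes_tsv` returns a [geno_matrix()].
#' @export
write_genotypes_tsv <- function(geno, file) {
  stopifnot(inherits(geno, "geno_matrix"))
  dt <- data.table::data.table(id = geno$individual_ids)
  dt <- cbind(dt, data.table::as.data.table(geno$values))
  data.table::fwrite(dt, file, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(data.table::data.table(snp = geno$snp_ids,
                                            chromosome = geno$chromosome),
                     paste0(file, ".chrom.tsv"), sep = "\t", quote = FALSE)
  invisible(file)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(file) {
  dt <- data.table::fread(file, sep = "\t", na.strings = "NA")
  ids <- as.character(dt[[1L]])
  v <- as.matrix(dt[, -1L])
  storage.mode(v) <- "integer"
  chrom <- NULL
  side <- paste0(file, ".chrom.tsv")
  if (file.exists(side)) {
    cd <- data.table::fread(side, sep = "\t")
    chrom <- as.character(cd$chromosome)[match(colnames(v), cd$snp)]
  }
  geno_matrix(v, individual_ids = ids, snp_ids = colnames(v),
              chromosome = chrom)
}

#' Write / read genotypes as PLINK text (.ped/.map)
#'
#' Alleles coded A (reference) / B (counted); missing calls written as
#' `0 0`. The .map carries chromosome and SNP id with zero genetic and
#' physical positions.
#'
#' @param geno a [geno_matrix()].
#' @param prefix path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return `read_genotypes_plink` returns a [geno_matrix()].
#' @export
write_genotypes_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "geno_matrix"))
  v <- geno$values
  code <- c("A A", "A B", "B B")
  gm <- matrix("0 0", nrow(v), ncol(v))
  ok <- !is.na(v)
  gm[ok] <- code[v[ok] + 1L]
  ped <- data.frame(fid = geno$individual_ids, iid = geno$individual_ids,
                    pat = 0, mat = 0, sex = 0, pheno = -9,
                    stringsAsFactors = FALSE)
  lines <- paste(ped$fid, ped$iid, ped$pat, ped$mat, ped$sex, ped$pheno,
                 apply(gm, 1L, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  map <- data.frame(chrom = geno$chromosome, snp = geno$snp_ids,
                    cm = 0, pos = seq_along(geno$snp_ids))
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_genotypes_plink
#' @export
read_genotypes_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chrom", "snp", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  ped <- utils::read.table(paste0(prefix, ".ped"),
                           colClasses = "character")
  ids <- ped[[2L]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  m <- nrow(map)
  if (ncol(al) != 2L * m) stop("ped/map disagree on the number of loci")
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  v <- (a1 == "B") + (a2 == "B")
  v[a1 == "0" | a2 == "0"] <- NA
  storage.mode(v) <- "integer"
  geno_matrix(v, individual_ids = ids, snp_ids = map$snp,
              chromosome = map$chrom)
}

#' Write / read phenotypes as TSV
#'
#' Columns: id, sire_id, herd, parity, then one column per trait.
#'
#' @param pheno phenotype data.frame.
#' @param file path.
#' @export
write_phenotypes_tsv <- function(pheno, file) {
  data.table::fwrite(pheno, file, sep = "\t", na = "NA", quote = FALSE)
  invisible(file)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(file) {
  as.data.frame(data.table::fread(file, sep = "\t", na.strings = "NA"))
}

#' Write / read a GRM as full-matrix TSV
#'
#' Square matrix with an id header row and an id first column; the scaling
#' denominator and SNP count are kept in comment lines (`#key value`).
#'
#' @param grm a `grm` object.
#' @param file path.
#' @export
write_grm_tsv <- function(grm, file) {
  stopifnot(inherits(grm, "grm"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste0("#scaling_denominator\t", format(grm$scaling_denominator, digits = 17)),
               paste0("#n_snps\t", grm$n_snps)), con)
  dt <- data.table::data.table(id = grm$individual_ids)
  dt <- cbind(dt, data.table::as.data.table(grm$values))
  data.table::setnames(dt, c("id", grm$individual_ids))
  utils::write.table(dt, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_grm_tsv
#' @export
read_grm_tsv <- function(file) {
  hdr <- readLines(file, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  kv <- do.call(rbind, strsplit(sub("^#", "", meta), "\t"))
  dt <- utils::read.table(file, sep = "\t", header = TRUE, skip = length(meta),
                          check.names = FALSE)
  ids <- as.character(dt[[1L]])
  G <- as.matrix(dt[, -1L]); dimnames(G) <- list(ids, ids)
  structure(list(values = G,
                 scaling_denominator = as.numeric(kv[kv[, 1] == "scaling_denominator", 2]),
                 individual_ids = ids,
                 n_snps = as.integer(kv[kv[, 1] == "n_snps", 2])),
            class = "grm")
}

#' Persist simulation truth as JSON
#'
#' @param truth a `sim_truth` from [simulate_phenotypes()].
#' @param file path.
#' @export
write_truth_json <- function(truth, file) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- truth
  class(out) <- NULL
  out$snp_effects <- NULL; out$genetic_values <- NULL  # bulky; regenerable
  ## named vectors as JSON objects, not bare arrays
  out <- lapply(out, function(x)
    if (is.numeric(x) && is.null(dim(x)) && !is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(file)
}

#' Persist a chain as TSV plus JSON summary
#'
#' One row per saved cycle in the TSV; the summary JSON carries posterior
#' means/psds, seed, dimensions, runtime and acceptance rate.
#'
#' @param chain a `chain_result`.
#' @param prefix path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @export
write_chain <- function(chain, prefix) {
  stopifnot(inherits(chain, "chain_result"))
  data.table::fwrite(chain$draws, paste0(prefix, ".tsv"), sep = "\t")
  s <- summarize_chain(chain)
  meta <- list(seed = chain$config$seed, sampler = chain$config$sampler,
               n_iterations = chain$config$n_iterations,
               burn_in = chain$config$burn_in, thin = chain$config$thin,
               n = chain$n, m = chain$m, runtime = chain$runtime,
               acceptance_rate = chain$acceptance_rate,
               summary = unclass_recursive(s))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}
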