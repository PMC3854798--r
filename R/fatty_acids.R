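## Milk fatty-acid trait derivation: groups (SFA, UFA, MUFA, PUFA, even-chain
## C6-C14) as per-cow sums of the measured weight proportions (g/100 g fat),
## and delta-9-desaturase indices as product / (product + substrate).

.FA_NAMES <- c("C6:0", "C8:0", "C10:0", "C12:0", "C13:0", "C14:0", "C15:0",
               "C16:0", "C17:0", "C18:0", "C14:1c9", "C16:1c9", "C18:1t11",
               "C18:1c9", "C18:2n6", "C18:3n3", "CLAc9t11")

#' Fatty-acid trait definitions
#'
#' Group memberships and desaturase product/substrate pairs for the 17
#' measured milk fatty acids. SFA and UFA partition the measured set; MUFA
#' and PUFA partition UFA. The even-chain C6-C14 group contains only the
#' even-chain members (C6:0, C8:0, C10:0, C12:0, C14:0) — C13:0 and C15:0
#' are excluded.
#'
#' @return a `fa_definitions` list: `fatty_acids`, `groups` (named list of
#'   member vectors), `indices` (named list of `c(product, substrate)`).
#' @export
fa_trait_definitions <- function() {
  groups <- list(
    SFA = c("C6:0", "C8:0", "C10:0", "C12:0", "C13:0", "C14:0", "C15:0",
            "C16:0", "C17:0", "C18:0"),
    UFA = c("C14:1c9", "C16:1c9", "C18:1t11", "C18:1c9", "C18:2n6",
            "C18:3n3", "CLAc9t11"),
    MUFA = c("C14:1c9", "C16:1c9", "C18:1t11", "C18:1c9"),
    PUFA = c("C18:2n6", "C18:3n3", "CLAc9t11"),
    C6toC14 = c("C6:0", "C8:0", "C10:0", "C12:0", "C14:0"))
  indices <- list(
    C14index = c(product = "C14:1c9", substrate = "C14:0"),
    C16index = c(product = "C16:1c9", substrate = "C16:0"),
    C18index = c(product = "C18:1c9", substrate = "C18:0"),
    CLAindex = c(product = "CLAc9t11", substrate = "C18:1t11"))
  structure(list(fatty_acids = .FA_NAMES, groups = groups, indices = indices),
            class = "fa_definitions")
}

#' Derive fatty-acid groups and desaturase indices
#'
#' Per cow, each group value is the sum of its member proportions and each
#' desaturase index is `product / (product + substrate)`. An index is
#' undefined (`NA`, counted in a message) for cows where product + substrate
#' is zero.
#'
#' @param table data.frame with one column per measured fatty acid (names as
#'   in [fa_trait_definitions()]); other columns (ids, fat content) pass
#'   through.
#' @param defs a `fa_definitions` object.
#' @return the input with group and index columns appended.
#' @export
derive_fa_traits <- function(table, defs = fa_trait_definitions()) {
  missing_cols <- setdiff(defs$fatty_acids, names(table))
  if (length(missing_cols))
    stop("missing fatty-acid column(s): ", paste(missing_cols, collapse = ", "))
  fa <- as.matrix(table[, defs$fatty_acids, drop = FALSE])
  if (any(fa < 0, na.rm = TRUE)) stop("fatty-acid proportions must be >= 0")
  out <- table
  for (g in names(defs$groups))
    out[[g]] <- rowSums(fa[, defs$groups[[g]], drop = FALSE])
  for (ix in names(defs$indices)) {
    prod <- fa[, defs$indices[[ix]][["product"]]]
    subs <- fa[, defs$indices[[ix]][["substrate"]]]
    tot <- prod + subs
    val <- ifelse(tot > 0, prod / tot, NA_real_)
    n_undef <- sum(tot == 0, na.rm = TRUE)
    if (n_undef > 0)
      message(ix, " undefined (product + substrate = 0) for ", n_undef, " cow(s)")
    out[[ix]] <- val
  }
  out
}

#' Per-trait summary statistics
#'
#' Mean, sample SD, coefficient of variation (SD/mean x 100) and median per
#' trait column. The CV is reported as `NA` (with a message) when the trait
#' mean is not positive.
#'
#' @param pheno data.frame of phenotypes.
#' @param traits character vector of columns to summarize (default: all
#'   numeric columns).
#' @return data.frame with columns trait, mean, sd, cv, median.
#' @export
summarize_traits <- function(pheno, traits = NULL) {
  traits <- traits %||% names(pheno)[vapply(pheno, is.numeric, TRUE)]
  if (nrow(pheno) < 2L) stop("need at least 2 cows to summarize")
  rows <- lapply(traits, function(tr) {
    x <- pheno[[tr]]
    if (is.null(x)) stop("trait not found: ", tr)
    x <- x[!is.na(x)]
    m <- mean(x); s <- stats::sd(x)
    cv <- if (m > 0) s / m * 100 else {
      message("CV undefined for ", tr, " (mean <= 0)"); NA_real_
    }
    data.frame(trait = tr, mean = m, sd = s, cv = cv, median = stats::median(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published per-trait summary fixture
#'
#' The printed milk fatty-acid summary table this package's trait
#' definitions are checked against: per-trait mean, SD, CV, median and the
#' published genomic heritability with its posterior standard deviation, for
#' fat content (g/100 g milk), the 17 measured fatty acids (g/100 g fat),
#' their groups, and the four desaturase indices.
#'
#' @return data.frame (trait, group, mean, sd, cv, median, h2, psd).
#' @export
table1_summary <- function() {
  path <- system.file("extdata", "table1_milk_fa_summary.tsv",
                      package = "snpherit", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Published fatty-acid mean composition
#'
#' Named vector of the printed mean weight proportions of the 17 measured
#' fatty acids plus the fat content mean, used by the composition-identity
#' checks (group means are sums of member means by linearity).
#'
#' @return named numeric vector (17 fatty acids + `Fat`).
#' @export
table1_means <- function() {
  tab <- table1_summary()
  stats::setNames(tab$mean, tab$trait)[c(.FA_NAMES, "Fat")]
}
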