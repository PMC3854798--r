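`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("snpherit_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_prop <- function(x, name, allow_one = TRUE) {
  hi <- if (allow_one) 1 else 1 - 1e-12
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > hi)
    stop_config(name, " must be a proportion in [0,", if (allow_one) "1]" else "1)",
                ", got ", format(x))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_config(name, " must be an integer >= ", min, ", got ", format(x))
  invisible(as.integer(x))
}

## Intercept + treatment-coded herd and parity incidence; factors with a
## single level are absorbed into the intercept.
fixed_design <- function(herd, parity) {
  herd <- droplevels(factor(herd))
  parity <- droplevels(factor(parity))
  terms <- c(if (nlevels(herd) > 1) "herd", if (nlevels(parity) > 1) "parity")
  f <- if (length(terms)) stats::reformulate(terms) else ~1
  W <- stats::model.matrix(f, data = data.frame(herd = herd, parity = parity))
  attr(W, "assign") <- NULL
  attr(W, "contrasts") <- NULL
  W
}

#' Population (co)variance with n denominator
#'
#' Variance/covariance over individuals using the n (not n-1) denominator,
#' the convention used for per-cycle genomic variances.
#' @param x numeric vector or matrix (columns = variables).
#' @return scalar (vector input) or covariance matrix.
#' @keywords internal
pop_var <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 observations for a variance")
  xc <- sweep(x, 2L, colMeans(x))
  v <- crossprod(xc) / n
  if (ncol(v) == 1L) v[1L, 1L] else v
}

## Draw from N(0, Sigma) for a PSD (possibly singular) Sigma via eigen
## decomposition; negative eigenvalues below tolerance are clipped to zero.
rmvn_psd <- function(n, sigma) {
  p <- ncol(sigma)
  ee <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(ee$values, 0)
  A <- ee$vectors %*% (t(ee$vectors) * sqrt(lam))
  matrix(stats::rnorm(n * p), n, p) %*% t(A)
}

check_corr_matrix <- function(R, name) {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop_config(name, " must be a square matrix")
  if (max(abs(R - t(R))) > 1e-10)
    stop_config(name, " must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10)
    stop_config(name, " must have unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop_config(name, " must be positive semi-definite")
  invisible(R)
}

#' Effective sample size of an MCMC draw sequence
#'
#' Initial positive sequence estimator based on the sample autocorrelation
#' function: n / (1 + 2 * sum(rho_k)) truncated at the first non-positive
#' pair sum.
#' @param x numeric vector of draws.
#' @return effective sample size (capped at `length(x)`).
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(n)
  lag_max <- min(n - 2L, 1000L)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[-1L]
  s <- 0
  k <- 1L
  while (k <= length(rho)) {
    pair <- rho[k] + if (k + 1L <= length(rho)) rho[k + 1L] else 0
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' Geweke convergence diagnostic
#'
#' Z-score comparing the mean of the first `frac1` and last `frac2` of a
#' chain, with segment variances scaled by their effective sample sizes.
#' @param x numeric vector of draws.
#' @param frac1,frac2 fractions of the chain used for the two windows.
#' @return z statistic (approximately N(0,1) under stationarity).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[seq.int(n - max(2L, floor(frac2 * n)) + 1L, n)]
  va <- stats::var(a) / effective_size(a)
  vb <- stats::var(b) / effective_size(b)
  if (va + vb == 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}
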