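## Average-information REML for the GBLUP animal model
##
##   y_t = X b_t + g_t + e_t,  g ~ N(0, Sigma_g x G),  e ~ N(0, Sigma_e x I)
##
## for t = 1 (univariate) or t = 2 (bivariate) traits with complete trait
## overlap. G is eigendecomposed once (G = U D U'); in the rotated basis the
## phenotypic covariance is block diagonal with t x t blocks
## V_i = d_i Sigma_g + Sigma_e, so likelihood, score, average-information
## matrix and EM updates all cost O(n p^2) per iteration.

## symmetric basis index helpers for t traits (vech order: 11, 21, 22)
vech_pairs <- function(t) {
  out <- list()
  for (j in seq_len(t)) for (i in j:t) out[[length(out) + 1L]] <- c(i, j)
  out
}

theta_to_mats <- function(theta, t) {
  np <- t * (t + 1) / 2
  pairs <- vech_pairs(t)
  Sg <- Se <- matrix(0, t, t)
  for (k in seq_len(np)) {
    ij <- pairs[[k]]
    Sg[ij[1], ij[2]] <- Sg[ij[2], ij[1]] <- theta[k]
    Se[ij[1], ij[2]] <- Se[ij[2], ij[1]] <- theta[np + k]
  }
  list(Sg = Sg, Se = Se)
}

mats_to_theta <- function(Sg, Se) {
  t <- nrow(Sg)
  pairs <- vech_pairs(t)
  c(vapply(pairs, function(ij) Sg[ij[1], ij[2]], 0),
    vapply(pairs, function(ij) Se[ij[1], ij[2]], 0))
}

## clamp a covariance matrix to the admissible region: variances >= vfloor,
## |correlations| <= rmax; returns the matrix and whether clamping happened
clamp_cov <- function(S, vfloor, rmax = 0.9999) {
  t <- nrow(S)
  hit <- FALSE
  d <- diag(S)
  if (any(d < vfloor)) { d <- pmax(d, vfloor); hit <- TRUE }
  if (t == 2) {
    lim <- rmax * sqrt(d[1] * d[2])
    if (abs(S[1, 2]) > lim) {
      S[1, 2] <- S[2, 1] <- sign(S[1, 2]) * lim
      hit <- TRUE
    }
  }
  diag(S) <- d
  list(S = S, hit = hit)
}

## core REML state evaluation at theta: loglik, score, AI, projected data
reml_eval <- function(theta, t, d, Yr, Xr, compute_ai = TRUE) {
  n <- nrow(Yr); p0 <- ncol(Xr); np <- t * (t + 1) / 2
  ms <- theta_to_mats(theta, t)
  Sg <- ms$Sg; Se <- ms$Se
  if (t == 1) {
    V11 <- d * Sg[1, 1] + Se[1, 1]
    if (any(V11 <= 0)) return(NULL)
    Vinv <- list(matrix(1 / V11, ncol = 1))   # store as n-vectors per (s,t)
    logdet <- sum(log(V11))
    Vi <- array(1 / V11, c(n, 1, 1))
  } else {
    a <- d * Sg[1, 1] + Se[1, 1]
    b <- d * Sg[1, 2] + Se[1, 2]
    cc <- d * Sg[2, 2] + Se[2, 2]
    det <- a * cc - b^2
    if (any(det <= 0) || any(a <= 0)) return(NULL)
    logdet <- sum(log(det))
    Vi <- array(0, c(n, 2, 2))
    Vi[, 1, 1] <- cc / det; Vi[, 2, 2] <- a / det
    Vi[, 1, 2] <- Vi[, 2, 1] <- -b / det
  }

  ## B = X' V^-1 X (pt x pt, trait-major blocks), rhs = X' V^-1 y
  pt <- p0 * t
  B <- matrix(0, pt, pt); rhs <- numeric(pt)
  for (s in seq_len(t)) for (u in seq_len(t)) {
    w <- Vi[, s, u]
    blk <- crossprod(Xr, Xr * w)
    B[((s - 1) * p0 + 1):(s * p0), ((u - 1) * p0 + 1):(u * p0)] <- blk
    rhs[((s - 1) * p0 + 1):(s * p0)] <-
      rhs[((s - 1) * p0 + 1):(s * p0)] + crossprod(Xr, w * Yr[, u])
  }
  Bc <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(Bc)) return(NULL)
  beta <- backsolve(Bc, forwardsolve(t(Bc), rhs))
  R <- Yr - Xr %*% matrix(beta, p0, t)          # residuals per trait
  ## Py (n x t): V^-1 r
  Py <- matrix(0, n, t)
  for (s in seq_len(t)) for (u in seq_len(t)) Py[, s] <- Py[, s] + Vi[, s, u] * R[, u]
  yPy <- sum(R * Py)
  ll <- -0.5 * (logdet + 2 * sum(log(diag(Bc))) + yPy)

  ## derivative structures A_k = c_i E_k; c = d (genomic) or 1 (residual)
  pairs <- vech_pairs(t)
  nk <- 2 * np
  cvecs <- c(rep(list(d), np), rep(list(rep(1, n)), np))
  kpairs <- c(pairs, pairs)

  Binv <- chol2inv(Bc)
  score <- numeric(nk)
  ## q_k = A_k P y (n x t per k), needed for AI
  qk <- vector("list", nk)
  for (k in seq_len(nk)) {
    ij <- kpairs[[k]]; cv <- cvecs[[k]]
    i <- ij[1]; j <- ij[2]
    ## tr(V^-1 A_k)
    trV <- if (i == j) sum(cv * Vi[, i, i]) else 2 * sum(cv * Vi[, i, j])
    ## X' V^-1 A_k V^-1 X, blocks M_su = sum_i c_i (Vi E Vi)[s,u] x x'
    Mk <- matrix(0, pt, pt)
    for (s in seq_len(t)) for (u in seq_len(t)) {
      w <- if (i == j) cv * Vi[, s, i] * Vi[, i, u]
      else cv * (Vi[, s, i] * Vi[, j, u] + Vi[, s, j] * Vi[, i, u])
      Mk[((s - 1) * p0 + 1):(s * p0), ((u - 1) * p0 + 1):(u * p0)] <-
        crossprod(Xr, Xr * w)
    }
    trP <- trV - sum(Binv * Mk)
    q <- matrix(0, n, t)
    if (i == j) q[, i] <- cv * Py[, i]
    else { q[, i] <- cv * Py[, j]; q[, j] <- cv * Py[, i] }
    qk[[k]] <- q
    yPAPy <- sum(Py * q)
    score[k] <- -0.5 * (trP - yPAPy)
  }

  AI <- NULL
  if (compute_ai) {
    ## P q = V^-1 q - V^-1 X B^-1 X' V^-1 q
    Pq <- vector("list", nk)
    for (k in seq_len(nk)) {
      q <- qk[[k]]
      Vq <- matrix(0, n, t)
      for (s in seq_len(t)) for (u in seq_len(t)) Vq[, s] <- Vq[, s] + Vi[, s, u] * q[, u]
      xv <- numeric(pt)
      for (s in seq_len(t))
        xv[((s - 1) * p0 + 1):(s * p0)] <- crossprod(Xr, Vq[, s])
      corr <- Binv %*% xv
      VXc <- matrix(0, n, t)
      Xc <- Xr %*% matrix(corr, p0, t)
      for (s in seq_len(t)) for (u in seq_len(t)) VXc[, s] <- VXc[, s] + Vi[, s, u] * Xc[, u]
      Pq[[k]] <- Vq - VXc
    }
    AI <- matrix(0, nk, nk)
    for (k in seq_len(nk)) for (l in k:nk) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(qk[[k]] * Pq[[l]])
    }
  }

  list(ll = ll, score = score, AI = AI, Py = Py, Vi = Vi, Binv = Binv,
       beta = beta, Sg = Sg, Se = Se, Xr = Xr, d = d, n = n, t = t, p0 = p0)
}

## REML-EM update of (Sigma_g, Sigma_e) from a reml_eval state; guarantees a
## non-decreasing restricted likelihood
reml_em_step <- function(st) {
  n <- st$n; t <- st$t; p0 <- st$p0
  d <- st$d; Py <- st$Py; Vi <- st$Vi; Xr <- st$Xr; Binv <- st$Binv
  Sg <- st$Sg; Se <- st$Se
  Sg_new <- matrix(0, t, t); Se_new <- matrix(0, t, t)
  for (i in seq_len(n)) {
    Vii <- matrix(Vi[i, , ], t, t)
    xi <- Xr[i, ]
    Xi <- diag(t) %x% matrix(xi, 1)           # t x (t p0)
    Wi <- Vii %*% Xi
    Pii <- Vii - Wi %*% Binv %*% t(Wi)
    py <- Py[i, ]
    Ag <- d[i] * Sg
    ahat <- Ag %*% py
    Va <- Ag - Ag %*% Pii %*% Ag
    Sg_new <- Sg_new + (tcrossprod(ahat) + Va) / max(d[i], 1e-12)
    ehat <- Se %*% py
    Ve <- Se - Se %*% Pii %*% Se
    Se_new <- Se_new + tcrossprod(ehat) + Ve
  }
  list(Sg = Sg_new / n, Se = Se_new / n)
}

reml_core <- function(Y, X, G, max_iter = 200, tol_param = 1e-8,
                      tol_grad = 1e-6, ridge = 0, verbose = FALSE) {
  Y <- as.matrix(Y)
  t <- ncol(Y); n <- nrow(Y)
  if (nrow(G) != n) stop("G and phenotypes disagree on individuals")
  Gm <- G
  if (ridge > 0) Gm <- Gm + diag(ridge, n)
  ee <- eigen((Gm + t(Gm)) / 2, symmetric = TRUE)
  d <- pmax(ee$values, 0)
  lam_max <- max(d)
  if (min(ee$values) < -1e-8 * lam_max)
    stop("G is not positive semi-definite beyond tolerance; consider a ridge")
  if (stats::sd(d) < 1e-10 * max(1, lam_max))
    stop("G is (proportional to) the identity: genomic and residual variance are not separable")
  U <- ee$vectors
  Yr <- crossprod(U, Y)
  Xr <- crossprod(U, X)

  ## start at an even split of the OLS residual covariance
  ols <- stats::lm.fit(X, Y)
  S0 <- crossprod(as.matrix(ols$residuals)) / max(1, n - ncol(X))
  ## shrink toward the diagonal so a singular start (perfectly correlated
  ## traits) still gives an invertible phenotypic covariance
  S0 <- 0.9 * S0 + 0.1 * diag(diag(S0), t)
  vfloor <- 1e-8 * mean(diag(S0))
  Sg <- S0 / 2; Se <- S0 / 2
  theta <- mats_to_theta(Sg, Se)
  np <- t * (t + 1) / 2

  st <- reml_eval(theta, t, d, Yr, Xr)
  if (is.null(st)) stop("REML failed to evaluate at the starting values")
  ll_trace <- st$ll
  em_ll_trace <- numeric(0)
  converged <- FALSE
  used <- max_iter
  for (it in seq_len(max_iter)) {
    step_ok <- FALSE
    used_em <- FALSE
    ## AI step with step halving
    delta <- tryCatch(solve(st$AI + diag(1e-10, nrow(st$AI)), st$score),
                      error = function(e) NULL)
    if (!is.null(delta)) {
      fac <- 1
      for (h in 1:6) {
        cand <- theta + fac * delta
        cm <- theta_to_mats(cand, t)
        cg <- clamp_cov(cm$Sg, vfloor); ce <- clamp_cov(cm$Se, vfloor)
        cand <- mats_to_theta(cg$S, ce$S)
        st2 <- reml_eval(cand, t, d, Yr, Xr)
        if (!is.null(st2) && is.finite(st2$ll) && st2$ll >= st$ll - 1e-8) {
          theta_new <- cand; st_new <- st2; step_ok <- TRUE
          break
        }
        fac <- fac / 2
      }
    }
    if (!step_ok) {
      ## EM fallback: guaranteed ascent
      em <- reml_em_step(st)
      cg <- clamp_cov(em$Sg, vfloor); ce <- clamp_cov(em$Se, vfloor)
      cand <- mats_to_theta(cg$S, ce$S)
      st2 <- reml_eval(cand, t, d, Yr, Xr)
      if (is.null(st2)) break
      theta_new <- cand; st_new <- st2; used_em <- TRUE
      em_ll_trace <- c(em_ll_trace, st2$ll)
    }
    rel <- max(abs(theta_new - theta)) / max(abs(theta), 1e-12)
    theta <- theta_new; st <- st_new
    ll_trace <- c(ll_trace, st$ll)
    if (verbose)
      message(sprintf("iter %d ll %.6f rel %.2e %s", it, st$ll, rel,
                      if (used_em) "(EM)" else "(AI)"))
    gnorm <- sqrt(sum(st$score^2)) / max(1, abs(st$ll))
    if (rel < tol_param && gnorm < tol_grad) {
      converged <- TRUE; used <- it; break
    }
  }

  ms <- theta_to_mats(theta, t)
  Sg <- ms$Sg; Se <- ms$Se
  ## standard errors from the inverse AI matrix
  se_theta <- rep(NA_real_, 2 * np)
  Vtheta <- tryCatch(solve(st$AI), error = function(e) NULL)
  if (!is.null(Vtheta) && all(diag(Vtheta) >= 0))
    se_theta <- sqrt(pmax(diag(Vtheta), 0))

  boundary <- FALSE
  h2 <- se_h2 <- rep(NA_real_, t)
  for (s in seq_len(t)) {
    va <- Sg[s, s]; ve <- Se[s, s]
    h2[s] <- va / (va + ve)
    if (va <= vfloor * 1.01) boundary <- TRUE
    if (!is.null(Vtheta)) {
      ## delta method on (va, ve); indices in theta: vech order
      iv <- which(vapply(vech_pairs(t), function(ij) all(ij == c(s, s)), TRUE))
      ie <- np + iv
      gr <- c(ve, -va) / (va + ve)^2
      sub <- Vtheta[c(iv, ie), c(iv, ie)]
      se_h2[s] <- sqrt(max(0, drop(t(gr) %*% sub %*% gr)))
    }
  }
  rg <- se_rg <- re <- NA_real_
  if (t == 2) {
    rg <- Sg[1, 2] / sqrt(Sg[1, 1] * Sg[2, 2])
    re <- Se[1, 2] / sqrt(Se[1, 1] * Se[2, 2])
    if (abs(rg) > 0.999) boundary <- TRUE
    if (!is.null(Vtheta)) {
      ## delta method for rg = g12 / sqrt(g11 g22); theta order g11,g21,g22
      g11 <- Sg[1, 1]; g12 <- Sg[1, 2]; g22 <- Sg[2, 2]
      gr <- c(-0.5 * g12 / (g11^1.5 * sqrt(g22)),
              1 / sqrt(g11 * g22),
              -0.5 * g12 / (sqrt(g11) * g22^1.5))
      sub <- Vtheta[1:3, 1:3]
      se_rg <- sqrt(max(0, drop(t(gr) %*% sub %*% gr)))
    }
  }

  structure(list(
    Sigma_g = Sg, Sigma_e = Se, h2 = h2, se_h2 = se_h2,
    genomic_correlation = rg, se_genomic_correlation = se_rg,
    environmental_correlation = re,
    loglik = st$ll, loglik_trace = ll_trace, em_loglik_trace = em_ll_trace,
    converged = converged, boundary_flag = boundary,
    n_iterations_used = used, n = n, n_traits = t,
    se_theta = se_theta, beta = st$beta), class = "reml_result")
}

#' Univariate GBLUP REML
#'
#' Restricted maximum likelihood for the animal model
#' `y = mu + herd + parity + animal + e` with the random genomic values
#' distributed `N(0, G sigma_a2)`. Estimation is by average-information
#' iteration with EM fallback whenever the AI update leaves the parameter
#' space or decreases the restricted likelihood; heritability is
#' `h2 = sigma_a2 / (sigma_a2 + sigma_e2)`.
#'
#' @param y numeric phenotype vector.
#' @param herd,parity fixed-effect factors.
#' @param G a `grm` object (or plain symmetric matrix) over the phenotyped
#'   individuals.
#' @param max_iter,ridge,verbose iteration controls; `ridge` is added to the
#'   diagonal of `G` before eigendecomposition.
#' @return a `reml_result`: variance components, `h2`, standard errors from
#'   the inverse AI matrix, convergence and boundary flags.
#' @export
reml_univariate <- function(y, herd, parity, G, max_iter = 200, ridge = 0,
                            verbose = FALSE) {
  Gv <- if (inherits(G, "grm")) G$values else as.matrix(G)
  keep <- !is.na(y)
  X <- fixed_design(herd[keep], parity[keep])
  res <- reml_core(y[keep], X, Gv[keep, keep, drop = FALSE],
                   max_iter = max_iter, ridge = ridge, verbose = verbose)
  res$sigma_a2 <- res$Sigma_g[1, 1]
  res$sigma_e2 <- res$Sigma_e[1, 1]
  res$h2 <- res$h2[1]
  res$se_h2 <- res$se_h2[1]
  res
}

#' Bivariate GBLUP REML
#'
#' Two-trait animal model with 2x2 genomic and residual covariance matrices;
#' the genomic correlation is derived from the genomic covariance. A result
#' is flagged as a boundary estimate when `|r| > 0.999` or a variance is
#' pinned at its lower bound — the signature of weak identification, where
#' REML correlation estimates collapse to +/-1.
#'
#' @param y1,y2 phenotype vectors over the same individuals.
#' @inheritParams reml_univariate
#' @return a `reml_result` with `genomic_correlation`,
#'   `environmental_correlation` and per-trait `h2`.
#' @export
reml_bivariate <- function(y1, y2, herd, parity, G, max_iter = 200,
                           ridge = 0, verbose = FALSE) {
  Gv <- if (inherits(G, "grm")) G$values else as.matrix(G)
  keep <- !is.na(y1) & !is.na(y2)
  if (sum(keep) < 3L) stop("no (or too few) jointly observed individuals")
  X <- fixed_design(herd[keep], parity[keep])
  reml_core(cbind(y1[keep], y2[keep]), X, Gv[keep, keep, drop = FALSE],
            max_iter = max_iter, ridge = ridge, verbose = verbose)
}

#' @export
print.reml_result <- function(x, ...) {
  if (x$n_traits == 1) {
    cat(sprintf("REML: sigma_a2 = %.4f, sigma_e2 = %.4f, h2 = %.3f (SE %.3f)\n",
                x$sigma_a2, x$sigma_e2, x$h2, x$se_h2))
  } else {
    cat(sprintf("REML bivariate: r_genomic = %.3f (SE %.3f), r_environmental = %.3f\n",
                x$genomic_correlation, x$se_genomic_correlation,
                x$environmental_correlation))
    cat(sprintf("  h2: %.3f, %.3f\n", x$h2[1], x$h2[2]))
  }
  cat(sprintf("  converged: %s, boundary: %s, iterations: %d\n",
              x$converged, x$boundary_flag, x$n_iterations_used))
  invisible(x)
}

#' Compare Bayesian and REML genomic correlations
#'
#' Pairs the posterior-mean genomic correlations from bivariate MCMC runs
#' with the REML point estimates on the same trait pairs, carrying the raw
#' phenotypic correlation and the REML boundary flags. The agreement
#' statistic (mean absolute difference) excludes boundary-flagged REML runs,
#' which are convergence failures rather than estimates, but keeps them in
#' the table.
#'
#' @param bayes list of `bivariate_posterior` objects.
#' @param reml list of `reml_result` objects (bivariate), same pair order.
#' @param phenotypes optional data.frame of raw traits used to add the raw
#'   phenotypic correlation per pair.
#' @return a `comparison_table` data.frame with attribute
#'   `mean_abs_difference`.
#' @export
compare_bayes_reml <- function(bayes, reml, phenotypes = NULL) {
  if (length(bayes) != length(reml))
    stop("bayes and reml lists must have matching trait pairs")
  rows <- Map(function(b, r) {
    stopifnot(inherits(b, "bivariate_posterior"), inherits(r, "reml_result"))
    if (r$n_traits != 2) stop("reml entries must be bivariate results")
    phen <- NA_real_
    if (!is.null(phenotypes) && all(b$traits %in% names(phenotypes)))
      phen <- stats::cor(phenotypes[[b$traits[1]]], phenotypes[[b$traits[2]]],
                         use = "complete.obs")
    data.frame(trait1 = b$traits[1], trait2 = b$traits[2],
               r_bayes = b$genomic_correlation_mean,
               r_bayes_psd = b$genomic_correlation_psd,
               r_reml = r$genomic_correlation,
               r_reml_se = r$se_genomic_correlation,
               reml_boundary = r$boundary_flag,
               reml_converged = r$converged,
               phenotypic_correlation = phen,
               abs_difference = abs(b$genomic_correlation_mean -
                                      r$genomic_correlation),
               stringsAsFactors = FALSE)
  }, bayes, reml)
  out <- do.call(rbind, rows)
  ok <- !out$reml_boundary
  attr(out, "mean_abs_difference") <-
    if (any(ok)) mean(out$abs_difference[ok]) else NA_real_
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Scatter data / plot of the method comparison
#'
#' Produces the two comparison views on synthetic data: Bayesian vs REML
#' genomic correlation, and raw phenotypic vs genomic correlation for both
#' methods. Plotting requires ggplot2; the data are always returned.
#'
#' @param comparison a `comparison_table` from [compare_bayes_reml()].
#' @param file optional path (svg/png/pdf by extension) to save the plot.
#' @return invisibly, a list of the two long-format data.frames (and `plot`
#'   when ggplot2 is available).
#' @export
plot_method_comparison <- function(comparison, file = NULL) {
  d1 <- data.frame(x = comparison$r_bayes, y = comparison$r_reml,
                   boundary = comparison$reml_boundary)
  d2 <- rbind(
    data.frame(x = comparison$phenotypic_correlation,
               y = comparison$r_bayes, method = "Bayesian"),
    data.frame(x = comparison$phenotypic_correlation,
               y = comparison$r_reml, method = "REML"))
  out <- list(bayes_vs_reml = d1, phenotypic_vs_genomic = d2)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(d1, ggplot2::aes(x = x, y = y, colour = boundary)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "genomic correlation (Bayesian posterior mean)",
                    y = "genomic correlation (REML)",
                    colour = "REML boundary")
    out$plot <- p
    if (!is.null(file)) ggplot2::ggsave(file, p, width = 5, height = 4)
  }
  invisible(out)
}
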