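// MCMC samplers for the random-regression SNP-BLUP mixed model.
//
// Univariate: y = W b + Z u + e, u ~ N(0, I sigma_u2), e ~ N(0, I sigma_e2),
// flat priors on b and on both variances (scaled inverse-chi-square full
// conditionals with df n-2 and m-2). Bivariate: per-SNP effect 2-vectors
// with covariance Sigma_u, residual 2x2 covariance Sigma_e, both with flat
// (matrix) priors giving inverse-Wishart full conditionals with df n-3 and
// m-3. Per saved cycle the SNP-explained (co)variance Var(Zu) is evaluated
// with the population (n) denominator.
//
// All random numbers come from R's RNG so chains are reproducible from
// set.seed() on the R side.

#include <RcppArmadillo.h>
using namespace Rcpp;

// scaled inverse chi-square draw ssq / chisq(df), rejected above `upper`
static double rscinv_chisq(double ssq, double df, double upper) {
  for (int k = 0; k < 200; ++k) {
    double v = ssq / R::rchisq(df);
    if (v <= upper) return v;
  }
  return upper; // repeated rejection: pin at the bound
}

static arma::vec var_cov_pop(const arma::mat& Gv) {
  // population (n denominator) variances and covariance of columns of Gv
  int n = Gv.n_rows, t = Gv.n_cols;
  arma::rowvec mu = arma::mean(Gv, 0);
  arma::mat C = Gv.each_row() - mu;
  arma::mat S = (C.t() * C) / double(n);
  if (t == 1) return arma::vec({S(0, 0)});
  return arma::vec({S(0, 0), S(1, 1), S(0, 1)});
}

// inverse-Wishart(S, df) via Bartlett decomposition of Wishart(df, S^-1)
static arma::mat rinvwishart2(const arma::mat& S, double df) {
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  int t = S.n_rows;
  arma::mat A(t, t, arma::fill::zeros);
  for (int i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat W = L * A;
  W = W * W.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// [[Rcpp::export]]
List gibbs_univariate_cpp(const arma::vec& y, const arma::mat& W,
                          const arma::mat& Z, int n_iter, int burn_in,
                          int thin, double sigma_u2, double sigma_e2,
                          bool update_variances, double var_upper,
                          bool use_mh, int mh_block_size,
                          bool save_effects) {
  const int n = y.n_elem, p = W.n_cols, m = Z.n_cols;
  arma::vec wtw(p), ztz(m);
  for (int k = 0; k < p; ++k) wtw(k) = arma::dot(W.col(k), W.col(k));
  for (int j = 0; j < m; ++j) ztz(j) = arma::dot(Z.col(j), Z.col(j));

  arma::vec b(p, arma::fill::zeros), u(m, arma::fill::zeros), e = y;
  const int n_save = (n_iter - burn_in) / thin;
  arma::mat draws(n_save, 4);            // sigma_u2, sigma_e2, var_zu, h2
  arma::mat b_draws(n_save, p);
  arma::mat u_draws;
  if (save_effects) u_draws.set_size(n_save, m);
  arma::vec u_mean(m, arma::fill::zeros);

  // MH bookkeeping: relative step multiplier on the conditional posterior
  // SD, adapted toward ~25% acceptance during burn-in
  double step = 2.4 / std::sqrt((double)mh_block_size);
  long n_prop = 0, n_acc = 0; long win_prop = 0, win_acc = 0;
  int save_idx = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // fixed effects: single-site normal full conditionals, flat prior
    for (int k = 0; k < p; ++k) {
      double rhs = arma::dot(W.col(k), e) + wtw(k) * b(k);
      double mean = rhs / wtw(k);
      double bn = mean + std::sqrt(sigma_e2 / wtw(k)) * R::norm_rand();
      e -= W.col(k) * (bn - b(k));
      b(k) = bn;
    }

    if (!use_mh) {
      // SNP effects: single-site Gibbs
      const double lambda = sigma_e2 / sigma_u2;
      for (int j = 0; j < m; ++j) {
        double c = ztz(j);
        double rhs = arma::dot(Z.col(j), e) + c * u(j);
        double denom = c + lambda;
        double mean = rhs / denom;
        double un = mean + std::sqrt(sigma_e2 / denom) * R::norm_rand();
        e -= Z.col(j) * (un - u(j));
        u(j) = un;
      }
    } else {
      // blocked random-walk Metropolis-Hastings on u; proposal scale per
      // SNP follows the conditional posterior SD sqrt(sigma_e2/(z'z+lambda))
      // so the walk tracks the current variance components
      const double lambda = sigma_e2 / std::max(sigma_u2, 1e-300);
      for (int start = 0; start < m; start += mh_block_size) {
        int stop_ = std::min(start + mh_block_size, m) - 1;
        int bs = stop_ - start + 1;
        arma::vec du(bs);
        for (int j = 0; j < bs; ++j)
          du(j) = step * std::sqrt(sigma_e2 / (ztz(start + j) + lambda)) *
                  R::norm_rand();
        arma::vec d = Z.cols(start, stop_) * du;
        arma::vec u_old = u.subvec(start, stop_);
        double dll = (-2.0 * arma::dot(e, d) + arma::dot(d, d)) /
                     (-2.0 * sigma_e2);
        double dlp = (2.0 * arma::dot(u_old, du) + arma::dot(du, du)) /
                     (-2.0 * sigma_u2);
        ++n_prop; ++win_prop;
        if (std::log(R::unif_rand()) < dll + dlp) {
          u.subvec(start, stop_) += du;
          e -= d;
          ++n_acc; ++win_acc;
        }
      }
      if (it <= burn_in && win_prop >= 50) {  // adapt toward ~25% acceptance
        double acc = double(win_acc) / double(win_prop);
        step *= std::exp(0.5 * (acc - 0.25));
        win_prop = win_acc = 0;
      }
    }

    if (update_variances) {
      sigma_e2 = rscinv_chisq(arma::dot(e, e), double(n - 2), var_upper);
      if (m > 2)
        sigma_u2 = rscinv_chisq(arma::dot(u, u), double(m - 2), var_upper);
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && save_idx < n_save) {
      arma::vec g = Z * u;
      double vz = var_cov_pop(arma::mat(g))(0);
      draws(save_idx, 0) = sigma_u2;
      draws(save_idx, 1) = sigma_e2;
      draws(save_idx, 2) = vz;
      draws(save_idx, 3) = vz / (vz + sigma_e2);
      b_draws.row(save_idx) = b.t();
      if (save_effects) u_draws.row(save_idx) = u.t();
      u_mean += u;
      ++save_idx;
    }
  }
  if (save_idx > 0) u_mean /= double(save_idx);

  List out = List::create(
    _["draws"] = draws, _["fixed_draws"] = b_draws,
    _["u_mean"] = u_mean,
    _["acceptance_rate"] = use_mh && n_prop > 0 ?
      double(n_acc) / double(n_prop) : NA_REAL,
    _["n_saved"] = save_idx);
  if (save_effects) out["u_draws"] = u_draws;
  return out;
}

// [[Rcpp::export]]
List gibbs_bivariate_cpp(const arma::mat& Y, const arma::mat& W,
                         const arma::mat& Z, int n_iter, int burn_in,
                         int thin, arma::mat Sigma_u, arma::mat Sigma_e,
                         bool update_variances, double var_upper,
                         bool use_mh, int mh_block_size) {
  const int n = Y.n_rows, p = W.n_cols, m = Z.n_cols;
  arma::vec wtw(p), ztz(m);
  for (int k = 0; k < p; ++k) wtw(k) = arma::dot(W.col(k), W.col(k));
  for (int j = 0; j < m; ++j) ztz(j) = arma::dot(Z.col(j), Z.col(j));

  arma::mat B(p, 2, arma::fill::zeros), U(m, 2, arma::fill::zeros), E = Y;
  const int n_save = (n_iter - burn_in) / thin;
  // columns: su11 su22 su12 se11 se22 se12 vz1 vz2 cz12 rg re h2_1 h2_2
  arma::mat draws(n_save, 13);
  double step = 2.4 / std::sqrt((double)mh_block_size);
  long n_prop = 0, n_acc = 0, win_prop = 0, win_acc = 0;
  int save_idx = 0;

  for (int it = 1; it <= n_iter; ++it) {
    arma::mat Se_inv = arma::inv_sympd(arma::symmatu(Sigma_e));
    arma::mat Su_inv = arma::inv_sympd(arma::symmatu(Sigma_u));

    // fixed effects: joint 2-vector conditional, flat prior ->
    // N(rhs / wtw, Sigma_e / wtw)
    for (int k = 0; k < p; ++k) {
      arma::rowvec rhs = W.col(k).t() * E + wtw(k) * B.row(k);
      arma::rowvec mean = rhs / wtw(k);
      arma::mat L = arma::chol(Sigma_e / wtw(k), "lower");
      arma::vec z2 = {R::norm_rand(), R::norm_rand()};
      arma::rowvec bn = mean + (L * z2).t();
      E -= W.col(k) * (bn - B.row(k));
      B.row(k) = bn;
    }

    if (!use_mh) {
      for (int j = 0; j < m; ++j) {
        double c = ztz(j);
        arma::rowvec r = Z.col(j).t() * E + c * U.row(j);
        arma::mat A = c * Se_inv + Su_inv;
        arma::mat Ainv = arma::inv_sympd(arma::symmatu(A));
        arma::vec mean = Ainv * (Se_inv * r.t());
        arma::mat L = arma::chol(Ainv, "lower");
        arma::vec z2 = {R::norm_rand(), R::norm_rand()};
        arma::rowvec un = (mean + L * z2).t();
        E -= Z.col(j) * (un - U.row(j));
        U.row(j) = un;
      }
    } else {
      // proposal scale per SNP and trait follows the (marginal) conditional
      // posterior SD using per-trait variance ratios
      arma::vec lam = {Sigma_e(0, 0) / std::max(Sigma_u(0, 0), 1e-300),
                       Sigma_e(1, 1) / std::max(Sigma_u(1, 1), 1e-300)};
      for (int start = 0; start < m; start += mh_block_size) {
        int stop_ = std::min(start + mh_block_size, m) - 1;
        int bs = stop_ - start + 1;
        arma::mat dU(bs, 2);
        for (int j = 0; j < bs; ++j)
          for (int t = 0; t < 2; ++t)
            dU(j, t) = step *
              std::sqrt(Sigma_e(t, t) / (ztz(start + j) + lam(t))) *
              R::norm_rand();
        arma::mat D = Z.cols(start, stop_) * dU;          // n x 2
        arma::mat Uo = U.rows(start, stop_);
        // likelihood: -0.5 tr(Se^-1 ((E-D)'(E-D) - E'E))
        arma::mat dS = -D.t() * E - E.t() * D + D.t() * D;
        double dll = -0.5 * arma::trace(Se_inv * dS);
        arma::mat dP = dU.t() * Uo + Uo.t() * dU + dU.t() * dU;
        double dlp = -0.5 * arma::trace(Su_inv * dP);
        ++n_prop; ++win_prop;
        if (std::log(R::unif_rand()) < dll + dlp) {
          U.rows(start, stop_) += dU;
          E -= D;
          ++n_acc; ++win_acc;
        }
      }
      if (it <= burn_in && win_prop >= 50) {
        double acc = double(win_acc) / double(win_prop);
        step *= std::exp(0.5 * (acc - 0.25));
        win_prop = win_acc = 0;
      }
    }

    if (update_variances) {
      for (int tries = 0; tries < 100; ++tries) {
        arma::mat Se = rinvwishart2(arma::symmatu(E.t() * E), double(n - 3));
        if (Se(0, 0) <= var_upper && Se(1, 1) <= var_upper && Se.is_sympd()) {
          Sigma_e = Se; break;
        }
      }
      if (m > 3) {
        for (int tries = 0; tries < 100; ++tries) {
          arma::mat Su = rinvwishart2(arma::symmatu(U.t() * U), double(m - 3));
          if (Su(0, 0) <= var_upper && Su(1, 1) <= var_upper && Su.is_sympd()) {
            Sigma_u = Su; break;
          }
        }
      }
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && save_idx < n_save) {
      arma::mat Gv = Z * U;                        // n x 2 genomic values
      arma::vec v = var_cov_pop(Gv);               // vz1, vz2, cz12
      double rg = (v(0) > 0 && v(1) > 0) ? v(2) / std::sqrt(v(0) * v(1)) : 0.0;
      double re = Sigma_e(0, 1) / std::sqrt(Sigma_e(0, 0) * Sigma_e(1, 1));
      draws(save_idx, 0) = Sigma_u(0, 0);
      draws(save_idx, 1) = Sigma_u(1, 1);
      draws(save_idx, 2) = Sigma_u(0, 1);
      draws(save_idx, 3) = Sigma_e(0, 0);
      draws(save_idx, 4) = Sigma_e(1, 1);
      draws(save_idx, 5) = Sigma_e(0, 1);
      draws(save_idx, 6) = v(0);
      draws(save_idx, 7) = v(1);
      draws(save_idx, 8) = v(2);
      draws(save_idx, 9) = rg;
      draws(save_idx, 10) = re;
      draws(save_idx, 11) = v(0) / (v(0) + Sigma_e(0, 0));
      draws(save_idx, 12) = v(1) / (v(1) + Sigma_e(1, 1));
      ++save_idx;
    }
  }

  return List::create(
    _["draws"] = draws,
    _["acceptance_rate"] = use_mh && n_prop > 0 ?
      double(n_acc) / double(n_prop) : NA_REAL,
    _["n_saved"] = save_idx);
}
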