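// Coordinate-ascent variational inference for hierarchical Poisson
// factorization. The R wrapper (fit_hpf) owns initialization, seeding and
// packaging; this kernel runs the sweeps. Gamma variational parameters are
// updated in place; the evidence lower bound is evaluated at the top of each
// sweep with the multinomial responsibilities optimized out (log-sum-exp
// form), which keeps the trace non-decreasing across sweeps.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double gamma_entropy_sum(const mat &shp, const mat &rte) {
  double out = 0.0;
  for (uword j = 0; j < shp.n_elem; ++j) {
    double s = shp(j), r = rte(j);
    out += s - std::log(r) + R::lgammafn(s) + (1.0 - s) * R::digamma(s);
  }
  return out;
}

static double gamma_entropy_sum_vec(double shp, const vec &rte) {
  double out = 0.0;
  for (uword j = 0; j < rte.n_elem; ++j) {
    out += shp - std::log(rte(j)) + R::lgammafn(shp) +
      (1.0 - shp) * R::digamma(shp);
  }
  return out;
}

// [[Rcpp::export(name = ".hpf_cavi")]]
Rcpp::List hpf_cavi(const arma::uvec &u_idx, const arma::uvec &i_idx,
                    const arma::vec &y,
                    arma::mat g_shp, arma::mat g_rte,
                    arma::mat l_shp, arma::mat l_rte,
                    arma::vec k_rte, arma::vec t_rte,
                    double a, double a_prime, double c, double c_prime,
                    double b_prime, double d_prime,
                    int max_iter, double tol) {
  const uword n = g_shp.n_rows, g = l_shp.n_rows, k = g_shp.n_cols;
  const uword nnz = y.n_elem;
  const double k_shp = a_prime + k * a;
  const double t_shp = c_prime + k * c;

  std::vector<double> elbo_trace;
  elbo_trace.reserve(max_iter);
  bool converged = false;

  mat e_ln_theta(n, k), e_ln_beta(g, k), e_theta(n, k), e_beta(g, k);
  mat phi_theta(n, k), phi_beta(g, k);
  vec srow(k);

  for (int iter = 0; iter < max_iter; ++iter) {
    for (uword j = 0; j < n * k; ++j) {
      e_ln_theta(j) = R::digamma(g_shp(j)) - std::log(g_rte(j));
      e_theta(j) = g_shp(j) / g_rte(j);
    }
    for (uword j = 0; j < g * k; ++j) {
      e_ln_beta(j) = R::digamma(l_shp(j)) - std::log(l_rte(j));
      e_beta(j) = l_shp(j) / l_rte(j);
    }
    vec e_xi = k_shp / k_rte;
    vec e_eta = t_shp / t_rte;

    // responsibilities and likelihood part of the bound in one pass
    phi_theta.zeros();
    phi_beta.zeros();
    double lik = 0.0;
    for (uword m = 0; m < nnz; ++m) {
      const uword u = u_idx(m), i = i_idx(m);
      double smax = -datum::inf;
      for (uword f = 0; f < k; ++f) {
        srow(f) = e_ln_theta(u, f) + e_ln_beta(i, f);
        if (srow(f) > smax) smax = srow(f);
      }
      double wsum = 0.0;
      for (uword f = 0; f < k; ++f) {
        srow(f) = std::exp(srow(f) - smax);
        wsum += srow(f);
      }
      lik += y(m) * (smax + std::log(wsum));
      const double scale = y(m) / wsum;
      for (uword f = 0; f < k; ++f) {
        const double phi_y = srow(f) * scale;
        phi_theta(u, f) += phi_y;
        phi_beta(i, f) += phi_y;
      }
    }
    for (uword f = 0; f < k; ++f) {
      lik -= accu(e_theta.col(f)) * accu(e_beta.col(f));
    }

    // remaining ELBO terms
    double prior_theta = -double(n) * k * R::lgammafn(a);
    double prior_xi = n * (a_prime * std::log(a_prime / b_prime) -
                           R::lgammafn(a_prime));
    for (uword u = 0; u < n; ++u) {
      const double e_ln_xi = R::digamma(k_shp) - std::log(k_rte(u));
      double row_ln = 0.0, row_e = 0.0;
      for (uword f = 0; f < k; ++f) {
        row_ln += e_ln_theta(u, f);
        row_e += e_theta(u, f);
      }
      prior_theta += a * e_ln_xi * k + (a - 1.0) * row_ln - e_xi(u) * row_e;
      prior_xi += (a_prime - 1.0) * e_ln_xi - a_prime / b_prime * e_xi(u);
    }
    double prior_beta = -double(g) * k * R::lgammafn(c);
    double prior_eta = g * (c_prime * std::log(c_prime / d_prime) -
                            R::lgammafn(c_prime));
    for (uword i = 0; i < g; ++i) {
      const double e_ln_eta = R::digamma(t_shp) - std::log(t_rte(i));
      double row_ln = 0.0, row_e = 0.0;
      for (uword f = 0; f < k; ++f) {
        row_ln += e_ln_beta(i, f);
        row_e += e_beta(i, f);
      }
      prior_beta += c * e_ln_eta * k + (c - 1.0) * row_ln - e_eta(i) * row_e;
      prior_eta += (c_prime - 1.0) * e_ln_eta - c_prime / d_prime * e_eta(i);
    }
    const double entropy = gamma_entropy_sum(g_shp, g_rte) +
      gamma_entropy_sum(l_shp, l_rte) +
      gamma_entropy_sum_vec(k_shp, k_rte) +
      gamma_entropy_sum_vec(t_shp, t_rte);
    const double elbo = lik + prior_theta + prior_beta + prior_xi +
      prior_eta + entropy;
    elbo_trace.push_back(elbo);
    if (iter > 0) {
      const double prev = elbo_trace[iter - 1];
      if (std::abs(elbo - prev) < tol * std::abs(prev)) {
        converged = true;
        break;
      }
    }

    // q(theta)
    rowvec beta_colsums = sum(e_beta, 0);
    for (uword f = 0; f < k; ++f) {
      for (uword u = 0; u < n; ++u) {
        g_shp(u, f) = a + phi_theta(u, f);
        g_rte(u, f) = e_xi(u) + beta_colsums(f);
        e_theta(u, f) = g_shp(u, f) / g_rte(u, f);
      }
    }
    // q(xi)
    k_rte = a_prime / b_prime + sum(e_theta, 1);
    // q(beta)
    rowvec theta_colsums = sum(e_theta, 0);
    for (uword f = 0; f < k; ++f) {
      for (uword i = 0; i < g; ++i) {
        l_shp(i, f) = c + phi_beta(i, f);
        l_rte(i, f) = e_eta(i) + theta_colsums(f);
        e_beta(i, f) = l_shp(i, f) / l_rte(i, f);
      }
    }
    // q(eta)
    t_rte = c_prime / d_prime + sum(e_beta, 1);
  }

  return Rcpp::List::create(
    Rcpp::Named("g_shp") = g_shp, Rcpp::Named("g_rte") = g_rte,
    Rcpp::Named("l_shp") = l_shp, Rcpp::Named("l_rte") = l_rte,
    Rcpp::Named("k_rte") = k_rte, Rcpp::Named("t_rte") = t_rte,
    Rcpp::Named("k_shp") = k_shp, Rcpp::Named("t_shp") = t_shp,
    Rcpp::Named("elbo_trace") = elbo_trace,
    Rcpp::Named("converged") = converged
  );
}
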