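// Gibbs sweeps for overfitted finite mixtures (diagonal Gaussian, Bernoulli).
//
// All randomness is drawn from R's RNG so that a chain is fully determined by
// the R-side seed set immediately before the call. Allocation updates are
// vectorised across items: given (weights, theta) the allocations are
// conditionally independent, so one K x N log-probability matrix per sweep
// suffices (K x N rather than N x K keeps each item's column contiguous).
// Components whose log-probability trails the item's maximum by more than
// EXP_FLOOR are skipped when exponentiating; their contribution (< 1e-13
// relative) is negligible for both sampling and the log-likelihood.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

constexpr double EXP_FLOOR = 30.0;

// Dirichlet(alpha + counts) via normalised gammas.
inline void draw_weights(arma::vec& w, const arma::uvec& counts, double alpha) {
  double tot = 0.0;
  for (arma::uword k = 0; k < w.n_elem; ++k) {
    double g = R::rgamma(alpha + static_cast<double>(counts[k]), 1.0);
    if (g < 1e-300) g = 1e-300;
    w[k] = g;
    tot += g;
  }
  w /= tot;
}

// For one item's contiguous log-probability column: accumulate the item's
// log-sum-exp into `ll` and return a categorical draw (0-based).
inline arma::uword sample_column(const double* col, arma::uword K,
                                 double* buf, double& ll) {
  double m = col[0];
  for (arma::uword k = 1; k < K; ++k) {
    if (col[k] > m) m = col[k];
  }
  double tot = 0.0;
  for (arma::uword k = 0; k < K; ++k) {
    double d = col[k] - m;
    double e = (d > -EXP_FLOOR) ? std::exp(d) : 0.0;
    buf[k] = e;
    tot += e;
  }
  ll += m + std::log(tot);
  double u = R::unif_rand() * tot;
  double acc = 0.0;
  for (arma::uword k = 0; k < K; ++k) {
    acc += buf[k];
    if (u <= acc) return k;
  }
  return K - 1;  // guard against rounding
}

}  // namespace

// Run `nsweeps` full Gibbs sweeps of the diagonal-Gaussian mixture starting
// from the supplied state. Priors: weights ~ Dirichlet(alpha, ..., alpha);
// per feature p and component k, sigma2 ~ InvGamma(a0, b0_p) and
// mu | sigma2 ~ Normal(m0_p, sigma2 / kappa).
// `checkpoints` are sorted 1-based sweep indices at which the partition is
// snapshotted. Returns the final state, per-sweep log-likelihoods (of the
// state *after* each sweep) and the checkpoint partitions (0-based labels).
// [[Rcpp::export]]
List gaussian_sweeps_cpp(const arma::mat& X,
                         arma::uvec labels,  // 0-based allocation
                         arma::vec weights,
                         arma::mat means,    // K x P
                         arma::mat vars,     // K x P
                         double alpha,
                         const arma::rowvec& m0,
                         double kappa,
                         double a0,
                         const arma::rowvec& b0,
                         int nsweeps,
                         const arma::uvec& checkpoints) {
  const arma::uword N = X.n_rows, P = X.n_cols, K = weights.n_elem;
  const arma::mat Xt = X.t();                 // P x N
  const arma::mat X2t = arma::square(Xt);     // P x N
  const double half_l2pi = 0.5 * std::log(2.0 * M_PI);

  arma::vec loglik(nsweeps, arma::fill::zeros);
  arma::umat snaps(checkpoints.n_elem, N);
  arma::uword next_cp = 0;

  arma::mat lp(K, N), B1(K, P), B2(K, P);
  arma::vec shift(K), buf(K);
  arma::uvec counts(K);
  arma::mat S(K, P), SS(K, P);

  // fills `lp` and `shift` from the current (weights, means, vars)
  auto compute_lp = [&]() {
    B1 = 0.5 / vars;
    B2 = means / vars;
    shift = arma::log(weights) -
      arma::sum(means % B2 * 0.5 + 0.5 * arma::log(vars) + half_l2pi, 1);
    lp = B2 * Xt;
    lp -= B1 * X2t;
    lp.each_col() += shift;
  };

  for (int t = 1; t <= nsweeps; ++t) {
    compute_lp();

    // allocations + log-likelihood of the incoming state
    double ll = 0.0;
    counts.zeros();
    for (arma::uword i = 0; i < N; ++i) {
      arma::uword k = sample_column(lp.colptr(i), K, buf.memptr(), ll);
      labels[i] = k;
      counts[k] += 1;
    }
    if (t >= 2) loglik[t - 2] = ll;

    // weights | counts
    draw_weights(weights, counts, alpha);

    // component sufficient statistics
    S.zeros();
    SS.zeros();
    for (arma::uword i = 0; i < N; ++i) {
      const arma::uword k = labels[i];
      for (arma::uword p = 0; p < P; ++p) {
        double x = Xt(p, i);
        S(k, p) += x;
        SS(k, p) += x * x;
      }
    }

    // (mu, sigma2) | members, Normal-Inverse-Gamma conjugacy
    for (arma::uword k = 0; k < K; ++k) {
      double n = static_cast<double>(counts[k]);
      for (arma::uword p = 0; p < P; ++p) {
        double kn, mn, an, bn;
        if (n > 0.0) {
          double xbar = S(k, p) / n;
          double ssd = SS(k, p) - n * xbar * xbar;
          if (ssd < 0.0) ssd = 0.0;
          kn = kappa + n;
          mn = (kappa * m0[p] + n * xbar) / kn;
          an = a0 + 0.5 * n;
          double d = xbar - m0[p];
          bn = b0[p] + 0.5 * ssd + 0.5 * kappa * n * d * d / kn;
        } else {
          kn = kappa; mn = m0[p]; an = a0; bn = b0[p];
        }
        double g = R::rgamma(an, 1.0);
        if (g < 1e-300) g = 1e-300;
        double v = bn / g;
        vars(k, p) = v;
        means(k, p) = mn + R::norm_rand() * std::sqrt(v / kn);
      }
    }

    if (next_cp < checkpoints.n_elem &&
        checkpoints[next_cp] == static_cast<arma::uword>(t)) {
      snaps.row(next_cp) = labels.t();
      ++next_cp;
    }
  }

  // log-likelihood of the final state
  if (nsweeps >= 1) {
    compute_lp();
    double ll = 0.0;
    for (arma::uword i = 0; i < N; ++i) {
      const double* col = lp.colptr(i);
      double m = col[0];
      for (arma::uword k = 1; k < K; ++k) {
        if (col[k] > m) m = col[k];
      }
      double tot = 0.0;
      for (arma::uword k = 0; k < K; ++k) {
        double d = col[k] - m;
        if (d > -EXP_FLOOR) tot += std::exp(d);
      }
      ll += m + std::log(tot);
    }
    loglik[nsweeps - 1] = ll;
  }

  return List::create(_["labels"] = IntegerVector(labels.begin(), labels.end()),
                      _["weights"] = weights,
                      _["means"] = means,
                      _["vars"] = vars,
                      _["loglik"] = loglik,
                      _["partitions"] = snaps);
}

// Bernoulli analogue: rates theta_kp ~ Beta(beta_a, beta_b), data in {0, 1}.
// [[Rcpp::export]]
List bernoulli_sweeps_cpp(const arma::mat& X,
                          arma::uvec labels,
                          arma::vec weights,
                          arma::mat rates,  // K x P
                          double alpha,
                          double beta_a,
                          double beta_b,
                          int nsweeps,
                          const arma::uvec& checkpoints) {
  const arma::uword N = X.n_rows, P = X.n_cols, K = weights.n_elem;
  const arma::mat Xt = X.t();  // P x N
  const double eps = 1e-12;

  arma::vec loglik(nsweeps, arma::fill::zeros);
  arma::umat snaps(checkpoints.n_elem, N);
  arma::uword next_cp = 0;

  arma::mat lp(K, N);
  arma::vec buf(K);
  arma::uvec counts(K);
  arma::mat S(K, P);

  auto compute_lp = [&]() {
    arma::mat th = arma::clamp(rates, eps, 1.0 - eps);
    arma::mat logit = arma::log(th) - arma::log1p(-th);  // K x P
    arma::vec shift = arma::log(weights) + arma::sum(arma::log1p(-th), 1);
    lp = logit * Xt;
    lp.each_col() += shift;
  };

  for (int t = 1; t <= nsweeps; ++t) {
    compute_lp();

    double ll = 0.0;
    counts.zeros();
    for (arma::uword i = 0; i < N; ++i) {
      arma::uword k = sample_column(lp.colptr(i), K, buf.memptr(), ll);
      labels[i] = k;
      counts[k] += 1;
    }
    if (t >= 2) loglik[t - 2] = ll;

    draw_weights(weights, counts, alpha);

    S.zeros();
    for (arma::uword i = 0; i < N; ++i) {
      const arma::uword k = labels[i];
      for (arma::uword p = 0; p < P; ++p) S(k, p) += Xt(p, i);
    }

    for (arma::uword k = 0; k < K; ++k) {
      double n = static_cast<double>(counts[k]);
      for (arma::uword p = 0; p < P; ++p) {
        rates(k, p) = R::rbeta(beta_a + S(k, p), beta_b + n - S(k, p));
      }
    }

    if (next_cp < checkpoints.n_elem &&
        checkpoints[next_cp] == static_cast<arma::uword>(t)) {
      snaps.row(next_cp) = labels.t();
      ++next_cp;
    }
  }

  if (nsweeps >= 1) {
    compute_lp();
    double ll = 0.0;
    for (arma::uword i = 0; i < N; ++i) {
      const double* col = lp.colptr(i);
      double m = col[0];
      for (arma::uword k = 1; k < K; ++k) {
        if (col[k] > m) m = col[k];
      }
      double tot = 0.0;
      for (arma::uword k = 0; k < K; ++k) tot += std::exp(col[k] - m);
      ll += m + std::log(tot);
    }
    loglik[nsweeps - 1] = ll;
  }

  return List::create(_["labels"] = IntegerVector(labels.begin(), labels.end()),
                      _["weights"] = weights,
                      _["rates"] = rates,
                      _["loglik"] = loglik,
                      _["partitions"] = snaps);
}
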