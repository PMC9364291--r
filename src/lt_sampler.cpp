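// Metropolis-within-Gibbs sampler for the hierarchical latent-trait
// source-monitoring model: individual probit-scale parameter vectors
// z_i ~ MVN(mu, Sigma), theta_i = Phi(z_i), multinomial data per participant.
// Covariance prior: Huang-Wand hierarchical inverse-Wishart (half-t scale
// margins), which keeps every hyperparameter update conjugate.
//
// Mixing machinery: component-wise adaptive random-walk updates of the z_i;
// conjugate Gibbs updates of mu and Sigma; and two interweaving
// (ancillarity-sufficiency) moves that translate / rescale the group-level
// location and scale jointly with the individual deviations, which breaks
// the funnel-shaped coupling between hierarchy and individuals for weakly
// informed parameters.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int P = 6; // D_E, D_U, d_E, d_U, b, g

// standard normal CDF via erfc (cheaper than R::pnorm, same accuracy range)
static inline double phi_cdf(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

// category probabilities of the 3x3 source-monitoring tree;
// restriction 0: D_N = D_U, 1: D_N = D_E
static void cat_probs(const double* th, int restriction, double* Pm) {
  const double DE = th[0], DU = th[1], dE = th[2], dU = th[3],
               b = th[4], g = th[5];
  const double DN = (restriction == 1) ? DE : DU;
  Pm[0] = DE * dE + DE * (1 - dE) * g + (1 - DE) * b * g;
  Pm[1] = DE * (1 - dE) * (1 - g) + (1 - DE) * b * (1 - g);
  Pm[2] = (1 - DE) * (1 - b);
  Pm[3] = DU * (1 - dU) * g + (1 - DU) * b * g;
  Pm[4] = DU * dU + DU * (1 - dU) * (1 - g) + (1 - DU) * b * (1 - g);
  Pm[5] = (1 - DU) * (1 - b);
  Pm[6] = (1 - DN) * b * g;
  Pm[7] = (1 - DN) * b * (1 - g);
  Pm[8] = DN + (1 - DN) * (1 - b);
}

static double loglik_theta(const double* th, int restriction,
                           const double* y) {
  double Pm[9];
  cat_probs(th, restriction, Pm);
  double ll = 0.0;
  for (int c = 0; c < 9; ++c) {
    if (y[c] > 0) {
      if (Pm[c] <= 0) return -std::numeric_limits<double>::infinity();
      ll += y[c] * std::log(Pm[c]);
    }
  }
  return ll;
}

// Wishart(df, S) draw via Bartlett decomposition, R RNG
static arma::mat rwishart(double df, const arma::mat& S) {
  const int p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// One MCMC chain. counts: n x 9 (rows: participant; cols: expected row,
// unexpected row, new row of the 3x3 table). Returns retained draws.
// [[Rcpp::export]]
List lt_mpt_chain(const arma::mat& counts, int restriction,
                  int iter, int burnin, int thin,
                  const arma::vec& mu_init, double z_jitter,
                  double mu_prior_sd, double hw_nu, double hw_A,
                  bool store_theta) {
  const int n = counts.n_rows;
  if (counts.n_cols != 9) stop("counts must have 9 columns");
  if (iter <= burnin || thin < 1) stop("need iter > burnin and thin >= 1");
  const int S = (iter - burnin) / thin;
  const arma::mat countsT = counts.t(); // column i = participant i's 9 cells

  arma::vec mu = mu_init;
  arma::mat Sigma = arma::eye(P, P) * 0.3;
  arma::vec a(P, arma::fill::ones);
  arma::mat z(n, P);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < P; ++j)
      z(i, j) = mu[j] + z_jitter * R::norm_rand();

  // cached probabilities and data log-likelihoods (kept in sync with z)
  arma::mat th(n, P);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < P; ++j)
      th(i, j) = phi_cdf(z(i, j));
  arma::vec ll(n);
  for (int i = 0; i < n; ++i) {
    arma::rowvec thi = th.row(i);
    ll[i] = loglik_theta(thi.memptr(), restriction, countsT.colptr(i));
  }

  // adaptive proposal scales (frozen after burn-in)
  arma::mat scale(n, P, arma::fill::value(0.4));   // z components
  arma::imat acc_batch(n, P, arma::fill::zeros);
  arma::mat acc_total(n, P, arma::fill::zeros);
  arma::vec ascale(P, arma::fill::value(0.15));    // mu interweaving
  arma::ivec aacc_batch(P, arma::fill::zeros);
  arma::vec wscale(P, arma::fill::value(0.3));     // scale interweaving
  arma::ivec wacc_batch(P, arma::fill::zeros);
  const int batch = 50;

  arma::mat mu_out(S, P);
  arma::mat sig_out(S, P * (P + 1) / 2);
  arma::cube th_out;
  if (store_theta) th_out.set_size(n, P, S);

  arma::mat Prec = arma::inv_sympd(Sigma);
  int s_idx = 0;
  double thp_row[P];

  for (int t = 1; t <= iter; ++t) {
    const bool adapt = (t <= burnin);
    const double adapt_delta =
        std::min(0.1, 1.0 / std::sqrt((double) t / batch));

    // --- participant blocks: component-wise random-walk MH on z_(i,j);
    // the prior-term change for a single-component move is
    // -(delta * (Prec dc)_j + 0.5 * delta^2 * Prec_jj) with dc = z_i - mu,
    // so Prec * dc is maintained incrementally
    for (int i = 0; i < n; ++i) {
      arma::vec zi = z.row(i).t();
      for (int j = 0; j < P; ++j) thp_row[j] = th(i, j);
      arma::vec v = Prec * (zi - mu);
      for (int j = 0; j < P; ++j) {
        double delta = scale(i, j) * R::norm_rand();
        double thold = thp_row[j];
        thp_row[j] = phi_cdf(zi[j] + delta);
        double llp = loglik_theta(thp_row, restriction, countsT.colptr(i));
        double dprior = -(delta * v[j] + 0.5 * delta * delta * Prec(j, j));
        if (std::log(unif_rand()) < (llp - ll[i]) + dprior) {
          zi[j] += delta;
          v += delta * Prec.col(j);
          ll[i] = llp;
          acc_batch(i, j) += 1;
          acc_total(i, j) += 1.0;
        } else {
          thp_row[j] = thold;
        }
      }
      // independence proposals from the conditional prior: the proposal and
      // prior terms cancel, leaving the data-likelihood ratio. Weakly
      // informed components accept near-always, giving near-iid movement
      // where the random walk is slow.
      for (int j = 0; j < P; ++j) {
        double cond_mean = zi[j] - v[j] / Prec(j, j);
        double cond_sd = 1.0 / std::sqrt(Prec(j, j));
        double znew = cond_mean + cond_sd * R::norm_rand();
        double thold = thp_row[j];
        thp_row[j] = phi_cdf(znew);
        double llp = loglik_theta(thp_row, restriction, countsT.colptr(i));
        if (std::log(unif_rand()) < llp - ll[i]) {
          v += (znew - zi[j]) * Prec.col(j);
          zi[j] = znew;
          ll[i] = llp;
        } else {
          thp_row[j] = thold;
        }
      }
      z.row(i) = zi.t();
      for (int j = 0; j < P; ++j) th(i, j) = thp_row[j];
    }
    if (adapt && t % batch == 0) {
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < P; ++j) {
          double rate = acc_batch(i, j) / (double) batch;
          scale(i, j) *= std::exp(rate > 0.4 ? adapt_delta : -adapt_delta);
          acc_batch(i, j) = 0;
        }
    }

    // --- mu | z, Sigma  (conjugate normal, prior N(0, mu_prior_sd^2 I))
    {
      arma::mat V = arma::inv_sympd(
          arma::eye(P, P) / (mu_prior_sd * mu_prior_sd) + n * Prec);
      arma::vec m = V * (Prec * arma::sum(z, 0).t());
      arma::mat Lv = arma::chol(V, "lower");
      arma::vec eps(P);
      for (int j = 0; j < P; ++j) eps[j] = R::norm_rand();
      mu = m + Lv * eps;
    }

    // --- interweaving, location: holding the deviations z_i - mu fixed,
    // shift mu_j (and with it every z_(i,j)). The MVN density of the
    // deviations is unchanged; the ratio involves only the data likelihoods
    // and the mu prior. Run twice per iteration: these moves carry most of
    // the hierarchical mixing.
    for (int sweep = 0; sweep < 2; ++sweep) {
      arma::vec lln(n);
      for (int j = 0; j < P; ++j) {
        double shift = ascale[j] * R::norm_rand();
        double muj_new = mu[j] + shift;
        double dll = -0.5 * (muj_new * muj_new - mu[j] * mu[j]) /
                     (mu_prior_sd * mu_prior_sd);
        for (int i = 0; i < n; ++i) {
          for (int k = 0; k < P; ++k) thp_row[k] = th(i, k);
          thp_row[j] = phi_cdf(z(i, j) + shift);
          lln[i] = loglik_theta(thp_row, restriction, countsT.colptr(i));
          dll += lln[i] - ll[i];
        }
        if (std::log(unif_rand()) < dll) {
          mu[j] = muj_new;
          z.col(j) += shift;
          for (int i = 0; i < n; ++i)
            th(i, j) = phi_cdf(z(i, j));
          ll = lln;
          aacc_batch[j] += 1;
        }
      }
      if (adapt && sweep == 1 && t % batch == 0) {
        for (int j = 0; j < P; ++j) {
          double rate = aacc_batch[j] / (2.0 * batch);
          ascale[j] *= std::exp(rate > 0.44 ? adapt_delta : -adapt_delta);
          aacc_batch[j] = 0;
        }
      }
    }

    // --- Sigma | z, mu, a  (inverse-Wishart)
    {
      arma::mat Sz(P, P, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        arma::vec d = z.row(i).t() - mu;
        Sz += d * d.t();
      }
      arma::mat Psi = Sz;
      for (int j = 0; j < P; ++j) Psi(j, j) += 2.0 * hw_nu / a[j];
      double dfp = hw_nu + n + P - 1;
      Prec = rwishart(dfp, arma::inv_sympd(Psi));
      Sigma = arma::inv_sympd(Prec);
    }

    // --- a_j | Sigma  (inverse-gamma)
    for (int j = 0; j < P; ++j) {
      double shape = 0.5 * (hw_nu + P);
      double rate = hw_nu * Prec(j, j) + 1.0 / (hw_A * hw_A);
      a[j] = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    // --- interweaving, scale: holding the standardized deviations
    // (z_(i,j) - mu_j) / w_j and the correlations fixed, rescale w_j
    // (multiplicative log-normal walk). Deviations and the row/column j of
    // Sigma move with it. With the standardized deviations as coordinates
    // the MVN terms cancel, leaving the data likelihoods, the
    // inverse-Wishart prior terms in w_j, and the Jacobian:
    //   (1 - nu - P) * log w_j  -  nu * (Sigma^-1)_jj / a_j  (at proposal).
    // Three sweeps: the scale components mix slowest.
    for (int sweep = 0; sweep < 3; ++sweep) {
      arma::vec lln(n);
      arma::vec prec_diag(P);
      for (int j = 0; j < P; ++j) prec_diag[j] = Prec(j, j);
      bool sigma_changed = false;
      for (int j = 0; j < P; ++j) {
        double c = std::exp(wscale[j] * R::norm_rand()); // w'_j / w_j
        double dll = (1.0 - hw_nu - P) * std::log(c) -
                     hw_nu * prec_diag[j] / a[j] * (1.0 / (c * c) - 1.0);
        for (int i = 0; i < n; ++i) {
          for (int k = 0; k < P; ++k) thp_row[k] = th(i, k);
          thp_row[j] =
              phi_cdf(mu[j] + c * (z(i, j) - mu[j]));
          lln[i] = loglik_theta(thp_row, restriction, countsT.colptr(i));
          dll += lln[i] - ll[i];
        }
        if (std::log(unif_rand()) < dll) {
          for (int i = 0; i < n; ++i) {
            z(i, j) = mu[j] + c * (z(i, j) - mu[j]);
            th(i, j) = phi_cdf(z(i, j));
          }
          // Sigma row/col j scales by c, the diagonal element by c^2;
          // (Sigma^-1)_jj scales by 1/c^2, other diagonal entries unchanged
          for (int k = 0; k < P; ++k) {
            Sigma(j, k) *= c;
            Sigma(k, j) *= c;
          }
          prec_diag[j] /= c * c;
          ll = lln;
          sigma_changed = true;
          wacc_batch[j] += 1;
        }
      }
      if (sigma_changed) Prec = arma::inv_sympd(Sigma);
      if (adapt && sweep == 2 && t % batch == 0) {
        for (int j = 0; j < P; ++j) {
          double rate = wacc_batch[j] / (3.0 * batch);
          wscale[j] *= std::exp(rate > 0.44 ? adapt_delta : -adapt_delta);
          wacc_batch[j] = 0;
        }
      }
    }

    // --- retain
    if (t > burnin && (t - burnin) % thin == 0) {
      mu_out.row(s_idx) = mu.t();
      int k = 0;
      for (int c = 0; c < P; ++c)
        for (int r = c; r < P; ++r) sig_out(s_idx, k++) = Sigma(r, c);
      if (store_theta) {
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < P; ++j)
            th_out(i, j, s_idx) = th(i, j);
      }
      ++s_idx;
    }
  }

  List out = List::create(
      _["mu"] = mu_out,
      _["sigma_lt"] = sig_out,
      _["accept"] = acc_total / iter,
      _["scale"] = scale);
  if (store_theta) out["theta"] = th_out;
  return out;
}
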