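// MCMC core for the spatially varying mixture logistic model.
//
// Blocks per sweep:
//   (a) each Gaussian-process field (intercept + one per mixture) by
//       elliptical slice sampling under its MVN(0, (1/tau) Omega) prior;
//   (b) each weight simplex by adaptive random-walk Metropolis on the
//       additive-log-ratio transform with Jacobian correction;
//   (c) covariate effects by adaptive scalar random walks;
//   (d) the spatial range rho by a reflective random walk on its uniform
//       support (Omega and its Cholesky recomputed on proposal);
//   (e) field scales sigma_beta and covariate prior scales sigma_theta by
//       reflective random walks on (0, sigma_upper).
//
// All randomness comes from R's RNG, so runs are reproducible under set.seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double stable_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static double bern_loglik(const arma::vec &y, const arma::vec &eta) {
  double s = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i)
    s += y[i] * eta[i] - stable_log1pexp(eta[i]);
  return s;
}

static arma::mat matern32(const arma::mat &D, double rho) {
  arma::mat U = D / rho;
  return (1.0 + U) % arma::exp(-U);
}

// quadratic form f' Omega^{-1} f via the lower Cholesky factor
static double quad_form(const arma::mat &L, const arma::vec &f) {
  arma::vec v = arma::solve(arma::trimatl(L), f);
  return arma::dot(v, v);
}

static double runif1() { return R::runif(0.0, 1.0); }

static arma::vec rnorm_vec(arma::uword n) {
  arma::vec z(n);
  for (arma::uword i = 0; i < n; ++i) z[i] = R::norm_rand();
  return z;
}

// reflect x into [a, b]
static double reflect(double x, double a, double b) {
  double w = b - a;
  for (int it = 0; it < 1000 && (x < a || x > b); ++it) {
    if (x < a) x = 2.0 * a - x;
    if (x > b) x = 2.0 * b - x;
    (void)w;
  }
  return x;
}

struct AdaptScalar {
  double ls;       // log step size
  double target;
  int acc = 0, tries = 0, batch = 0;
  double acc_keep = 0.0, tries_keep = 0.0;
  AdaptScalar(double ls0 = -1.0, double target_ = 0.44) : ls(ls0), target(target_) {}
  void tally(bool accepted, bool adapting) {
    ++tries;
    if (accepted) ++acc;
    if (!adapting) { tries_keep += 1.0; acc_keep += accepted ? 1.0 : 0.0; }
    if (adapting && tries >= 50) {
      ++batch;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
      ls += (acc > target * tries) ? delta : -delta;
      acc = 0; tries = 0;
    }
  }
  double rate() const { return tries_keep > 0 ? acc_keep / tries_keep : NA_REAL; }
};

// [[Rcpp::export(name = ".svm_run_chain")]]
List svm_run_chain(const arma::vec &y,
                   const List &qmats,          // per mixture: n x Cj score matrix (double)
                   const arma::mat &X,         // n x B (B may be 0)
                   const arma::mat &D,         // n x n distances
                   const List &init,
                   const List &prior,
                   const List &ctrl) {
  const arma::uword n = y.n_elem;
  const int C = qmats.size();
  const int B = X.n_cols;

  // --- control ---
  const int n_burn = as<int>(ctrl["burn_in"]);
  const int n_keep = as<int>(ctrl["retained"]);
  const int thin = as<int>(ctrl["thin"]);
  const double jitter = as<double>(ctrl["jitter"]);
  const bool spatial_intercept = as<bool>(ctrl["spatial_intercept"]);
  const bool use_lik = as<bool>(ctrl["likelihood"]);
  const bool upd_fields = as<bool>(ctrl["update_fields"]);
  const bool upd_omega = as<bool>(ctrl["update_omega"]);
  const bool upd_theta = as<bool>(ctrl["update_theta"]);
  const bool upd_rho = as<bool>(ctrl["update_rho"]);
  const bool upd_sigma = as<bool>(ctrl["update_sigma"]);
  const bool store_fields = as<bool>(ctrl["store_fields"]);
  const int rho_every = as<int>(ctrl["rho_every"]);

  // --- priors ---
  const List alpha_list = prior["alpha"];
  const double sigma_upper = as<double>(prior["sigma_upper"]);
  const double rho_min = as<double>(prior["rho_min"]);
  const double rho_max = as<double>(prior["rho_max"]);

  // --- state ---
  arma::vec beta0 = as<arma::vec>(init["beta0"]);
  arma::mat beta = as<arma::mat>(init["beta"]);       // n x C
  List omega_init = init["omega"];
  std::vector<arma::vec> omega(C);
  std::vector<arma::vec> alpha(C);
  for (int j = 0; j < C; ++j) {
    omega[j] = as<arma::vec>(omega_init[j]);
    alpha[j] = as<arma::vec>(alpha_list[j]);
  }
  arma::vec theta = as<arma::vec>(init["theta"]);
  double rho = as<double>(init["rho"]);
  arma::vec sigma_beta = as<arma::vec>(init["sigma_beta"]);   // length C + 1
  arma::vec sigma_theta = as<arma::vec>(init["sigma_theta"]); // length B
  arma::vec tau = arma::pow(sigma_beta, -2.0);

  const int F = C + 1; // fields: intercept + mixtures

  // group indices and linear predictor
  std::vector<arma::mat> Q(C);
  std::vector<arma::vec> idx(C);
  for (int j = 0; j < C; ++j) {
    Q[j] = as<arma::mat>(qmats[j]);
    idx[j] = Q[j] * omega[j];
  }
  arma::vec eta = beta0;
  for (int j = 0; j < C; ++j) eta += beta.col(j) % idx[j];
  if (B > 0) eta += X * theta;

  auto loglik = [&](const arma::vec &e) -> double {
    return use_lik ? bern_loglik(y, e) : 0.0;
  };
  double ll = loglik(eta);

  // correlation matrix state
  arma::mat Omega = matern32(D, rho);
  Omega.diag() += jitter - (Omega.diag() - 1.0); // exact unit diagonal + jitter
  arma::mat L;
  if (!arma::chol(L, Omega, "lower"))
    stop("Cholesky factorization of the spatial correlation matrix failed at initialization.");
  double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  arma::vec qf(F);
  qf[0] = quad_form(L, beta0);
  for (int j = 0; j < C; ++j) qf[j + 1] = quad_form(L, beta.col(j));

  // adaptation state
  std::vector<AdaptScalar> ad_omega, ad_theta, ad_sb, ad_st;
  for (int j = 0; j < C; ++j) ad_omega.emplace_back(-1.0, 0.234);
  for (int b = 0; b < B; ++b) ad_theta.emplace_back(-1.0, 0.44);
  for (int f = 0; f < F; ++f) ad_sb.emplace_back(-1.5, 0.44);
  for (int b = 0; b < B; ++b) ad_st.emplace_back(-0.5, 0.44);
  AdaptScalar ad_rho(std::log(0.1 * (rho_max - rho_min)), 0.44);
  AdaptScalar ad_rho_nc(std::log(0.1 * (rho_max - rho_min)), 0.44);
  std::vector<AdaptScalar> ad_sb_nc;
  for (int f = 0; f < F; ++f) ad_sb_nc.emplace_back(-1.5, 0.44);
  AdaptScalar ad_b0(-1.0, 0.44); // constant-intercept walk (spatial_intercept = false)

  // storage
  arma::mat keep_beta0, keep_theta, keep_sigma_theta;
  std::vector<arma::mat> keep_beta(C), keep_omega(C);
  arma::vec keep_rho(n_keep), keep_ll(n_keep);
  arma::mat keep_sigma_beta(n_keep, F);
  if (store_fields) keep_beta0.set_size(n_keep, n);
  for (int j = 0; j < C; ++j) {
    if (store_fields) keep_beta[j].set_size(n_keep, n);
    keep_omega[j].set_size(n_keep, Q[j].n_cols);
  }
  keep_theta.set_size(n_keep, B);
  keep_sigma_theta.set_size(n_keep, B);

  const int total = n_burn + n_keep * thin;
  int kept = 0;

  // elliptical slice sampling update of field f (mult = multiplier on eta)
  auto ess_update = [&](arma::vec &f, int fi, const arma::vec *mult) {
    arma::vec nu = (L * rnorm_vec(n)) / std::sqrt(tau[fi]);
    double logy = ll + std::log(runif1());
    double th = runif1() * 2.0 * M_PI;
    double thmin = th - 2.0 * M_PI, thmax = th;
    arma::vec f0 = f;
    for (int it = 0; it < 100; ++it) {
      arma::vec fprop = f0 * std::cos(th) + nu * std::sin(th);
      arma::vec eprop = mult ? arma::vec(eta + (fprop - f) % (*mult))
                             : arma::vec(eta + (fprop - f));
      double lp = loglik(eprop);
      if (lp > logy || (thmax - thmin) < 1e-12) {
        eta = eprop; f = fprop; ll = lp;
        qf[fi] = quad_form(L, f);
        return;
      }
      if (th < 0) thmin = th; else thmax = th;
      th = thmin + runif1() * (thmax - thmin);
    }
  };

  for (int iter = 0; iter < total; ++iter) {
    const bool adapting = iter < n_burn;

    // (a) fields
    if (upd_fields) {
      if (spatial_intercept) {
        ess_update(beta0, 0, nullptr);
      } else {
        // constant intercept: scalar random walk under a diffuse N(0, 10^2) prior
        double b0 = beta0[0];
        double bp = b0 + std::exp(ad_b0.ls) * R::norm_rand();
        arma::vec eprop = eta + (bp - b0);
        double lp = loglik(eprop);
        double dpost = lp - ll + (b0 * b0 - bp * bp) / 200.0;
        bool accept = std::log(runif1()) < dpost;
        if (accept) { beta0.fill(bp); eta = eprop; ll = lp; }
        ad_b0.tally(accept, adapting);
      }
      for (int j = 0; j < C; ++j) {
        arma::vec fj = beta.col(j);
        ess_update(fj, j + 1, &idx[j]);
        beta.col(j) = fj;
      }
    }

    // (b) omega via ALR random walk
    if (upd_omega) {
      for (int j = 0; j < C; ++j) {
        const arma::uword K = omega[j].n_elem;
        if (K < 2) continue;
        arma::vec w = omega[j];
        arma::vec z(K - 1);
        for (arma::uword k = 0; k < K - 1; ++k) z[k] = std::log(w[k] / w[K - 1]);
        arma::vec zp = z + std::exp(ad_omega[j].ls) * rnorm_vec(K - 1);
        arma::vec wp(K);
        double mx = 0.0;
        for (arma::uword k = 0; k < K - 1; ++k) mx = std::max(mx, zp[k]);
        double denom = std::exp(-mx);
        for (arma::uword k = 0; k < K - 1; ++k) denom += std::exp(zp[k] - mx);
        for (arma::uword k = 0; k < K - 1; ++k) wp[k] = std::exp(zp[k] - mx) / denom;
        wp[K - 1] = std::exp(-mx) / denom;

        arma::vec idx_p = Q[j] * wp;
        arma::vec eprop = eta + beta.col(j) % (idx_p - idx[j]);
        double lp = loglik(eprop);
        double dpost = lp - ll;
        for (arma::uword k = 0; k < K; ++k) {
          dpost += (alpha[j][k] - 1.0) * (std::log(wp[k]) - std::log(w[k]));
          dpost += std::log(wp[k]) - std::log(w[k]); // ALR Jacobian
        }
        bool accept = std::log(runif1()) < dpost;
        if (accept) {
          omega[j] = wp; idx[j] = idx_p; eta = eprop; ll = lp;
        }
        ad_omega[j].tally(accept, adapting);
      }
    }

    // (c) theta scalar random walks
    if (upd_theta) {
      for (int b = 0; b < B; ++b) {
        double tp = theta[b] + std::exp(ad_theta[b].ls) * R::norm_rand();
        arma::vec eprop = eta + X.col(b) * (tp - theta[b]);
        double lp = loglik(eprop);
        double s2 = sigma_theta[b] * sigma_theta[b];
        double dpost = lp - ll + (theta[b] * theta[b] - tp * tp) / (2.0 * s2);
        bool accept = std::log(runif1()) < dpost;
        if (accept) { theta[b] = tp; eta = eprop; ll = lp; }
        ad_theta[b].tally(accept, adapting);
      }
    }

    // (d) rho: alternate a centered update (fields fixed, prior ratio) with a
    // non-centered one (whitened fields fixed, likelihood ratio) for mixing
    if (upd_rho && (iter % rho_every == 0)) {
      const bool centered = ((iter / rho_every) % 2) == 0;
      AdaptScalar &ad = centered ? ad_rho : ad_rho_nc;
      double rp = reflect(rho + std::exp(ad.ls) * R::norm_rand(), rho_min, rho_max);
      arma::mat Op = matern32(D, rp);
      Op.diag() += jitter - (Op.diag() - 1.0);
      arma::mat Lp;
      bool ok = arma::chol(Lp, Op, "lower");
      bool accept = false;
      if (ok && centered) {
        double logdet_p = 2.0 * arma::sum(arma::log(Lp.diag()));
        arma::vec qfp(F);
        qfp[0] = quad_form(Lp, beta0);
        for (int j = 0; j < C; ++j) qfp[j + 1] = quad_form(Lp, beta.col(j));
        int nf = spatial_intercept ? F : C; // constant intercept: no MVN term
        double dpost = -0.5 * nf * (logdet_p - logdet);
        int f0i = spatial_intercept ? 0 : 1;
        for (int f = f0i; f < F; ++f) dpost += -0.5 * tau[f] * (qfp[f] - qf[f]);
        accept = std::log(runif1()) < dpost;
        if (accept) {
          rho = rp; L = Lp; logdet = logdet_p; qf = qfp;
        }
      } else if (ok) {
        // whitened: v_f = L^{-1} f_f held fixed, so f'_f = Lp v_f; the MVN
        // prior term cancels and only the likelihood enters the ratio
        double logdet_p = 2.0 * arma::sum(arma::log(Lp.diag()));
        arma::vec b0p = beta0;
        arma::mat betap = beta;
        arma::vec eprop = eta;
        if (spatial_intercept) {
          b0p = Lp * arma::solve(arma::trimatl(L), beta0);
          eprop += b0p - beta0;
        }
        for (int j = 0; j < C; ++j) {
          betap.col(j) = Lp * arma::solve(arma::trimatl(L), beta.col(j));
          eprop += (betap.col(j) - beta.col(j)) % idx[j];
        }
        double lp = loglik(eprop);
        accept = std::log(runif1()) < (lp - ll);
        if (accept) {
          rho = rp; L = Lp; logdet = logdet_p;
          beta0 = b0p; beta = betap; eta = eprop; ll = lp;
          // qf is invariant under the whitened map
        }
      }
      ad.tally(accept, adapting);
    }

    // (e) scales
    if (upd_sigma) {
      int f0i = spatial_intercept ? 0 : 1;
      for (int f = f0i; f < F; ++f) {
        double sp = reflect(sigma_beta[f] + std::exp(ad_sb[f].ls) * R::norm_rand(),
                            1e-8, sigma_upper);
        double taup = 1.0 / (sp * sp);
        double dpost = ((double)n) * (std::log(sigma_beta[f]) - std::log(sp)) -
                       0.5 * (taup - tau[f]) * qf[f];
        bool accept = std::log(runif1()) < dpost;
        if (accept) { sigma_beta[f] = sp; tau[f] = taup; }
        ad_sb[f].tally(accept, adapting);
      }
      // interweaved non-centered scale update: rescale the field with the
      // scale (whitened field fixed), so only the likelihood enters
      for (int f = f0i; f < F; ++f) {
        double s0 = sigma_beta[f];
        double sp = reflect(s0 + std::exp(ad_sb_nc[f].ls) * R::norm_rand(),
                            1e-8, sigma_upper);
        double g = sp / s0;
        arma::vec eprop;
        if (f == 0) {
          eprop = eta + (g - 1.0) * beta0;
        } else {
          eprop = eta + ((g - 1.0) * beta.col(f - 1)) % idx[f - 1];
        }
        double lp = loglik(eprop);
        bool accept = std::log(runif1()) < (lp - ll);
        if (accept) {
          if (f == 0) beta0 *= g; else beta.col(f - 1) *= g;
          sigma_beta[f] = sp; tau[f] = 1.0 / (sp * sp);
          qf[f] *= g * g;
          eta = eprop; ll = lp;
        }
        ad_sb_nc[f].tally(accept, adapting);
      }
      for (int b = 0; b < B; ++b) {
        double sp = reflect(sigma_theta[b] + std::exp(ad_st[b].ls) * R::norm_rand(),
                            1e-8, sigma_upper);
        double dpost = (std::log(sigma_theta[b]) - std::log(sp)) -
                       0.5 * theta[b] * theta[b] *
                       (1.0 / (sp * sp) - 1.0 / (sigma_theta[b] * sigma_theta[b]));
        bool accept = std::log(runif1()) < dpost;
        if (accept) sigma_theta[b] = sp;
        ad_st[b].tally(accept, adapting);
      }
    }

    // store every thin-th post-burn sweep, starting with the first
    if (iter >= n_burn && (iter - n_burn) % thin == 0 && kept < n_keep) {
      if (store_fields) {
        keep_beta0.row(kept) = beta0.t();
        for (int j = 0; j < C; ++j) keep_beta[j].row(kept) = beta.col(j).t();
      }
      for (int j = 0; j < C; ++j) keep_omega[j].row(kept) = omega[j].t();
      if (B > 0) {
        keep_theta.row(kept) = theta.t();
        keep_sigma_theta.row(kept) = sigma_theta.t();
      }
      keep_rho[kept] = rho;
      keep_sigma_beta.row(kept) = sigma_beta.t();
      keep_ll[kept] = ll;
      ++kept;
    }

    if (iter % 512 == 0) Rcpp::checkUserInterrupt();
  }

  List omega_out(C), beta_out(C);
  for (int j = 0; j < C; ++j) {
    omega_out[j] = keep_omega[j];
    beta_out[j] = store_fields ? wrap(keep_beta[j]) : R_NilValue;
  }
  NumericVector acc_omega(C), acc_theta(B), acc_sb(F), acc_st(B);
  for (int j = 0; j < C; ++j) acc_omega[j] = ad_omega[j].rate();
  for (int b = 0; b < B; ++b) acc_theta[b] = ad_theta[b].rate();
  for (int f = 0; f < F; ++f) acc_sb[f] = ad_sb[f].rate();
  for (int b = 0; b < B; ++b) acc_st[b] = ad_st[b].rate();

  return List::create(
    _["beta0"] = store_fields ? wrap(keep_beta0) : R_NilValue,
    _["beta"] = beta_out,
    _["omega"] = omega_out,
    _["theta"] = keep_theta,
    _["rho"] = keep_rho,
    _["sigma_beta"] = keep_sigma_beta,
    _["sigma_theta"] = keep_sigma_theta,
    _["loglik"] = keep_ll,
    _["acceptance"] = List::create(
      _["omega"] = acc_omega, _["theta"] = acc_theta, _["rho"] = ad_rho.rate(),
      _["sigma_beta"] = acc_sb, _["sigma_theta"] = acc_st)
  );
}

// Joint conditional (kriging) draws of one field at new locations, one draw
// per retained iteration. field_draws is K x n; returns K x m.
// [[Rcpp::export(name = ".svm_grid_draws")]]
arma::mat svm_grid_draws(const arma::mat &field_draws,
                         const arma::vec &rho_draws,
                         const arma::vec &tau_draws,
                         const arma::mat &D_oo,
                         const arma::mat &D_no,
                         const arma::mat &D_nn,
                         double jitter) {
  const arma::uword K = field_draws.n_rows;
  const arma::uword m = D_no.n_rows;
  arma::mat out(K, m);
  for (arma::uword k = 0; k < K; ++k) {
    double rho = rho_draws[k], tau = tau_draws[k];
    arma::mat Coo = matern32(D_oo, rho);
    Coo.diag() += jitter - (Coo.diag() - 1.0);
    arma::mat L;
    if (!arma::chol(L, Coo, "lower"))
      stop("Cholesky factorization failed during grid prediction (iteration %d).", (int)k + 1);
    arma::mat Cno = matern32(D_no, rho);                 // m x n
    arma::mat V = arma::solve(arma::trimatl(L), Cno.t()); // n x m
    arma::vec w = arma::solve(arma::trimatl(L), field_draws.row(k).t());
    arma::vec mean = V.t() * w;
    arma::mat cond = matern32(D_nn, rho);
    cond.diag() += jitter - (cond.diag() - 1.0);
    cond -= V.t() * V;
    cond = arma::symmatu(cond);
    arma::mat Lc;
    if (!arma::chol(Lc, cond, "lower")) {
      arma::vec ev; arma::mat evec;
      if (!arma::eig_sym(ev, evec, cond))
        stop("Conditional covariance is not factorizable during grid prediction.");
      ev.transform([](double v) { return v > 0 ? std::sqrt(v) : 0.0; });
      Lc = evec * arma::diagmat(ev);
    }
    out.row(k) = (mean + (Lc * rnorm_vec(m)) / std::sqrt(tau)).t();
    if (k % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
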