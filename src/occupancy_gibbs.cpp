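// Blocked Gibbs sampler for the autologistic multi-season occupancy model.
//
// Latent occupancy states z(i,t) are updated from their full conditionals
// one site-year at a time; the occupancy-level coefficients
// (beta0, beta, a_t, b_t[, beta_zint]) and the detection-level coefficients
// (alpha0, alpha1) are updated as two Gaussian blocks after Polya-Gamma
// augmentation of their logistic likelihoods (Polson, Scott & Windle 2013).
// All randomness goes through R's RNG so that set.seed() in the caller
// makes a chain fully reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double PG_TRUNC = 0.64;

// Piece n of the alternating series for the Jacobi density J*(1, .).
static double pg_a_coef(int n, double x) {
  double n5 = n + 0.5;
  if (x > PG_TRUNC) {
    return M_PI * n5 * std::exp(-n5 * n5 * M_PI * M_PI * x / 2.0);
  }
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * n5 * std::exp(-2.0 * n5 * n5 / x);
}

// P(proposal comes from the truncated-exponential tail) in the J*(1,z) mixture.
static double pg_mass_texpon(double z) {
  double t = PG_TRUNC;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double b = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// Inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, PG_TRUNC].
static double pg_rtigauss(double z) {
  double t = PG_TRUNC;
  double x = t + 1.0;
  if (t < 1.0 / z || z == 0.0) {  // mode right of t: rejection from truncated chi
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = norm_rand();
      y *= y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// One draw from PG(1, c) by the Devroye-type alternating-series method.
static double rpg1(double c) {
  double z = std::fabs(c) * 0.5;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  for (;;) {
    double x;
    if (unif_rand() < pg_mass_texpon(z)) {
      x = PG_TRUNC + exp_rand() / fz;
    } else {
      x = pg_rtigauss(z);
    }
    double s = pg_a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= pg_a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += pg_a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

// Exposed for unit tests (moment checks against tanh(c/2)/(2c)).
// [[Rcpp::export(name = ".rpg_vec")]]
NumericVector rpg_vec(int n, double c) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(c);
  return out;
}

static inline double log_invlogit(double x) {
  // log(1/(1+exp(-x))), stable for large |x|
  if (x > 0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

static inline double invlogit(double x) {
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export(name = ".occu_gibbs_chain")]]
List occu_gibbs_chain(IntegerVector y,       // n*T*J, (i,t,j) col-major, -1 = missing
                      NumericVector date,    // n*T*J standardized dates (0 where missing)
                      NumericMatrix X,       // n x K standardized covariates
                      int n, int T, int J,
                      NumericVector prior_mean_occ, NumericVector prior_prec_occ,
                      NumericVector prior_mean_det, NumericVector prior_prec_det,
                      NumericVector theta_occ_init, NumericVector theta_det_init,
                      IntegerMatrix z_init,  // n x T
                      int n_burn, int n_keep, int thin,
                      bool share_trans, bool interaction,
                      NumericVector inter_cov,  // n, covariate entering the z_prev interaction
                      bool save_z) {
  const int K = X.ncol();
  const int S = (T > 1) ? (share_trans ? 1 : T - 1) : 0;
  const int P = 1 + K + 2 * S + (interaction ? 1 : 0);
  const int idx_a0 = 1 + K;           // first a column
  const int idx_b0 = 1 + K + S;       // first b column
  const int idx_int = 1 + K + 2 * S;  // interaction column (if any)

  arma::vec th(P), pm(P), pr(P);
  for (int p = 0; p < P; ++p) {
    th(p) = theta_occ_init[p];
    pm(p) = prior_mean_occ[p];
    pr(p) = prior_prec_occ[p];
  }
  arma::vec thd(2), pmd(2), prd(2);
  for (int p = 0; p < 2; ++p) {
    thd(p) = theta_det_init[p];
    pmd(p) = prior_mean_det[p];
    prd(p) = prior_prec_det[p];
  }

  IntegerMatrix z(clone(z_init));
  // site-years with at least one detection: z pinned at 1
  std::vector<char> forced(n * T, 0);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t)
      for (int j = 0; j < J; ++j)
        if (y[i + n * t + n * T * j] == 1) forced[i + n * t] = 1;

  // covariate part of the occupancy predictor, fixed across iterations
  std::vector<double> etaX(n, 0.0);

  NumericMatrix theta_out(n_keep, P + 2);
  IntegerMatrix z_out(save_z ? n_keep : 1, save_z ? n * T : 1);

  const int n_sweep = n_burn + n_keep * thin;
  int kept = 0;

  auto s_of = [&](int t) { return share_trans ? 0 : (t - 1); };  // t = 1..T-1 transition index

  for (int sweep = 0; sweep < n_sweep; ++sweep) {
    // refresh cached covariate predictor (theta changes every sweep)
    for (int i = 0; i < n; ++i) {
      double e = 0.0;
      for (int k = 0; k < K; ++k) e += th(1 + k) * X(i, k);
      etaX[i] = e;
    }
    const double alpha0 = thd(0), alpha1 = thd(1);

    // --- latent occupancy states -------------------------------------------
    for (int i = 0; i < n; ++i) {
      for (int t = 0; t < T; ++t) {
        if (forced[i + n * t]) { z(i, t) = 1; continue; }
        // log P(z=1, rest)/P(z=0, rest) pieces
        double eta_in;
        if (t == 0) {
          eta_in = th(0) + etaX[i];
        } else {
          int s = s_of(t);
          eta_in = th(idx_a0 + s) + etaX[i] + z(i, t - 1) *
            (th(idx_b0 + s) + (interaction ? th(idx_int) * inter_cov[i] : 0.0));
        }
        double l1 = log_invlogit(eta_in);
        double l0 = log_invlogit(-eta_in);
        // detections at (i,t): all observed y are 0 here (else forced)
        for (int j = 0; j < J; ++j) {
          int yy = y[i + n * t + n * T * j];
          if (yy < 0) continue;
          double pe = alpha0 + alpha1 * date[i + n * t + n * T * j];
          l1 += log_invlogit(-pe);  // P(y=0 | z=1) = 1-p
          // P(y=0 | z=0) = 1 contributes 0 to l0
        }
        if (t < T - 1) {  // effect on the next transition
          int s = s_of(t + 1);
          double base = th(idx_a0 + s) + etaX[i];
          double bump = th(idx_b0 + s) + (interaction ? th(idx_int) * inter_cov[i] : 0.0);
          int znext = z(i, t + 1);
          double e1 = base + bump, e0 = base;
          l1 += log_invlogit(znext ? e1 : -e1);
          l0 += log_invlogit(znext ? e0 : -e0);
        }
        z(i, t) = (unif_rand() < invlogit(l1 - l0)) ? 1 : 0;
      }
    }

    // --- occupancy-level coefficients (PG-augmented Gaussian block) --------
    {
      arma::mat A(P, P, arma::fill::zeros);
      arma::vec c(P, arma::fill::zeros);
      std::vector<int> nz;
      std::vector<double> xv;
      nz.reserve(K + 3);
      xv.reserve(K + 3);
      for (int i = 0; i < n; ++i) {
        for (int t = 0; t < T; ++t) {
          nz.clear();
          xv.clear();
          double eta;
          if (t == 0) {
            nz.push_back(0); xv.push_back(1.0);
            eta = th(0) + etaX[i];
          } else {
            int s = s_of(t);
            nz.push_back(idx_a0 + s); xv.push_back(1.0);
            eta = th(idx_a0 + s) + etaX[i];
            if (z(i, t - 1) == 1) {
              nz.push_back(idx_b0 + s); xv.push_back(1.0);
              eta += th(idx_b0 + s);
              if (interaction) {
                nz.push_back(idx_int); xv.push_back(inter_cov[i]);
                eta += th(idx_int) * inter_cov[i];
              }
            }
          }
          for (int k = 0; k < K; ++k) {
            if (X(i, k) != 0.0) { nz.push_back(1 + k); xv.push_back(X(i, k)); }
          }
          double om = rpg1(eta);
          double kap = z(i, t) - 0.5;
          int M = nz.size();
          for (int u = 0; u < M; ++u) {
            c(nz[u]) += kap * xv[u];
            for (int v = 0; v <= u; ++v) {
              int hi = std::max(nz[u], nz[v]), lo = std::min(nz[u], nz[v]);
              A(hi, lo) += om * xv[u] * xv[v];  // always the lower triangle
            }
          }
        }
      }
      A = arma::symmatl(A);
      A.diag() += pr;
      arma::vec rhs = c + pr % pm;
      arma::mat U = arma::chol(A);  // upper: A = U' U
      arma::vec mu = arma::solve(arma::trimatl(U.t()), rhs);
      mu = arma::solve(arma::trimatu(U), mu);
      arma::vec eps(P);
      for (int p = 0; p < P; ++p) eps(p) = norm_rand();
      th = mu + arma::solve(arma::trimatu(U), eps);
    }

    // --- detection-level coefficients --------------------------------------
    {
      arma::mat A(2, 2, arma::fill::zeros);
      arma::vec c(2, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        for (int t = 0; t < T; ++t) {
          if (z(i, t) != 1) continue;
          for (int j = 0; j < J; ++j) {
            int yy = y[i + n * t + n * T * j];
            if (yy < 0) continue;
            double d = date[i + n * t + n * T * j];
            double eta = thd(0) + thd(1) * d;
            double om = rpg1(eta);
            double kap = yy - 0.5;
            c(0) += kap;
            c(1) += kap * d;
            A(0, 0) += om;
            A(0, 1) += om * d;
            A(1, 1) += om * d * d;
          }
        }
      }
      A(1, 0) = A(0, 1);
      A.diag() += prd;
      arma::vec rhs = c + prd % pmd;
      arma::mat U = arma::chol(A);
      arma::vec mu = arma::solve(arma::trimatl(U.t()), rhs);
      mu = arma::solve(arma::trimatu(U), mu);
      arma::vec eps(2);
      eps(0) = norm_rand();
      eps(1) = norm_rand();
      thd = mu + arma::solve(arma::trimatu(U), eps);
    }

    // --- store --------------------------------------------------------------
    if (sweep >= n_burn && ((sweep - n_burn + 1) % thin == 0)) {
      for (int p = 0; p < P; ++p) theta_out(kept, p) = th(p);
      theta_out(kept, P) = thd(0);
      theta_out(kept, P + 1) = thd(1);
      if (save_z) {
        for (int t = 0; t < T; ++t)
          for (int i = 0; i < n; ++i)
            z_out(kept, i + n * t) = z(i, t);
      }
      ++kept;
      if (kept == n_keep) break;
    }
  }

  return List::create(_["theta"] = theta_out, _["z"] = z_out);
}
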