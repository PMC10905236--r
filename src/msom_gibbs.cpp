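// Polya-Gamma augmented Gibbs sampler for the seasonal multi-species
// robust-design occupancy model.
//
// State per species i: occupancy coefficients a_i (intercept + site
// covariates), detection coefficients b_i (one intercept per primary
// period + visit covariates), latent incidence z_ijk. Community layer:
// per-coefficient-family mean mu_f and variance s2_f with
// mu_f ~ N(0, 2.72) and s2_f ~ InvGamma(0.1, 0.1) (both conjugate here).
//
// The PG(1, c) sampler is Devroye's exact alternating-series method; all
// randomness is driven by R's uniform stream so set.seed() governs
// reproducibility. Normal deviates use Box-Muller on that stream (faster
// than R's inversion sampler in this inner loop).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double PG_TRUNC = 0.64;

// --- fast normal draws: Box-Muller with a cached spare -------------------
static double norm_spare = 0.0;
static bool norm_have_spare = false;

static inline void norm_reset() { norm_have_spare = false; }

static inline double fast_norm() {
  if (norm_have_spare) {
    norm_have_spare = false;
    return norm_spare;
  }
  double u1 = R::unif_rand(), u2 = R::unif_rand();
  double r = std::sqrt(-2.0 * std::log(u1));
  double th = 2.0 * M_PI * u2;
  norm_spare = r * std::sin(th);
  norm_have_spare = true;
  return r * std::cos(th);
}

// log Phi(x); erfc in the bulk, asymptotic expansion in the far left tail
static inline double log_phi(double x) {
  if (x < -8.0) {
    double x2 = x * x;
    return -0.5 * x2 - std::log(-x) - 0.9189385332046727 +
           std::log1p(-1.0 / x2 + 3.0 / (x2 * x2));
  }
  return std::log(0.5 * std::erfc(-x * M_SQRT1_2));
}

// coefficients of the alternating series for the Jacobi-type density
static inline double pg_a_coef(int n, double x) {
  double h = n + 0.5;
  if (x > PG_TRUNC) {
    double K = h * M_PI;
    return K * std::exp(-0.5 * K * K * x);
  }
  double s = 2.0 / (M_PI * x);
  return M_PI * h * s * std::sqrt(s) * std::exp(-2.0 * h * h / x);
}

// P(choose the truncated-exponential proposal) = p/(p+q)
static inline double pg_mass_texpon(double Z, double fz) {
  double t = PG_TRUNC;
  double rt = 1.25;                       // sqrt(1/t) for t = 0.64
  double b = rt * (t * Z - 1.0);
  double a = -rt * (t * Z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - Z + log_phi(b);
  double xa = x0 + Z + log_phi(a);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// inverse-Gaussian(1/Z, 1) truncated to (0, PG_TRUNC)
static inline double pg_rtigauss(double Z) {
  double R_ = PG_TRUNC;
  double X = R_ + 1.0;
  if (1.0 / Z > R_) {
    // mu > truncation point: rejection from truncated inverse-chi^2
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double E1 = R::exp_rand(), E2 = R::exp_rand();
      while (E1 * E1 > 2.0 * E2 / R_) {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      }
      X = R_ / ((1.0 + R_ * E1) * (1.0 + R_ * E1));
      alpha = std::exp(-0.5 * Z * Z * X);
    }
  } else {
    double mu = 1.0 / Z;
    while (X > R_) {
      double Y = fast_norm();
      Y = Y * Y;
      double mu_Y = mu * Y;
      X = mu + 0.5 * mu * mu_Y -
          0.5 * mu * std::sqrt(4.0 * mu_Y + mu_Y * mu_Y);
      if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

// The proposal mixture weight is a smooth function of Z; tabulate it once
// on a fine grid and interpolate with a 4-point Lagrange rule (error well
// below 1e-12, the same order as the libm special functions themselves).
static const int PMIX_N = 4097;
static const double PMIX_STEP = 1.0 / 512.0;   // covers Z in [0, 8]
static double pmix_tab[PMIX_N];
static bool pmix_ready = false;

static void pmix_init() {
  for (int i = 0; i < PMIX_N; ++i) {
    double Z = i * PMIX_STEP;
    pmix_tab[i] = pg_mass_texpon(Z, 0.125 * M_PI * M_PI + 0.5 * Z * Z);
  }
  pmix_ready = true;
}

static inline double pmix_lookup(double Z, double fz) {
  if (Z >= 8.0 - 2.0 * PMIX_STEP) return pg_mass_texpon(Z, fz);
  double u = Z / PMIX_STEP;
  int i = (int)u;
  if (i < 1) i = 1;
  if (i > PMIX_N - 3) i = PMIX_N - 3;
  double t = u - i;                 // in [-1, 2] near edges, [0,1] inside
  const double* f = &pmix_tab[i - 1];
  // 4-point Lagrange at nodes -1, 0, 1, 2 in units of the step
  double tm1 = t + 1.0, t0 = t, t1 = t - 1.0, t2 = t - 2.0;
  return (-f[0] * t0 * t1 * t2 / 6.0 + f[1] * tm1 * t1 * t2 / 2.0 -
          f[2] * tm1 * t0 * t2 / 2.0 + f[3] * tm1 * t0 * t1 / 6.0);
}

// one exact PG(1, z) draw (Devroye / Polson-Scott-Windle)
static double rpg1(double z) {
  double Z = std::fabs(z) * 0.5;
  double fz = 0.125 * M_PI * M_PI + 0.5 * Z * Z;
  double pmix = pmix_lookup(Z, fz);
  for (;;) {
    double X;
    if (R::unif_rand() < pmix) {
      X = PG_TRUNC + R::exp_rand() / fz;
    } else {
      X = pg_rtigauss(Z);
    }
    double S = pg_a_coef(0, X);
    double Y = R::unif_rand() * S;
    int n = 0;
    bool accept = false;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= pg_a_coef(n, X);
        if (Y <= S) { accept = true; break; }
      } else {
        S += pg_a_coef(n, X);
        if (Y > S) break;
      }
    }
    if (accept) return 0.25 * X;
  }
}

// [[Rcpp::export(name = ".rpg_devroye")]]
NumericVector rpg_devroye(int n, NumericVector z) {
  norm_reset();
  if (!pmix_ready) pmix_init();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i % z.size()]);
  return out;
}

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// draw from N(Prec^{-1} b, Prec^{-1}); Prec given as full symmetric matrix
static void mvn_from_precision(const arma::mat& Prec, const arma::vec& b,
                               arma::vec& out) {
  arma::mat U = arma::chol(Prec);          // U'U = Prec
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), b));
  arma::vec zdraw(b.n_elem);
  for (arma::uword i = 0; i < b.n_elem; ++i) zdraw(i) = fast_norm();
  out = mu + arma::solve(arma::trimatu(U), zdraw);
}

// symmetrize the upper triangle accumulated in-place
static inline void symmetrize_upper(arma::mat& M) {
  for (arma::uword c = 0; c < M.n_cols; ++c)
    for (arma::uword r = c + 1; r < M.n_rows; ++r) M(r, c) = M(c, r);
}

// One MCMC chain. Data layout prepared in R:
//  Xocc:       J x P occupancy design (intercept column included)
//  cell_site:  ncell ints, 0-based site of each active cell (site-primary)
//  Y:          nobs x N integer matrix, detection per observed visit x species
//  Bdet:       nobs x Q detection design (period dummies + visit covariates)
//  visit_cell: nobs ints, 0-based active-cell index of each visit row
// Only site-primaries with >= 1 observed secondary occasion enter the
// likelihood ("active" cells); z there is part of the Gibbs state.
// [[Rcpp::export(name = ".msom_gibbs_chain")]]
List msom_gibbs_chain(const arma::mat& Xocc,
                      const arma::ivec& cell_site,
                      const arma::imat& Y,
                      const arma::mat& Bdet,
                      const arma::ivec& visit_cell,
                      int n_iter, int burn_in, int thin,
                      bool hierarchical,
                      double mu_prior_var,
                      double ig_shape, double ig_rate,
                      double fixed_coef_var) {
  norm_reset();
  if (!pmix_ready) pmix_init();
  const int J = Xocc.n_rows, P = Xocc.n_cols;
  const int N = Y.n_cols;
  const int nobs = Bdet.n_rows, Q = Bdet.n_cols;
  const int ncell = cell_site.n_elem;

  // visits grouped by cell (flat CSR layout)
  std::vector<int> cell_start(ncell + 1, 0), cell_vis(nobs);
  {
    std::vector<int> cnt(ncell, 0);
    for (int v = 0; v < nobs; ++v) ++cnt[visit_cell(v)];
    for (int c = 0; c < ncell; ++c) cell_start[c + 1] = cell_start[c] + cnt[c];
    std::vector<int> pos(cell_start.begin(), cell_start.end() - 1);
    for (int v = 0; v < nobs; ++v) cell_vis[pos[visit_cell(v)]++] = v;
  }

  // detection-implies-presence: fixed z cells per species
  arma::imat any_det(ncell, N, arma::fill::zeros);
  for (int v = 0; v < nobs; ++v)
    for (int i = 0; i < N; ++i)
      if (Y(v, i) == 1) any_det(visit_cell(v), i) = 1;

  // state
  arma::mat A(P, N, arma::fill::zeros);   // occupancy coefs per species
  arma::mat B(Q, N, arma::fill::zeros);   // detection coefs per species
  arma::imat Z(ncell, N);                 // latent incidence (active cells)
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < ncell; ++c) Z(c, i) = any_det(c, i);
  arma::vec mu_a(P, arma::fill::zeros), s2_a(P, arma::fill::ones);
  arma::vec mu_b(Q, arma::fill::zeros), s2_b(Q, arma::fill::ones);
  if (!hierarchical) {
    s2_a.fill(fixed_coef_var);
    s2_b.fill(fixed_coef_var);
  }

  const int n_store = (n_iter - burn_in) / thin;
  arma::cube outA(P, N, n_store), outB(Q, N, n_store);
  arma::mat out_mu_a(P, n_store), out_s2_a(P, n_store);
  arma::mat out_mu_b(Q, n_store), out_s2_b(Q, n_store);
  arma::icube outZ(ncell, N, n_store);

  arma::vec p_vis(nobs), psi(ncell), xb(J);
  arma::vec somega(J), kappa(J);
  arma::mat PrecA(P, P), PrecB(Q, Q);
  arma::vec bvecA(P), bvecB(Q), coef(std::max(P, Q));
  int stored = 0;

  // contiguous upper-triangle outer products of the fixed design rows,
  // so the weighted cross-product accumulations are cache-friendly
  const int PT = P * (P + 1) / 2, QT = Q * (Q + 1) / 2;
  std::vector<double> Xout((size_t)J * PT), Bout((size_t)nobs * QT);
  for (int j = 0; j < J; ++j) {
    int idx = 0;
    for (int p2 = 0; p2 < P; ++p2)
      for (int p1 = 0; p1 <= p2; ++p1)
        Xout[(size_t)j * PT + idx++] = Xocc(j, p1) * Xocc(j, p2);
  }
  for (int v = 0; v < nobs; ++v) {
    int idx = 0;
    for (int q2 = 0; q2 < Q; ++q2)
      for (int q1 = 0; q1 <= q2; ++q1)
        Bout[(size_t)v * QT + idx++] = Bdet(v, q1) * Bdet(v, q2);
  }
  std::vector<double> accA(PT), accB(QT);

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      xb = Xocc * A.col(i);
      for (int c = 0; c < ncell; ++c) psi(c) = inv_logit(xb(cell_site(c)));
      arma::vec etad = Bdet * B.col(i);
      for (int v = 0; v < nobs; ++v) p_vis(v) = inv_logit(etad(v));

      // z update at cells with no detection
      for (int c = 0; c < ncell; ++c) {
        if (any_det(c, i)) { Z(c, i) = 1; continue; }
        double q = 1.0;
        for (int s = cell_start[c]; s < cell_start[c + 1]; ++s)
          q *= (1.0 - p_vis(cell_vis[s]));
        double num = psi(c) * q;
        Z(c, i) = (R::unif_rand() * (num + 1.0 - psi(c)) < num) ? 1 : 0;
      }

      // occupancy coefficients: PG logistic regression of z on Xocc rows;
      // cells within a site share the design row, so accumulate by site
      {
        somega.zeros();
        kappa.zeros();
        for (int c = 0; c < ncell; ++c) {
          somega(cell_site(c)) += rpg1(xb(cell_site(c)));
          kappa(cell_site(c)) += Z(c, i) - 0.5;
        }
        std::fill(accA.begin(), accA.end(), 0.0);
        bvecA.zeros();
        for (int j = 0; j < J; ++j) {
          const double sj = somega(j), kj = kappa(j);
          const double* xo = &Xout[(size_t)j * PT];
          for (int u = 0; u < PT; ++u) accA[u] += sj * xo[u];
          for (int p2 = 0; p2 < P; ++p2) bvecA(p2) += kj * Xocc(j, p2);
        }
        {
          int idx = 0;
          for (int p2 = 0; p2 < P; ++p2)
            for (int p1 = 0; p1 <= p2; ++p1) PrecA(p1, p2) = accA[idx++];
        }
        symmetrize_upper(PrecA);
        PrecA.diag() += 1.0 / s2_a;
        bvecA += mu_a / s2_a;
        arma::vec draw(P);
        mvn_from_precision(PrecA, bvecA, draw);
        A.col(i) = draw;
      }

      // detection coefficients: PG regression of y on Bdet, occupied cells
      {
        std::fill(accB.begin(), accB.end(), 0.0);
        bvecB.zeros();
        const arma::sword* zi = Z.colptr(i);
        for (int v = 0; v < nobs; ++v) {
          if (zi[visit_cell(v)] != 1) continue;
          const double om = rpg1(etad(v));
          const double ky = Y(v, i) - 0.5;
          const double* bo = &Bout[(size_t)v * QT];
          for (int u = 0; u < QT; ++u) accB[u] += om * bo[u];
          for (int q2 = 0; q2 < Q; ++q2) bvecB(q2) += ky * Bdet(v, q2);
        }
        {
          int idx = 0;
          for (int q2 = 0; q2 < Q; ++q2)
            for (int q1 = 0; q1 <= q2; ++q1) PrecB(q1, q2) = accB[idx++];
        }
        symmetrize_upper(PrecB);
        PrecB.diag() += 1.0 / s2_b;
        bvecB += mu_b / s2_b;
        arma::vec draw(Q);
        mvn_from_precision(PrecB, bvecB, draw);
        B.col(i) = draw;
      }
    }

    // community hyperparameters, conjugate updates per coefficient family
    if (hierarchical) {
      for (int f = 0; f < P; ++f) {
        double sum = arma::accu(A.row(f));
        double prec = N / s2_a(f) + 1.0 / mu_prior_var;
        mu_a(f) = (sum / s2_a(f)) / prec + fast_norm() / std::sqrt(prec);
        double ss = arma::accu(arma::square(A.row(f) - mu_a(f)));
        s2_a(f) = 1.0 / R::rgamma(ig_shape + 0.5 * N,
                                  1.0 / (ig_rate + 0.5 * ss));
      }
      for (int f = 0; f < Q; ++f) {
        double sum = arma::accu(B.row(f));
        double prec = N / s2_b(f) + 1.0 / mu_prior_var;
        mu_b(f) = (sum / s2_b(f)) / prec + fast_norm() / std::sqrt(prec);
        double ss = arma::accu(arma::square(B.row(f) - mu_b(f)));
        s2_b(f) = 1.0 / R::rgamma(ig_shape + 0.5 * N,
                                  1.0 / (ig_rate + 0.5 * ss));
      }
    }

    if (it >= burn_in && ((it - burn_in) % thin == 0) && stored < n_store) {
      outA.slice(stored) = A;
      outB.slice(stored) = B;
      out_mu_a.col(stored) = mu_a;
      out_s2_a.col(stored) = s2_a;
      out_mu_b.col(stored) = mu_b;
      out_s2_b.col(stored) = s2_b;
      outZ.slice(stored) = Z;
      ++stored;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["alpha"] = outA, _["beta"] = outB,
      _["mu_alpha"] = out_mu_a, _["sigma2_alpha"] = out_s2_a,
      _["mu_beta"] = out_mu_b, _["sigma2_beta"] = out_s2_b,
      _["z"] = outZ, _["n_store"] = stored);
}
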