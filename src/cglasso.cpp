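// Complex-valued graphical lasso and support-constrained ML refit.
//
// The penalized problem is
//   min_{Phi Hermitian PD}  -log det Phi + tr(Theta Phi) + sum_{j!=k} P_jk |Phi_jk|
// with |.| the complex modulus and the diagonal unpenalized (the penalty
// runs over both triangles, so max_{j<k}|Theta_jk| is exactly the smallest
// flat penalty that zeroes every edge).  Solved by block
// coordinate descent on the covariance estimate W = Phi^{-1} (the classic
// graphical-lasso scheme), where each column update is an L1-penalized
// complex regression solved by coordinate descent with a modulus
// soft-threshold.  The refit solves the same likelihood with exact zero
// constraints off a given support (column updates become exact linear solves
// restricted to the support), which is the standard covariance-selection
// algorithm.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline cx_double csoft(const cx_double r, const double t) {
  double m = std::abs(r);
  if (m <= t) return cx_double(0.0, 0.0);
  return r * ((m - t) / m);
}

// Reassemble Phi from the covariance iterate W and the regression
// coefficients B (column j of B holds beta_j in the rows != j).
static cx_mat phi_from_WB(const cx_mat& W, const cx_mat& B) {
  const uword n = W.n_rows;
  cx_mat Phi(n, n, fill::zeros);
  for (uword j = 0; j < n; ++j) {
    cx_double q(0.0, 0.0);
    for (uword k = 0; k < n; ++k)
      if (k != j) q += std::conj(W(k, j)) * B(k, j);
    double denom = W(j, j).real() - q.real();
    if (denom <= 0) denom = 1e-12;
    double pjj = 1.0 / denom;
    Phi(j, j) = cx_double(pjj, 0.0);
    for (uword k = 0; k < n; ++k)
      if (k != j) Phi(k, j) = -B(k, j) * pjj;
  }
  Phi = 0.5 * (Phi + Phi.t());  // .t() is conjugate transpose
  return Phi;
}

static double obj_value(const cx_mat& Phi, const cx_mat& Theta, const mat& P) {
  cx_double ld;
  double sign;
  log_det(ld, sign, Phi);
  double tr = real(accu(Theta % strans(Phi)));
  double pen = 0.0;
  const uword n = Phi.n_rows;
  for (uword j = 0; j < n; ++j)
    for (uword k = j + 1; k < n; ++k)
      pen += 2.0 * P(j, k) * std::abs(Phi(j, k));  // both triangles
  return -ld.real() + tr + pen;
}

// [[Rcpp::export]]
Rcpp::List cglasso_cpp(const arma::cx_mat& Theta, const arma::mat& P,
                       double tol, int max_iter,
                       const arma::cx_mat& W0, const arma::cx_mat& B0,
                       bool warm) {
  const uword n = Theta.n_rows;
  cx_mat W, B;
  if (warm) {
    W = W0; B = B0;
    W.diag() = Theta.diag();  // diagonal is fixed by the unpenalized KKT
  } else {
    W = Theta;
    B.zeros(n, n);
  }

  const double inner_tol = 1e-8 * (1.0 + std::abs(Theta.max()));
  const int inner_max = 200;

  double obj_prev = datum::inf;
  double obj = obj_value(phi_from_WB(W, B), Theta, P);
  int it = 0;
  bool converged = false;

  std::vector<uword> active;
  active.reserve(n);
  for (it = 1; it <= max_iter; ++it) {
    for (uword j = 0; j < n; ++j) {
      // coordinate-descent lasso for column j with an active-set strategy:
      // full passes collect the working set, then cheap passes iterate on
      // the nonzero coordinates only until stable.
      auto coord_update = [&](uword k) {
        // residual r = Theta_kj - sum_{l != k,j} W_kl * beta_lj
        cx_double r = Theta(k, j);
        for (uword l = 0; l < n; ++l) {
          if (l == j || l == k) continue;
          r -= W(k, l) * B(l, j);
        }
        double wkk = W(k, k).real();
        if (wkk <= 0) wkk = 1e-12;
        cx_double bnew = csoft(r, P(k, j)) / wkk;
        double d = std::abs(bnew - B(k, j));
        B(k, j) = bnew;
        return d;
      };
      for (int pass = 0; pass < inner_max; ++pass) {
        double max_delta = 0.0;
        active.clear();
        for (uword k = 0; k < n; ++k) {
          if (k == j) continue;
          max_delta = std::max(max_delta, coord_update(k));
          if (B(k, j) != cx_double(0.0, 0.0)) active.push_back(k);
        }
        if (max_delta < inner_tol) break;
        for (int ap = 0; ap < inner_max; ++ap) {
          double mda = 0.0;
          for (uword k : active) mda = std::max(mda, coord_update(k));
          if (mda < inner_tol) break;
        }
      }
      // w12 = W11 * beta
      for (uword k = 0; k < n; ++k) {
        if (k == j) continue;
        cx_double s(0.0, 0.0);
        for (uword l = 0; l < n; ++l) {
          if (l == j) continue;
          s += W(k, l) * B(l, j);
        }
        W(k, j) = s;
        W(j, k) = std::conj(s);
      }
    }
    cx_mat Phi = phi_from_WB(W, B);
    obj = obj_value(Phi, Theta, P);
    if (std::abs(obj_prev - obj) < tol) { converged = true; break; }
    obj_prev = obj;
  }

  cx_mat Phi = phi_from_WB(W, B);
  return Rcpp::List::create(
      Rcpp::Named("Phi") = Phi, Rcpp::Named("W") = W, Rcpp::Named("B") = B,
      Rcpp::Named("niter") = it, Rcpp::Named("converged") = converged,
      Rcpp::Named("objective") = obj,
      Rcpp::Named("gap") = std::abs(obj_prev - obj));
}

// Support-constrained ML refit: min -log det Phi + tr(ThetaD Phi) subject to
// Phi_jk = 0 (j != k) off the support.  Classic covariance-selection block
// algorithm: starting from W = ThetaD, each column update solves the
// regression restricted to the support exactly; stops when the objective
// decrease falls below tol.  Warm-startable from a previous (W, B) pair.
// [[Rcpp::export]]
Rcpp::List refit_cpp(const arma::cx_mat& ThetaD, const arma::umat& S,
                     double tol, int max_iter,
                     const arma::cx_mat& W0, const arma::cx_mat& B0,
                     bool warm) {
  const uword n = ThetaD.n_rows;
  const mat Pzero(n, n, fill::zeros);

  // complete support: unconstrained MLE, no iteration needed
  uword m_on = 0;
  for (uword j = 0; j < n; ++j)
    for (uword k = j + 1; k < n; ++k) if (S(j, k)) ++m_on;
  if (m_on == n * (n - 1) / 2) {
    cx_mat Phi = inv_sympd(ThetaD);
    return Rcpp::List::create(Rcpp::Named("Phi") = Phi,
                              Rcpp::Named("W") = ThetaD,
                              Rcpp::Named("B") = cx_mat(n, n, fill::zeros),
                              Rcpp::Named("niter") = 0,
                              Rcpp::Named("converged") = true);
  }

  cx_mat W, B;
  if (warm) {
    W = W0; B = B0;
    W.diag() = ThetaD.diag();
  } else {
    W = ThetaD;
    B.zeros(n, n);
  }

  std::vector<uvec> supp(n);
  for (uword j = 0; j < n; ++j) {
    uvec idx = find(S.col(j));
    supp[j] = idx(find(idx != j));
  }

  double obj_prev = datum::inf;
  double obj = datum::inf;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= max_iter; ++it) {
    for (uword j = 0; j < n; ++j) {
      const uvec& idx = supp[j];
      B.col(j).zeros();
      if (idx.n_elem > 0) {
        cx_mat W11 = W(idx, idx);
        cx_vec s12 = ThetaD.col(j);
        cx_vec beta;
        bool ok = solve(beta, W11, cx_vec(s12(idx)),
                        solve_opts::likely_sympd + solve_opts::no_approx);
        if (!ok) beta = pinv(W11) * cx_vec(s12(idx));
        for (uword t = 0; t < idx.n_elem; ++t) B(idx(t), j) = beta(t);
      }
      for (uword k = 0; k < n; ++k) {
        if (k == j) continue;
        cx_double s(0.0, 0.0);
        for (uword t = 0; t < idx.n_elem; ++t) s += W(k, idx(t)) * B(idx(t), j);
        W(k, j) = s;
        W(j, k) = std::conj(s);
      }
    }
    obj = obj_value(phi_from_WB(W, B), ThetaD, Pzero);
    if (std::abs(obj_prev - obj) < tol) { converged = true; break; }
    obj_prev = obj;
  }

  cx_mat Phi = phi_from_WB(W, B);
  for (uword j = 0; j < n; ++j)
    for (uword k = 0; k < n; ++k)
      if (k != j && S(k, j) == 0) Phi(k, j) = cx_double(0.0, 0.0);
  return Rcpp::List::create(Rcpp::Named("Phi") = Phi, Rcpp::Named("W") = W,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("niter") = it,
                            Rcpp::Named("converged") = converged);
}

// [[Rcpp::export]]
double deviance_cpp(const arma::cx_mat& Phi, const arma::cx_mat& Theta) {
  cx_double ld;
  double sign;
  log_det(ld, sign, Phi);
  return -ld.real() + real(accu(Theta % strans(Phi)));
}

// Full cross-validation grid: for each ensemble i and each (lambda1, lambda2)
// pair, fit the penalized problem on Theta_i (warm-started along the grid),
// extract the support, refit, and accumulate the held-out deviance against
// the other ensembles.  Returns the G1 x G2 total-deviance table.
// [[Rcpp::export]]
arma::mat cv_grid_cpp(const Rcpp::List& thetas, const arma::mat& mask,
                      const arma::vec& lam1, const arma::vec& lam2,
                      double tol, int max_iter, double zero_tol,
                      double delta_factor) {
  const int K = thetas.size();
  const int G1 = lam1.n_elem, G2 = lam2.n_elem;
  mat dev(G1, G2, fill::zeros);

  std::vector<cx_mat> Th(K);
  for (int i = 0; i < K; ++i) Th[i] = Rcpp::as<cx_mat>(thetas[i]);
  const uword n = Th[0].n_rows;

  mat offd = ones<mat>(n, n) - eye<mat>(n, n);
  mat Pon = mask % offd;          // constraint edges
  mat Poff = (1.0 - mask) % offd; // off-constraint

  for (int i = 0; i < K; ++i) {
    // ridge loading for the refit
    double mx = 0.0;
    for (uword a = 0; a < n; ++a)
      for (uword b = a + 1; b < n; ++b)
        mx = std::max(mx, std::abs(Th[i](a, b)));
    cx_mat ThD = Th[i] + delta_factor * mx * eye<cx_mat>(n, n);

    cx_mat Wws, Bws, rWws, rBws;      // warm starts carried along the grid
    bool have_ws = false;
    for (int g2 = G2 - 1; g2 >= 0; --g2) {   // large lambda2 first
      cx_mat Wrow, Brow, rWrow, rBrow;
      bool have_row = false;
      for (int g1 = G1 - 1; g1 >= 0; --g1) { // large lambda1 first
        mat P = lam1(g1) * Pon + lam2(g2) * Poff;
        cx_mat W0, B0, rW0, rB0;
        bool warm = false;
        if (have_row) { W0 = Wrow; B0 = Brow; rW0 = rWrow; rB0 = rBrow; warm = true; }
        else if (have_ws) { W0 = Wws; B0 = Bws; rW0 = rWws; rB0 = rBws; warm = true; }
        else {
          W0.zeros(n, n); B0.zeros(n, n);
          rW0.zeros(n, n); rB0.zeros(n, n);
        }
        Rcpp::List fit = cglasso_cpp(Th[i], P, tol, max_iter, W0, B0, warm);
        cx_mat Phi = Rcpp::as<cx_mat>(fit["Phi"]);
        Wrow = Rcpp::as<cx_mat>(fit["W"]);
        Brow = Rcpp::as<cx_mat>(fit["B"]);
        // support
        double mo = 0.0;
        for (uword a = 0; a < n; ++a)
          for (uword b = a + 1; b < n; ++b)
            mo = std::max(mo, std::abs(Phi(a, b)));
        umat S(n, n, fill::zeros);
        if (mo > 0) {
          for (uword a = 0; a < n; ++a)
            for (uword b = a + 1; b < n; ++b)
              if (std::abs(Phi(a, b)) > zero_tol * mo) { S(a, b) = 1; S(b, a) = 1; }
        }
        Rcpp::List rf = refit_cpp(ThD, S, tol, max_iter, rW0, rB0, warm);
        cx_mat Phit = Rcpp::as<cx_mat>(rf["Phi"]);
        rWrow = Rcpp::as<cx_mat>(rf["W"]);
        rBrow = Rcpp::as<cx_mat>(rf["B"]);
        have_row = true;
        if (g1 == G1 - 1) {
          Wws = Wrow; Bws = Brow; rWws = rWrow; rBws = rBrow; have_ws = true;
        }
        for (int j = 0; j < K; ++j)
          if (j != i) dev(g1, g2) += deviance_cpp(Phit, Th[j]);
      }
    }
  }
  return dev;
}

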