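// Solver core: proximal operators and the multi-block ADMM for the
// penalized conditional Gaussian likelihood. Small dense problems only;
// full eigen/SVD factorizations are affordable at the intended scale.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Elementwise soft threshold; mask entries equal to 1 are left unpenalized.
// [[Rcpp::export(name = ".prox_l1_cpp")]]
arma::mat prox_l1_cpp(const arma::mat& M, double t,
                      Rcpp::Nullable<Rcpp::NumericMatrix> mask = R_NilValue) {
  if (t < 0) Rcpp::stop("threshold t must be nonnegative");
  mat out = sign(M) % clamp(abs(M) - t, 0.0, datum::inf);
  if (mask.isNotNull()) {
    mat mk = Rcpp::as<mat>(mask.get());
    if (mk.n_rows != M.n_rows || mk.n_cols != M.n_cols)
      Rcpp::stop("mask dimensions do not match");
    out = out % (1 - mk) + M % mk;
  }
  return out;
}

// [[Rcpp::export(name = ".svt_cpp")]]
arma::mat svt_cpp(const arma::mat& M, double t) {
  if (t < 0) Rcpp::stop("threshold t must be nonnegative");
  if (t == 0) return M;
  mat U, V; vec s;
  svd_econ(U, s, V, M);
  vec st = clamp(s - t, 0.0, datum::inf);
  return U * diagmat(st) * V.t();
}

// Symmetrize then clip eigenvalues at `floor`.
// [[Rcpp::export(name = ".project_psd_cpp")]]
arma::mat project_psd_cpp(const arma::mat& M, double floor_ev = 0.0) {
  mat A = symmatu((M + M.t()) / 2);
  vec ev; mat V;
  eig_sym(ev, V, A);
  ev = clamp(ev, floor_ev, datum::inf);
  return V * diagmat(ev) * V.t();
}

// Projection onto {L : top p x p block symmetric PSD}; bottom block free.
static mat proj_top_psd(const mat& M, unsigned int p) {
  if (p == 0) return M;
  mat out = M;
  out.rows(0, p - 1) = project_psd_cpp(M.rows(0, p - 1), 0.0);
  return out;
}

// Dykstra core for the constrained nuclear prox; iteration count and final
// residual are returned through the output arguments.
static mat dykstra_nuc_psd(const mat& M, double t, int p, double tol,
                           int max_iter, int& iters, double& resid_out) {
  mat M0 = M;
  if (p > 0) {
    mat top = M0.rows(0, p - 1);
    M0.rows(0, p - 1) = (top + top.t()) / 2; // symmetrize on entry
  }
  double scale = std::max(1.0, norm(M0, "fro"));
  mat x = M0, pc(size(M0), fill::zeros), qc(size(M0), fill::zeros);
  double resid = datum::inf;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    mat y = svt_cpp(x + pc, t);
    pc = x + pc - y;
    mat xn = proj_top_psd(y + qc, p);
    qc = y + qc - xn;
    resid = norm(xn - y, "fro") / scale;
    x = xn;
    if (resid <= tol) break;
  }
  iters = std::min(it, max_iter);
  resid_out = resid;
  return x;
}

// Proximal operator of t * ||.||_* over stacked (p+m) x p matrices subject
// to a symmetric PSD top block, by Dykstra's algorithm alternating the
// unconstrained singular-value shrinkage with the cone projection.
// [[Rcpp::export(name = ".prox_nuc_psd_cpp")]]
Rcpp::List prox_nuc_psd_cpp(const arma::mat& M, double t, int p,
                            double tol = 1e-8, int max_iter = 100) {
  if (t < 0) Rcpp::stop("threshold t must be nonnegative");
  if (p < 0 || (unsigned)p > M.n_rows) Rcpp::stop("invalid top-block size p");
  if (p > 0 && (unsigned)p != M.n_cols)
    Rcpp::stop("constrained prox needs a (p+m) x p matrix: ncol(M) must equal p");
  int iters = 0; double resid = datum::inf;
  mat x = dykstra_nuc_psd(M, t, p, tol, max_iter, iters, resid);
  return Rcpp::List::create(
    Rcpp::Named("argmin") = x,
    Rcpp::Named("inner_iterations") = iters,
    Rcpp::Named("inner_residual") = resid,
    Rcpp::Named("converged") = resid <= tol);
}

// Scalar solve of rho * r - 1 / r = b, r > 0 (eigenwise logdet prox).
static vec logdet_prox_eigs(const vec& b, double rho) {
  return (b + sqrt(square(b) + 4.0 * rho)) / (2.0 * rho);
}

struct LikTerms {
  double loglik;
  mat g_RX;   // d(-loglik)/dR_X (symmetric)
  mat g_RZX;  // d(-loglik)/dR_ZX
};

// Negative average log-likelihood and its gradient at (R_X, R_ZX).
static LikTerms neg_loglik(const mat& RX, const mat& RZX,
                           const mat& SigZ, const mat& SigX, const mat& SigZX) {
  LikTerms out;
  vec evl; mat evv;
  eig_sym(evl, evv, symmatu(RX));
  evl = clamp(evl, 1e-12, datum::inf);
  mat C = evv * diagmat(1.0 / evl) * evv.t();
  double ld; double sgn;
  log_det(ld, sgn, symmatu(RX));
  double ll = ld - accu(SigX % RX);
  if (RZX.n_rows > 0) {
    mat SzR = SigZ * RZX;
    mat Q = RZX.t() * SzR;
    ll += -2.0 * accu(SigZX % RZX) - accu(C % Q);
    out.g_RX = symmatu(-(C - SigX + C * Q * C));
    out.g_RZX = 2.0 * SigZX + 2.0 * SzR * C;
  } else {
    out.g_RX = symmatu(-(C - SigX));
    out.g_RZX = mat(0, RX.n_cols);
  }
  out.loglik = ll;
  return out;
}

// Value of the likelihood subproblem phi(R) = -loglik(R) + (rho/2)||R - A||^2
// (+inf outside the PD domain).
static double r_phi(const mat& RX, const mat& RZX, const mat& AX,
                    const mat& AZX, const mat& SigZ, const mat& SigX,
                    const mat& SigZX, double rho) {
  vec ev; mat V;
  eig_sym(ev, V, symmatu(RX));
  if (ev.min() <= 1e-12) return datum::inf;
  double val = -accu(log(ev)) + accu(SigX % RX);
  if (RZX.n_rows > 0) {
    mat C = V * diagmat(1.0 / ev) * V.t();
    mat Q = RZX.t() * (SigZ * RZX);
    val += 2.0 * accu(SigZX % RZX) + accu(C % Q);
  }
  val += 0.5 * rho * (accu(square(RX - AX)) + accu(square(RZX - AZX)));
  return val;
}

// Solve of min_R -loglik(R) + (rho/2) ||R - A||_F^2. The fast path
// alternates closed-form eigens (Sylvester-diagonalized R_ZX step, then a
// logdet-prox R_X step with the Schur-type quartic term frozen); sweeps
// are accepted only while they decrease the subproblem objective. When a
// sweep fails to decrease it, the solve falls back to backtracking
// gradient descent, which is guaranteed to converge (smooth + strongly
// convex).
static void r_update(mat& RX, mat& RZX, const mat& AX, const mat& AZX,
                     const mat& SigZ, const mat& SigX, const mat& SigZX,
                     const mat& Uz, const vec& dz, double rho,
                     int sweeps, double tol) {
  unsigned int m = AZX.n_rows;
  unsigned int p = RX.n_cols;
  double phi_cur = r_phi(RX, RZX, AX, AZX, SigZ, SigX, SigZX, rho);
  bool need_fallback = false;
  for (int s = 0; s < sweeps; ++s) {
    mat RX_old = RX, RZX_old = RZX;
    vec lam; mat V;
    if (m > 0) {
      eig_sym(lam, V, symmatu(RX));
      lam = clamp(lam, 1e-10, datum::inf);
      mat G = rho * AZX - 2.0 * SigZX;
      mat Gt = Uz.t() * G * V;
      mat T(m, p);
      for (unsigned int i = 0; i < m; ++i)
        for (unsigned int j = 0; j < p; ++j)
          T(i, j) = Gt(i, j) / (2.0 * dz(i) / lam(j) + rho);
      RZX = Uz * T * V.t();
    }
    mat B = rho * AX - SigX;
    if (m > 0) {
      mat C = V * diagmat(1.0 / lam) * V.t();
      mat Q = RZX.t() * (SigZ * RZX);
      B += C * Q * C;
    }
    B = symmatu((B + B.t()) / 2);
    vec b; mat W;
    eig_sym(b, W, B);
    RX = symmatu(W * diagmat(logdet_prox_eigs(b, rho)) * W.t());
    double phi_new = r_phi(RX, RZX, AX, AZX, SigZ, SigX, SigZX, rho);
    if (!(phi_new <= phi_cur + 1e-12 * std::abs(phi_cur))) {
      RX = RX_old; RZX = RZX_old;          // reject the sweep
      need_fallback = true;
      break;
    }
    double ch = norm(RX - RX_old, "fro") + (m > 0 ? norm(RZX - RZX_old, "fro") : 0.0);
    phi_cur = phi_new;
    if (ch <= tol * std::max(1.0, norm(RX, "fro"))) break;
    if (m == 0) break; // exact in one step
  }
  if (!need_fallback) return;
  // Armijo backtracking gradient descent on phi
  double step = 1.0 / rho;
  for (int it = 0; it < 80; ++it) {
    LikTerms lt = neg_loglik(RX, RZX, SigZ, SigX, SigZX);
    mat gX = lt.g_RX + rho * (RX - AX);
    mat gZX = m > 0 ? mat(lt.g_RZX + rho * (RZX - AZX)) : mat(0, p);
    double gn2 = accu(square(gX)) + accu(square(gZX));
    if (std::sqrt(gn2) <= tol * (1.0 + rho * (norm(AX, "fro") + 1.0))) break;
    bool accepted = false;
    for (int bt = 0; bt < 40; ++bt) {
      mat RXn = symmatu(RX - step * gX);
      mat RZXn = m > 0 ? mat(RZX - step * gZX) : RZX;
      double phin = r_phi(RXn, RZXn, AX, AZX, SigZ, SigX, SigZX, rho);
      if (phin <= phi_cur - 1e-4 * step * gn2) {
        RX = RXn; RZX = RZXn; phi_cur = phin;
        accepted = true;
        break;
      }
      step /= 2.0;
    }
    if (!accepted) break;
    step = std::min(step * 1.5, 10.0 / rho);
  }
}

// Full ADMM fit. Sigma blocks are the sufficient statistics; lambda/gamma
// use the bounded parameterization; fix_L_zero freezes the low-rank block
// (sparse-only estimators). Returns matrices plus convergence diagnostics.
// [[Rcpp::export(name = ".admm_fit_cpp")]]
Rcpp::List admm_fit_cpp(const arma::mat& SigZ, const arma::mat& SigX,
                        const arma::mat& SigZX,
                        double lambda, double gamma,
                        double rho, bool adaptive_rho,
                        double tol_primal, double tol_dual,
                        int max_iter, double inner_tol, int inner_sweeps,
                        int prox_max_iter, double pd_floor,
                        bool fix_L_zero, bool penalize_diagonal,
                        Rcpp::Nullable<Rcpp::List> warm = R_NilValue) {
  unsigned int p = SigX.n_cols, m = SigZ.n_cols;
  unsigned int q = p + m;
  mat Uz; vec dz;
  if (m > 0) eig_sym(dz, Uz, symmatu(SigZ));
  if (m > 0) dz = clamp(dz, 0.0, datum::inf);

  // stacked variables: rows 0..p-1 are the X block, p..q-1 the ZX block
  mat S(q, p, fill::zeros), L(q, p, fill::zeros), U(q, p, fill::zeros);
  S.rows(0, p - 1) = eye(p, p);
  mat RX = eye(p, p), RZX(m, p, fill::zeros);
  if (warm.isNotNull()) {
    Rcpp::List w(warm.get());
    S = Rcpp::as<mat>(w["S"]);
    L = Rcpp::as<mat>(w["L"]);
    if (w.containsElementNamed("U")) U = Rcpp::as<mat>(w["U"]);
    mat R0 = S - L;
    RX = symmatu(R0.rows(0, p - 1));
    vec ev; mat V;
    eig_sym(ev, V, RX);
    if (ev.min() < pd_floor)
      RX = V * diagmat(clamp(ev, pd_floor, datum::inf)) * V.t();
    if (m > 0) RZX = R0.rows(p, q - 1);
  }

  mat diag_mask(q, p, fill::zeros); // entries exempt from the l1 penalty
  if (!penalize_diagonal) diag_mask.rows(0, p - 1) = eye(p, p);
  Rcpp::Nullable<Rcpp::NumericMatrix> l1_mask = R_NilValue;
  if (!penalize_diagonal)
    l1_mask = Rcpp::Nullable<Rcpp::NumericMatrix>(Rcpp::wrap(diag_mask));

  std::vector<double> pri_hist, dua_hist, obj_hist;
  double last_rel = 1.0;  // relative primal residual of the previous iteration
  std::vector<int> prox_iters;
  bool converged = false;
  int iter = 0;
  double rho_cur = rho;
  for (iter = 1; iter <= max_iter; ++iter) {
    mat SmL = S - L;
    mat AX = SmL.rows(0, p - 1) - U.rows(0, p - 1);
    mat AZX = m > 0 ? mat(SmL.rows(p, q - 1) - U.rows(p, q - 1)) : mat(0, p);
    // subproblem accuracy follows the outer progress (inexact ADMM)
    double r_tol = std::max(inner_tol, std::min(1e-4, 0.01 * last_rel));
    r_update(RX, RZX, AX, AZX, SigZ, SigX, SigZX, Uz, dz, rho_cur,
             inner_sweeps, r_tol);
    mat R(q, p);
    R.rows(0, p - 1) = RX;
    if (m > 0) R.rows(p, q - 1) = RZX;

    mat SmL_prev = S - L;
    // joint (S, L) subproblem: min over both of the penalties plus
    // (rho/2) ||R - S + L + U||^2, by block-coordinate passes (the
    // quadratic couples the blocks; iterating to a joint minimizer keeps
    // the scheme a genuine two-block ADMM)
    mat RU = R + U;
    // prox accuracy follows the outer progress: roughly two orders of
    // magnitude below the current relative primal residual
    double dyk_tol = std::max(1e-10, std::min(1e-3, 0.01 * last_rel));
    double pass_tol = std::max(1e-9, std::min(1e-2, 0.1 * last_rel));
    for (int pass = 0; pass < 10; ++pass) {
      mat S_old = S, L_old = L;
      S = prox_l1_cpp(RU + L, lambda * gamma / rho_cur, l1_mask);
      S.rows(0, p - 1) = (S.rows(0, p - 1) + S.rows(0, p - 1).t()) / 2;
      if (!fix_L_zero) {
        int pi = 0; double pres = 0;
        L = dykstra_nuc_psd(S - RU, lambda * (1.0 - gamma) / rho_cur,
                            p, dyk_tol, prox_max_iter, pi, pres);
        if (pass == 0) prox_iters.push_back(pi);
      }
      double ch = norm(S - S_old, "fro") + norm(L - L_old, "fro");
      if (fix_L_zero || ch <= pass_tol * std::max(1.0, norm(S, "fro"))) break;
    }
    mat r_pri = R - S + L;
    mat s_dua = rho_cur * ((S - L) - SmL_prev);
    U += r_pri;

    double nr = norm(r_pri, "fro"), ns = norm(s_dua, "fro");
    double eps_pri = 1e-10 + tol_primal *
      std::max(norm(R, "fro"), norm(S - L, "fro"));
    last_rel = nr / std::max(1.0, std::max(norm(R, "fro"), norm(S - L, "fro")));
    double eps_dua = 1e-10 + tol_dual * rho_cur * norm(U, "fro");
    pri_hist.push_back(nr);
    dua_hist.push_back(ns);

    // objective trace at the (S, L) iterate, when feasible
    {
      mat RXc = symmatu(S.rows(0, p - 1) - L.rows(0, p - 1));
      vec ev = eig_sym(RXc);
      if (ev.min() > 1e-10) {
        mat RZXc = m > 0 ? mat(S.rows(p, q - 1) - L.rows(p, q - 1)) : mat(0, p);
        LikTerms lt = neg_loglik(RXc, RZXc, SigZ, SigX, SigZX);
        double pen = lambda * gamma *
          (penalize_diagonal ? accu(abs(S)) : accu(abs(S % (1 - diag_mask))));
        vec sv = svd(L);
        obj_hist.push_back(-lt.loglik + pen + lambda * (1 - gamma) * accu(sv));
      } else obj_hist.push_back(NA_REAL);
    }

    if (nr <= eps_pri && ns <= eps_dua) { converged = true; break; }
    // residual balancing, throttled: every 5 iterations, bounded range
    if (adaptive_rho && iter < 200 && iter % 5 == 0) {
      if (nr > 10.0 * ns && rho_cur < 1e4) { rho_cur *= 2.0; U /= 2.0; }
      else if (ns > 10.0 * nr && rho_cur > 1e-2) { rho_cur /= 2.0; U *= 2.0; }
    }
  }
  if (iter > max_iter) iter = max_iter;

  // final feasibility: L_X is PSD by construction; nudge S_X if needed
  mat SX = S.rows(0, p - 1), LX = L.rows(0, p - 1);
  vec ev = eig_sym(symmatu(SX - LX));
  if (ev.min() < pd_floor) SX += (pd_floor - ev.min()) * eye(p, p);

  return Rcpp::List::create(
    Rcpp::Named("S_X") = SX,
    Rcpp::Named("L_X") = LX,
    Rcpp::Named("S_ZX") = m > 0 ? mat(S.rows(p, q - 1)) : mat(0, p),
    Rcpp::Named("L_ZX") = m > 0 ? mat(L.rows(p, q - 1)) : mat(0, p),
    Rcpp::Named("S") = S, Rcpp::Named("L") = L, Rcpp::Named("U") = U,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("primal_residuals") = pri_hist,
    Rcpp::Named("dual_residuals") = dua_hist,
    Rcpp::Named("objective_trace") = obj_hist,
    Rcpp::Named("prox_inner_iterations") = prox_iters,
    Rcpp::Named("rho_final") = rho_cur);
}
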