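// ADMM core for sparse group multi-task logistic regression.
//
// The smooth sub-problem (ridge-penalised logistic regression towards an
// anchor) is solved by damped Newton steps.  The Hessian factorisation is
// refreshed lazily: along the ADMM iterations the iterate drifts slowly, so
// a factor computed at a recent point keeps near-quadratic convergence and
// one factorisation serves many updates.  When n_k < p the factorisation is
// held in Woodbury form (an n_k x n_k Cholesky) instead of p x p.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double log1pexp_stable(double z) {
  // overflow-safe log(1 + exp(z))
  if (z > 0.0) return z + std::log1p(std::exp(-z));
  return std::log1p(std::exp(z));
}

// negative log-likelihood of one study at linear predictor eta
static double nll_eta(const vec& eta, const vec& y) {
  double s = 0.0;
  for (uword i = 0; i < eta.n_elem; ++i)
    s += log1pexp_stable(eta[i]) - y[i] * eta[i];
  return s;
}

// [[Rcpp::export(name = "cpp_nll")]]
double cpp_nll(const Rcpp::List& Xs, const Rcpp::List& ys,
               const arma::mat& B) {
  double s = 0.0;
  for (int k = 0; k < Xs.size(); ++k) {
    mat X = Rcpp::as<mat>(Xs[k]);
    vec y = Rcpp::as<vec>(ys[k]);
    s += nll_eta(X * B.col(k), y);
  }
  return s;
}

// [[Rcpp::export(name = "cpp_nll_grad")]]
arma::mat cpp_nll_grad(const Rcpp::List& Xs, const Rcpp::List& ys,
                       const arma::mat& B) {
  mat G(B.n_rows, B.n_cols);
  for (int k = 0; k < Xs.size(); ++k) {
    mat X = Rcpp::as<mat>(Xs[k]);
    vec y = Rcpp::as<vec>(ys[k]);
    vec p = 1.0 / (1.0 + exp(-(X * B.col(k))));
    G.col(k) = X.t() * (p - y);
  }
  return G;
}

// Solver for min_b  sum_i log(1+exp(x_i'b)) - y_i x_i'b + (rho/2)||b - a||^2
class RidgeLogisticSolver {
 public:
  RidgeLogisticSolver(const mat& X_, const vec& y_)
      : X(X_), y(y_), n(X_.n_rows), p(X_.n_cols), have_fac(false),
        wood(false), rho_fac(-1.0) {}

  // gradient-norm tolerance `tol`; returns iterations used
  long n_inner = 0, n_refresh = 0, n_ls = 0;

  int solve(vec& b, const vec& a, double rho, double tol, int maxit,
            bool& hit_cap) {
    if (!have_fac || rho != rho_fac) refresh(b, rho);
    int since_refresh = 0;
    int it = 0;
    hit_cap = false;
    vec eta = X * b;
    for (; it < maxit; ++it) {
      vec pr = 1.0 / (1.0 + exp(-eta));
      vec g = X.t() * (pr - y) + rho * (b - a);
      if (norm(g, 2) <= tol) break;
      if (since_refresh >= 10) {
        refresh(b, rho);
        since_refresh = 0;
      }
      vec d = hsolve(g);
      double f0 = nll_eta(eta, y) + 0.5 * rho * dot(b - a, b - a);
      double gd = dot(g, d);  // > 0: d is a descent direction (H p.d.)
      double t = 1.0;
      vec eta_d = X * d;
      if (gd <= 1e-12 * (std::abs(f0) + 1.0)) {
        // predicted decrease is below the floating-point noise floor of f;
        // take the bare Newton step, which is safe this close to the optimum
        b -= d;
        eta -= eta_d;
        ++since_refresh;
        ++n_inner;
        continue;
      }
      int ls = 0;
      for (; ls < 40; ++ls) {
        vec eta_t = eta - t * eta_d;
        vec bt = b - t * d;
        double ft = nll_eta(eta_t, y) + 0.5 * rho * dot(bt - a, bt - a);
        if (ft <= f0 - 1e-4 * t * gd) break;
        t *= 0.5;
      }
      if (ls >= 40) {  // stale factor; refresh and retry
        refresh(b, rho);
        since_refresh = 0;
        continue;
      }
      b -= t * d;
      eta -= t * eta_d;
      ++since_refresh;
      ++n_inner;
      n_ls += ls;
    }
    hit_cap = (it >= maxit);
    return it;
  }

 public:
  void refresh(const vec& b, double rho) {
    ++n_refresh;
    vec pr = 1.0 / (1.0 + exp(-(X * b)));
    vec w = pr % (1.0 - pr);
    if (n < p) {
      Xw = X.each_col() % sqrt(w);
      mat M = Xw * Xw.t();
      M.diag() += rho;
      fac = chol(M);
      wood = true;
    } else {
      mat H = X.t() * (X.each_col() % w);
      H.diag() += rho;
      fac = chol(H);
      wood = false;
    }
    have_fac = true;
    rho_fac = rho;
  }

  vec hsolve(const vec& g) const {
    if (wood) {
      vec u = Xw * g;
      u = arma::solve(trimatu(fac), arma::solve(trimatl(fac.t()), u));
      return (g - Xw.t() * u) / rho_fac;
    }
    return arma::solve(trimatu(fac), arma::solve(trimatl(fac.t()), g));
  }

  const mat X;
  const vec y;
  uword n, p;
  bool have_fac, wood;
  double rho_fac;
  mat fac, Xw;
};

// sequential sparse-group prox applied in place:
// rows first (threshold thr_row[j]), then group blocks (threshold
// thr_grp[g]).  grp is a 0-based group id per row.
static void prox_sgl(mat& Z, const uvec& grp, const vec& thr_row,
                     const vec& thr_grp) {
  const uword p = Z.n_rows;
  for (uword j = 0; j < p; ++j) {
    double t = thr_row[j];
    if (t <= 0.0) continue;
    double nrm = norm(Z.row(j), 2);
    if (nrm <= t) Z.row(j).zeros();
    else Z.row(j) *= (nrm - t) / nrm;
  }
  const uword G = thr_grp.n_elem;
  vec gss(G, fill::zeros);
  for (uword j = 0; j < p; ++j)
    gss[grp[j]] += dot(Z.row(j), Z.row(j));
  vec scale(G, fill::ones);
  for (uword g = 0; g < G; ++g) {
    double t = thr_grp[g];
    if (t <= 0.0) continue;
    double nrm = std::sqrt(gss[g]);
    scale[g] = (nrm <= t) ? 0.0 : (nrm - t) / nrm;
  }
  for (uword j = 0; j < p; ++j) {
    double s = scale[grp[j]];
    if (s == 0.0) Z.row(j).zeros();
    else if (s != 1.0) Z.row(j) *= s;
  }
}

// [[Rcpp::export(name = "cpp_prox_sgl")]]
arma::mat cpp_prox_sgl(const arma::mat& V, const arma::uvec& grp,
                       const arma::vec& thr_row, const arma::vec& thr_grp) {
  mat Z = V;
  prox_sgl(Z, grp, thr_row, thr_grp);
  return Z;
}

// [[Rcpp::export(name = "cpp_logistic_prox")]]
Rcpp::List cpp_logistic_prox(const arma::mat& X, const arma::vec& y,
                             const arma::vec& a, double rho,
                             const arma::vec& b0, double tol, int maxit) {
  RidgeLogisticSolver solver(X, y);
  vec b = b0;
  bool cap = false;
  int it = solver.solve(b, a, rho, tol, maxit, cap);
  return Rcpp::List::create(Rcpp::Named("b") = b,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("hit_cap") = cap);
}

// Full ADMM loop.  thr_row_base = kappa * lambda2, thr_grp_base = gamma *
// lambda1 (division by rho happens per iteration so rho adaptation stays
// correct).
// [[Rcpp::export(name = "cpp_admm")]]
Rcpp::List cpp_admm(const Rcpp::List& Xs, const Rcpp::List& ys,
                    const arma::uvec& grp, const arma::vec& thr_row_base,
                    const arma::vec& thr_grp_base, double rho,
                    double tol_primal, double tol_dual, int max_iter,
                    arma::mat B, arma::mat Z, arma::mat U, bool adapt_rho,
                    double inner_tol_floor, int inner_maxit,
                    double relax = 1.5) {
  const uword p = B.n_rows;
  const uword K = B.n_cols;
  const int nK = Xs.size();
  const double scale0 = std::sqrt((double)(p * K));

  std::vector<RidgeLogisticSolver> solvers;
  solvers.reserve(nK);
  for (int k = 0; k < nK; ++k)
    solvers.emplace_back(Rcpp::as<mat>(Xs[k]), Rcpp::as<vec>(ys[k]));

  std::vector<double> tr_primal, tr_dual, tr_rho;
  double r_norm = datum::inf, s_norm = datum::inf;
  bool converged = false, inner_cap_any = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // B-update: K independent ridge-logistic problems anchored at Z - U
    // loose while the consensus is far (inexact ADMM), tightening to the
    // floor as the primal residual shrinks
    double inner_tol = inner_tol_floor;
    if (std::isfinite(r_norm))
      inner_tol = std::max(inner_tol_floor, 0.1 * r_norm);
    for (int k = 0; k < nK; ++k) {
      vec a = Z.col(k) - U.col(k);
      vec b = B.col(k);
      bool cap = false;
      solvers[k].solve(b, a, rho, inner_tol, inner_maxit, cap);
      if (cap) inner_cap_any = true;
      B.col(k) = b;
    }

    // Z-update: sequential sparse-group prox of the (over-relaxed) B + U
    mat Z_old = Z;
    mat Bh = relax * B + (1.0 - relax) * Z_old;
    Z = Bh + U;
    prox_sgl(Z, grp, thr_row_base / rho, thr_grp_base / rho);

    // dual update
    U += Bh - Z;

    r_norm = norm(B - Z, "fro");
    s_norm = rho * norm(Z - Z_old, "fro");
    tr_primal.push_back(r_norm);
    tr_dual.push_back(s_norm);
    tr_rho.push_back(rho);

    double eps_pri = tol_primal * scale0 *
                     std::max(1.0, std::max(norm(B, "fro"), norm(Z, "fro")));
    double eps_dual = tol_dual * scale0 * std::max(1.0, rho * norm(U, "fro"));
    if (r_norm <= eps_pri && s_norm <= eps_dual) {
      converged = true;
      break;
    }

    if (adapt_rho) {
      double rho_new = rho;
      if (r_norm > 10.0 * s_norm) rho_new = rho * 2.0;
      else if (s_norm > 10.0 * r_norm) rho_new = rho / 2.0;
      if (rho_new != rho) {
        U *= rho / rho_new;  // keep the scaled dual consistent
        rho = rho_new;
      }
    }
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("B") = B, Rcpp::Named("Z") = Z, Rcpp::Named("U") = U,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("primal_residual") = r_norm,
      Rcpp::Named("dual_residual") = s_norm,
      Rcpp::Named("converged") = converged, Rcpp::Named("rho") = rho,
      Rcpp::Named("inner_hit_cap") = inner_cap_any,
      Rcpp::Named("n_inner") = (double)(solvers[0].n_inner + (nK > 1 ? solvers[1].n_inner : 0)),
      Rcpp::Named("n_refresh") = (double)(solvers[0].n_refresh + (nK > 1 ? solvers[1].n_refresh : 0)),
      Rcpp::Named("n_ls") = (double)(solvers[0].n_ls + (nK > 1 ? solvers[1].n_ls : 0)),
      Rcpp::Named("trace_primal") = tr_primal,
      Rcpp::Named("trace_dual") = tr_dual, Rcpp::Named("trace_rho") = tr_rho);
}
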