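// [[Rcpp::depends(RcppArmadillo)]]
#include "kernels.h"
#include <functional>
#include <map>
using namespace Rcpp;

// Ecological equilibrium by direct linear solve with iterative feasibility
// pruning: solve A N = K over the active set; while some N_i <= 0, drop the
// species with the most negative abundance (largest violation) and re-solve.
// Returns positive abundances for the surviving subset plus 1-based indices.
// status: 0 ok, 1 empty (no feasible positive subset), 2 singular.
// [[Rcpp::export]]
List cpp_equilibrium(const arma::mat& Z, double sigma, const arma::mat& B,
                     bool printed, int kind) {
  const int M = Z.n_rows;
  arma::mat A = interaction_matrix_cpp(Z, sigma, B, printed);
  arma::vec K = arma::exp(log_K_vec(Z, kind));
  arma::uvec act = arma::regspace<arma::uvec>(0, M - 1);
  int status = 0;
  arma::vec N;
  while (act.n_elem > 0) {
    arma::mat As = A.submat(act, act);
    arma::vec Ks = K.elem(act);
    bool ok = arma::solve(N, As, Ks, arma::solve_opts::no_approx);
    if (!ok) { status = 2; break; }
    if (N.min() > 0.0) break;
    act.shed_row(N.index_min());
  }
  if (act.n_elem == 0 && status == 0) status = 1;
  if (status != 0) N.reset();
  return List::create(_["N"] = N, _["keep"] = act + 1, _["status"] = status);
}

// dN/dt for Eq-4 logistic Lotka-Volterra competition
static inline arma::vec lv_rhs(const arma::vec& N, const arma::mat& A,
                               const arma::vec& K, double r) {
  return r * N % (1.0 - (A * N) / K);
}

// Cash-Karp RK45 with adaptive stepping and nonnegativity clamping.
// Saves the state at `nsave`+1 evenly spaced times (including t=0, t_end).
// [[Rcpp::export]]
List cpp_integrate_lv(const arma::mat& Z, const arma::vec& N0, double r,
                      double t_end, double sigma, const arma::mat& B,
                      bool printed, int kind, double rtol, double atol,
                      int nsave) {
  static const double c2 = 1.0/5, c3 = 3.0/10, c4 = 3.0/5, c5 = 1.0, c6 = 7.0/8;
  static const double a21 = 1.0/5;
  static const double a31 = 3.0/40, a32 = 9.0/40;
  static const double a41 = 3.0/10, a42 = -9.0/10, a43 = 6.0/5;
  static const double a51 = -11.0/54, a52 = 5.0/2, a53 = -70.0/27, a54 = 35.0/27;
  static const double a61 = 1631.0/55296, a62 = 175.0/512, a63 = 575.0/13824,
                      a64 = 44275.0/110592, a65 = 253.0/4096;
  static const double b1 = 37.0/378, b3 = 250.0/621, b4 = 125.0/594,
                      b6 = 512.0/1771;
  static const double d1 = 2825.0/27648, d3 = 18575.0/48384, d4 = 13525.0/55296,
                      d5 = 277.0/14336, d6 = 1.0/4;
  (void)c2; (void)c3; (void)c4; (void)c5; (void)c6;

  arma::mat A = interaction_matrix_cpp(Z, sigma, B, printed);
  arma::vec K = arma::exp(log_K_vec(Z, kind));
  arma::vec N = N0;
  const int M = N.n_elem;
  arma::vec times(nsave + 1);
  arma::mat traj(nsave + 1, M);
  times(0) = 0.0; traj.row(0) = N.t();

  double t = 0.0, h = std::min(1e-3 * t_end, 0.1);
  int isave = 1;
  double tnext = t_end / nsave;
  int guard = 0;
  while (t < t_end && ++guard < 10000000) {
    if (t + h > tnext) h = tnext - t;
    arma::vec k1 = lv_rhs(N, A, K, r);
    arma::vec k2 = lv_rhs(N + h * a21 * k1, A, K, r);
    arma::vec k3 = lv_rhs(N + h * (a31 * k1 + a32 * k2), A, K, r);
    arma::vec k4 = lv_rhs(N + h * (a41 * k1 + a42 * k2 + a43 * k3), A, K, r);
    arma::vec k5 = lv_rhs(N + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4), A, K, r);
    arma::vec k6 = lv_rhs(N + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5), A, K, r);
    arma::vec N5 = N + h * (b1 * k1 + b3 * k3 + b4 * k4 + b6 * k6);
    arma::vec N4 = N + h * (d1 * k1 + d3 * k3 + d4 * k4 + d5 * k5 + d6 * k6);
    double err = 0.0;
    for (int i = 0; i < M; ++i) {
      double sc = atol + rtol * std::max(std::abs(N(i)), std::abs(N5(i)));
      err = std::max(err, std::abs(N5(i) - N4(i)) / sc);
    }
    if (err <= 1.0) {
      t += h;
      N = arma::clamp(N5, 0.0, arma::datum::inf);
      if (t >= tnext - 1e-12) {
        times(isave) = t; traj.row(isave) = N.t();
        ++isave;
        tnext = t_end * (double)isave / nsave;
        if (isave > nsave) break;
      }
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    h *= std::min(5.0, std::max(0.2, fac));
    h = std::min(h, t_end);
    if (h < 1e-14 * t_end) stop("integrate_lv: step size underflow");
  }
  if (guard >= 10000000) stop("integrate_lv: step budget exhausted");
  return List::create(_["times"] = times.head(isave),
                      _["N"] = traj.head_rows(isave));
}

// Canonical-equation trait flow dz_i/dt = kappa * N_i* * g_i with
// re-equilibration of abundances at every stage evaluation.  Adaptive
// Heun (explicit trapezoid with embedded Euler error estimate); per-substep
// displacement capped at max_disp.  Species pruned by the equilibrium
// (infeasible along the way) are dropped and reported.
// [[Rcpp::export]]
List cpp_canonical_flow(const arma::mat& Z0, double sigma, const arma::mat& B,
                        bool printed, int kind, double kappa, double t_total,
                        double max_disp, double tol) {
  arma::mat Z = Z0;
  const int d = Z.n_cols;
  arma::uvec alive = arma::regspace<arma::uvec>(0, Z0.n_rows - 1);
  double t = 0.0;
  double h = std::min(t_total, 0.1);
  arma::vec N;
  int guard = 0;

  // velocity field at Z, after pruning infeasible species in-place
  auto velocity = [&](arma::mat& Zc, arma::uvec& idx, arma::vec& Nout,
                      arma::mat& V) -> bool {
    List eq = cpp_equilibrium(Zc, sigma, B, printed, kind);
    int status = eq["status"];
    if (status != 0) return false;
    arma::uvec keep = as<arma::uvec>(eq["keep"]) - 1;
    if (keep.n_elem < Zc.n_rows) {
      Zc = Zc.rows(keep);
      idx = idx.elem(keep);
    }
    Nout = as<arma::vec>(eq["N"]);
    arma::mat G = cpp_selection_gradients(Zc, Nout, sigma, B, printed, kind);
    V = G.each_col() % (kappa * Nout);
    return V.is_finite();
  };

  while (t < t_total && Z.n_rows > 0 && ++guard < 200000) {
    arma::vec N1; arma::mat V1;
    if (!velocity(Z, alive, N1, V1)) break;   // total collapse or solver failure
    if (Z.n_rows == 0) break;
    double vmax = std::sqrt(arma::max(arma::sum(arma::square(V1), 1)));
    if (vmax * h > max_disp) h = max_disp / vmax;
    if (t + h > t_total) h = t_total - t;

    // trial full step; if trial state sheds species, shrink h, and below a
    // floor accept the extinction as part of the flow
    arma::mat Zt_ = Z + h * V1;
    arma::uvec idx_t = alive;
    arma::vec N2; arma::mat V2;
    bool ok = velocity(Zt_, idx_t, N2, V2);
    if (!ok) { h *= 0.5; if (h < 1e-9 * t_total) break; continue; }
    if (Zt_.n_rows < Z.n_rows && h > 1e-6 * t_total) { h *= 0.5; continue; }
    if (Zt_.n_rows < Z.n_rows) {
      // committed extinction during flow
      Z = Zt_; alive = idx_t; N = N2; t += h;
      continue;
    }
    double err = arma::abs((V2 - V1) * (h * 0.5)).max();
    if (err <= tol) {
      Z += (h * 0.5) * (V1 + V2);
      N = N1;
      t += h;
    }
    double fac = 0.9 * std::sqrt(tol / std::max(err, 1e-15));
    h *= std::min(4.0, std::max(0.2, fac));
  }
  // final equilibrium at the end state
  if (Z.n_rows > 0) {
    arma::vec Nf; arma::mat Vf;
    velocity(Z, alive, Nf, Vf);
    N = Nf;
  }
  return List::create(_["Z"] = Z, _["N"] = N, _["alive"] = alive + 1,
                      _["t"] = t);
}

// Connected components of the graph linking points closer than delta
// (single-linkage clustering cut at delta).  1-based component labels,
// relabelled to first-appearance order.
// [[Rcpp::export]]
IntegerVector cpp_cluster_labels(const arma::mat& Z, double delta) {
  const int n = Z.n_rows, d = Z.n_cols;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  const double d2 = delta * delta;
  arma::mat Zt = Z.t();
  for (int i = 0; i < n; ++i) {
    const double* zi = Zt.colptr(i);
    for (int j = i + 1; j < n; ++j) {
      const double* zj = Zt.colptr(j);
      double ss = 0.0;
      for (int k = 0; k < d; ++k) { double u = zi[k] - zj[k]; ss += u * u; }
      if (ss < d2) {
        int ri = find(i), rj = find(j);
        if (ri != rj) parent[rj] = ri;
      }
    }
  }
  IntegerVector lab(n);
  std::map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}
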