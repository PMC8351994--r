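// [[Rcpp::depends(RcppArmadillo)]]
#include "kernels.h"
using namespace Rcpp;

// [[Rcpp::export]]
arma::vec cpp_log_K(const arma::mat& Z, int kind) {
  return log_K_vec(Z, kind);
}

// [[Rcpp::export]]
arma::mat cpp_grad_log_K(const arma::mat& Z, int kind) {
  const int M = Z.n_rows, d = Z.n_cols;
  arma::mat Zt = Z.t();
  arma::mat G(M, d);
  std::vector<double> g(d);
  for (int i = 0; i < M; ++i) {
    grad_log_K(Zt.colptr(i), d, kind, g.data());
    for (int k = 0; k < d; ++k) G(i, k) = g[k];
  }
  return G;
}

// alpha(z_i, z_j) for paired rows of Zi, Zj (elementwise over rows)
// [[Rcpp::export]]
arma::vec cpp_alpha_pairs(const arma::mat& Zi, const arma::mat& Zj,
                          double sigma, const arma::mat& B, bool printed) {
  const int n = Zi.n_rows, d = Zi.n_cols;
  bool has_b = arma::any(arma::vectorise(arma::abs(B)) > 0.0);
  arma::mat Zit = Zi.t(), Zjt = Zj.t();
  arma::vec out(n);
  for (int i = 0; i < n; ++i)
    out(i) = std::exp(log_alpha(Zit.colptr(i), Zjt.colptr(i), d,
                                sigma, B.memptr(), has_b, printed));
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_interaction_matrix(const arma::mat& Z, double sigma,
                                 const arma::mat& B, bool printed) {
  return interaction_matrix_cpp(Z, sigma, B, printed);
}

// Community invasion fitness of candidate phenotypes Zm (n x d) against
// residents Z (M x d) with abundances N:
//   f(z_m) = 1 - sum_j alpha(z_j, z_m) N_j / K(z_m)
// computed through log K differences to dodge underflow of K(z_m).
// M = 0 gives f = 1 (pure birth rate of a mutant in an empty world).
// [[Rcpp::export]]
arma::vec cpp_invasion_fitness(const arma::mat& Z, const arma::vec& N,
                               const arma::mat& Zm, double sigma,
                               const arma::mat& B, bool printed, int kind) {
  const int M = Z.n_rows, n = Zm.n_rows, d = Zm.n_cols;
  bool has_b = arma::any(arma::vectorise(arma::abs(B)) > 0.0);
  arma::mat Zt = Z.t(), Zmt = Zm.t();
  arma::vec lKres(M);
  for (int j = 0; j < M; ++j) lKres(j) = log_K(Zt.colptr(j), d, kind);
  arma::vec out(n);
  for (int m = 0; m < n; ++m) {
    const double* zm = Zmt.colptr(m);
    double lKm = log_K(zm, d, kind);
    double load = 0.0;
    for (int j = 0; j < M; ++j) {
      double la = log_alpha(Zt.colptr(j), zm, d, sigma, B.memptr(),
                            has_b, printed);
      // exponent capped so K-underflow far outside viable space yields a
      // huge but finite negative fitness instead of -Inf
      double ex = la - lKm;
      if (ex > 700.0) ex = 700.0;
      load += N(j) * std::exp(ex);
    }
    out(m) = 1.0 - load;
  }
  return out;
}

// Analytic selection gradients d f / d z_m at z_m = z_i for every resident i.
// f(z_m) = 1 - S(z_m)/K(z_m) with S = sum_j N_j alpha(z_j, z_m), so
//   grad f = (-grad S + S grad log K) / K.
// grad_{z_m} alpha(z_j, z_m) = alpha * [ (z_j - z_m)/sigma^2 + grad_m A ]
// where, for the corrected asymmetric term A = sum_{k,l} b_kl (z_jk - z_mk) z_jl,
//   dA/dz_mk = -(B z_j)_k,
// and for the printed form A = sum_{k,l} b_kl (z_jk - z_ml) z_jl,
//   dA/dz_ml = -(sum_k b_kl) z_jl.
// [[Rcpp::export]]
arma::mat cpp_selection_gradients(const arma::mat& Z, const arma::vec& N,
                                  double sigma, const arma::mat& B,
                                  bool printed, int kind) {
  const int M = Z.n_rows, d = Z.n_cols;
  bool has_b = arma::any(arma::vectorise(arma::abs(B)) > 0.0);
  const double inv_s2 = 1.0 / (sigma * sigma);
  arma::mat Zt = Z.t();
  arma::vec bcolsum = has_b ? arma::sum(B, 0).t() : arma::vec(d, arma::fill::zeros);
  arma::mat G(M, d);
  std::vector<double> glk(d);
  for (int i = 0; i < M; ++i) {
    const double* zi = Zt.colptr(i);
    double lKi = log_K(zi, d, kind);
    double Ki = std::exp(lKi);
    double S = 0.0;
    arma::vec gS(d, arma::fill::zeros);
    for (int j = 0; j < M; ++j) {
      const double* zj = Zt.colptr(j);
      double a = std::exp(log_alpha(zj, zi, d, sigma, B.memptr(),
                                    has_b, printed));
      double w = N(j) * a;
      S += w;
      for (int k = 0; k < d; ++k) gS(k) += w * (zj[k] - zi[k]) * inv_s2;
      if (has_b) {
        if (!printed) {
          for (int k = 0; k < d; ++k) {
            double bz = 0.0;
            for (int l = 0; l < d; ++l) bz += B(k, l) * zj[l];
            gS(k) -= w * bz;
          }
        } else {
          for (int l = 0; l < d; ++l) gS(l) -= w * bcolsum(l) * zj[l];
        }
      }
    }
    grad_log_K(zi, d, kind, glk.data());
    for (int k = 0; k < d; ++k) G(i, k) = (-gS(k) + S * glk[k]) / Ki;
  }
  return G;
}
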