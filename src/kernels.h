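#ifndef NICHEPACK_KERNELS_H
#define NICHEPACK_KERNELS_H

#include <RcppArmadillo.h>

// Carrying-capacity kinds
enum KKind { K_QUARTIC = 0, K_RADIAL = 1 };

// log K(z).  quartic: -sum z^4/4;  radial: -(sum z^2/2)^2/2
inline double log_K(const double* z, int d, int kind) {
  if (kind == K_QUARTIC) {
    double s = 0.0;
    for (int k = 0; k < d; ++k) { double q = z[k] * z[k]; s += q * q; }
    return -0.25 * s;
  }
  double s = 0.0;
  for (int k = 0; k < d; ++k) s += z[k] * z[k];
  return -0.125 * s * s;
}

// grad log K(z) written into g
inline void grad_log_K(const double* z, int d, int kind, double* g) {
  if (kind == K_QUARTIC) {
    for (int k = 0; k < d; ++k) g[k] = -z[k] * z[k] * z[k];
  } else {
    double s = 0.0;
    for (int k = 0; k < d; ++k) s += z[k] * z[k];
    for (int k = 0; k < d; ++k) g[k] = -0.5 * s * z[k];
  }
}

// log alpha(z_i, z_j): competitive effect of phenotype j entering i's
// per-capita growth (Eq.-4 style summand uses alpha(z_j, z_i) on focal i).
// Gaussian part: -|z_i - z_j|^2 / (2 sigma^2).
// Asymmetric part (default, corrected): sum_{k,l} b_kl (z_ik - z_jk) z_il.
// Printed (legacy) form, behind `printed`: sum_{k,l} b_kl (z_ik - z_jl) z_il,
// which does NOT vanish at z_i = z_j.
inline double log_alpha(const double* zi, const double* zj, int d,
                        double sigma, const double* B /* d x d col-major */,
                        bool has_b, bool printed) {
  double ss = 0.0;
  for (int k = 0; k < d; ++k) { double u = zi[k] - zj[k]; ss += u * u; }
  double la = -ss / (2.0 * sigma * sigma);
  if (has_b) {
    double a = 0.0;
    if (!printed) {
      for (int l = 0; l < d; ++l) {
        double acc = 0.0;
        for (int k = 0; k < d; ++k) acc += B[k + l * d] * (zi[k] - zj[k]);
        a += acc * zi[l];
      }
    } else {
      for (int l = 0; l < d; ++l) {
        double acc = 0.0;
        for (int k = 0; k < d; ++k) acc += B[k + l * d] * (zi[k] - zj[l]);
        a += acc * zi[l];
      }
    }
    la += a;
  }
  return la;
}

// Interaction matrix A(i,j) = alpha(z_j, z_i): effect OF species j ON i.
// Z is M x d, rows are phenotypes.
inline arma::mat interaction_matrix_cpp(const arma::mat& Z, double sigma,
                                        const arma::mat& B, bool printed) {
  const int M = Z.n_rows, d = Z.n_cols;
  bool has_b = arma::any(arma::vectorise(arma::abs(B)) > 0.0);
  arma::mat Zt = Z.t();           // d x M, column i = z_i (contiguous)
  arma::mat A(M, M);
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < M; ++j) {
      A(i, j) = std::exp(log_alpha(Zt.colptr(j), Zt.colptr(i), d,
                                   sigma, B.memptr(), has_b, printed));
    }
  }
  return A;
}

inline arma::vec log_K_vec(const arma::mat& Z, int kind) {
  const int M = Z.n_rows, d = Z.n_cols;
  arma::mat Zt = Z.t();
  arma::vec out(M);
  for (int i = 0; i < M; ++i) out(i) = log_K(Zt.colptr(i), d, kind);
  return out;
}

// shared across translation units
arma::mat cpp_selection_gradients(const arma::mat& Z, const arma::vec& N,
                                  double sigma, const arma::mat& B,
                                  bool printed, int kind);

#endif
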