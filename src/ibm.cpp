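// [[Rcpp::depends(RcppArmadillo)]]
#include "kernels.h"
#include <functional>
#include <map>
using namespace Rcpp;

// Death rates for every individual: d_i = S_i / (K_max * K(z_i)) with
// S_i = sum_j alpha(z_j, z_i) over the whole population (self term alpha = 1
// included by default so the monomorphic birth-death balance lands at
// K_max * K exactly).
// [[Rcpp::export]]
arma::vec cpp_ibm_death_rates(const arma::mat& Z, double sigma,
                              const arma::mat& B, bool printed, int kind,
                              double kmax, bool self_term) {
  arma::mat A = interaction_matrix_cpp(Z, sigma, B, printed);
  arma::vec S = arma::sum(A, 1);
  if (!self_term) S -= A.diag();
  arma::vec K = arma::exp(log_K_vec(Z, kind));
  return S / (kmax * K);
}

struct IbmState {
  int d;
  std::vector<double> z;      // n*d, individual-major
  std::vector<double> S;      // competition load onto i (self included)
  std::vector<double> selfA;  // alpha(z_i, z_i) (1 unless printed form)
  std::vector<double> invKk;  // 1 / (kmax * K(z_i))
  int n() const { return (int)S.size(); }
};

// [[Rcpp::export]]
List cpp_run_ibm(const arma::mat& Z0, double sigma, const arma::mat& B,
                 bool printed, int kind, double kmax, double birth_rate,
                 double sigma_mut, double max_events, int record_every,
                 double cluster_delta, bool self_term, int keep_snapshots,
                 bool sequential) {
  const int d = Z0.n_cols;
  const double* Bp = B.memptr();
  bool has_b = arma::any(arma::vectorise(arma::abs(B)) > 0.0);

  IbmState st; st.d = d;
  int n0 = Z0.n_rows;
  st.z.resize((size_t)n0 * d);
  for (int i = 0; i < n0; ++i)
    for (int k = 0; k < d; ++k) st.z[(size_t)i * d + k] = Z0(i, k);
  st.S.assign(n0, 0.0); st.selfA.assign(n0, 1.0); st.invKk.assign(n0, 0.0);
  for (int i = 0; i < n0; ++i) {
    const double* zi = &st.z[(size_t)i * d];
    st.invKk[i] = std::exp(-log_K(zi, d, kind)) / kmax;
    double s = 0.0;
    for (int j = 0; j < n0; ++j)
      s += std::exp(log_alpha(&st.z[(size_t)j * d], zi, d, sigma, Bp, has_b, printed));
    st.S[i] = s;
    st.selfA[i] = std::exp(log_alpha(zi, zi, d, sigma, Bp, has_b, printed));
  }

  auto death_rate_i = [&](int i) {
    double s = st.S[i] - (self_term ? 0.0 : st.selfA[i]);
    return s * st.invKk[i];
  };

  double time = 0.0;
  std::vector<double> rec_t; std::vector<int> rec_n, rec_c;
  std::vector<double> snap_t; std::vector<arma::mat> snaps;
  int snap_stride = 1;  // in units of records; doubled when full

  auto count_clusters = [&](void) -> int {
    int n = st.n();
    if (n == 0) return 0;
    std::vector<int> parent(n);
    for (int i = 0; i < n; ++i) parent[i] = i;
    std::function<int(int)> find = [&](int x) {
      while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
      return x;
    };
    double d2 = cluster_delta * cluster_delta;
    for (int i = 0; i < n; ++i) {
      const double* zi = &st.z[(size_t)i * d];
      for (int j = i + 1; j < n; ++j) {
        const double* zj = &st.z[(size_t)j * d];
        double ss = 0.0;
        for (int k = 0; k < d; ++k) { double u = zi[k] - zj[k]; ss += u * u; }
        if (ss < d2) { int a = find(i), b = find(j); if (a != b) parent[b] = a; }
      }
    }
    int c = 0;
    for (int i = 0; i < n; ++i) if (find(i) == i) ++c;
    return c;
  };

  auto as_matrix = [&](void) {
    int n = st.n();
    arma::mat Z(n, d);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < d; ++k) Z(i, k) = st.z[(size_t)i * d + k];
    return Z;
  };

  auto record = [&](int rec_index) {
    rec_t.push_back(time); rec_n.push_back(st.n());
    rec_c.push_back(count_clusters());
    if (keep_snapshots > 0 && rec_index % snap_stride == 0) {
      snap_t.push_back(time); snaps.push_back(as_matrix());
      if ((int)snaps.size() >= 2 * keep_snapshots) {
        std::vector<double> t2; std::vector<arma::mat> s2;
        for (size_t q = 0; q < snaps.size(); q += 2) {
          t2.push_back(snap_t[q]); s2.push_back(snaps[q]);
        }
        snap_t.swap(t2); snaps.swap(s2);
        snap_stride *= 2;
      }
    }
  };

  record(0);
  bool extinct = false;
  double ev = 0;
  int rec_index = 0;
  for (ev = 0; ev < max_events; ++ev) {
    int n = st.n();
    if (n == 0) { extinct = true; break; }
    bool birth; int who;
    if (!sequential) {
      double totB = n * birth_rate, totD = 0.0;
      for (int i = 0; i < n; ++i) totD += death_rate_i(i);
      double tot = totB + totD;
      time += exp_rand() / tot;
      double u = unif_rand() * tot;
      if (u < totB) {
        birth = true; who = std::min(n - 1, (int)(u / birth_rate));
      } else {
        birth = false;
        double w = u - totB, acc = 0.0; who = n - 1;
        for (int i = 0; i < n; ++i) { acc += death_rate_i(i); if (acc >= w) { who = i; break; } }
      }
    } else {
      // discrete random-sequential scheduler: uniform individual, then
      // birth-vs-death by relative rate; one sweep-normalised time unit per n events
      who = std::min(n - 1, (int)(unif_rand() * n));
      double di = death_rate_i(who);
      birth = unif_rand() * (birth_rate + di) < birth_rate;
      time += 1.0 / n;
    }

    if (birth) {
      std::vector<double> child(d);
      for (int k = 0; k < d; ++k)
        child[k] = st.z[(size_t)who * d + k] + sigma_mut * norm_rand();
      double s = 0.0;
      for (int j = 0; j < n; ++j) {
        const double* zj = &st.z[(size_t)j * d];
        // effect of the child on j, and of j on the child (equal when b = 0)
        double a_on_j = std::exp(log_alpha(child.data(), zj, d, sigma, Bp, has_b, printed));
        st.S[j] += a_on_j;
        s += has_b ?
          std::exp(log_alpha(zj, child.data(), d, sigma, Bp, has_b, printed)) :
          a_on_j;
      }
      double sa = std::exp(log_alpha(child.data(), child.data(), d, sigma, Bp, has_b, printed));
      st.S.push_back(s + sa);
      st.selfA.push_back(sa);
      st.invKk.push_back(std::exp(-log_K(child.data(), d, kind)) / kmax);
      st.z.insert(st.z.end(), child.begin(), child.end());
    } else {
      std::vector<double> dead(st.z.begin() + (size_t)who * d,
                               st.z.begin() + (size_t)(who + 1) * d);
      // remove by swap-with-last
      int last = n - 1;
      for (int k = 0; k < d; ++k) st.z[(size_t)who * d + k] = st.z[(size_t)last * d + k];
      st.z.resize((size_t)last * d);
      st.S[who] = st.S[last]; st.S.pop_back();
      st.selfA[who] = st.selfA[last]; st.selfA.pop_back();
      st.invKk[who] = st.invKk[last]; st.invKk.pop_back();
      for (int j = 0; j < last; ++j) {
        const double* zj = &st.z[(size_t)j * d];
        st.S[j] -= std::exp(log_alpha(dead.data(), zj, d, sigma, Bp, has_b, printed));
      }
    }
    if (((long long)(ev + 1)) % record_every == 0) record(++rec_index);
    if (((long long)ev) % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  if (extinct || ((long long)(ev)) % record_every != 0) record(++rec_index);

  List snl(snaps.size());
  for (size_t q = 0; q < snaps.size(); ++q) snl[q] = snaps[q];
  return List::create(
    _["times"] = rec_t, _["sizes"] = rec_n, _["clusters"] = rec_c,
    _["snapshot_times"] = snap_t, _["snapshots"] = snl,
    _["Z"] = as_matrix(), _["time"] = time, _["events"] = ev,
    _["extinct"] = extinct,
    _["S_cache"] = arma::vec(st.S));
}
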