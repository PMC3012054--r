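#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Plug-in mutual information between two discrete vectors coded 0..A-1 and
// 0..B-1, in bits. Joint/marginal counts are integers, so the estimator is
// exact up to floating point; 0 * log(0) terms are skipped.

static double mi_from_joint(const std::vector<int>& joint,
                            const std::vector<int>& nx,
                            const std::vector<int>& ny,
                            int A, int B, double n) {
  double mi = 0.0;
  for (int a = 0; a < A; ++a) {
    if (nx[a] == 0) continue;
    for (int b = 0; b < B; ++b) {
      int c = joint[a * B + b];
      if (c == 0) continue;
      double p = c / n;
      mi += p * std::log2((c * n) / (static_cast<double>(nx[a]) * ny[b]));
    }
  }
  return mi > 0.0 ? mi : 0.0;
}

static void count_joint(const IntegerVector& x, const std::vector<int>& y,
                        std::vector<int>& joint, int B) {
  std::fill(joint.begin(), joint.end(), 0);
  int n = x.size();
  for (int i = 0; i < n; ++i) joint[x[i] * B + y[i]]++;
}

// [[Rcpp::export(name = ".cpp_mi_disc")]]
double cpp_mi_disc(IntegerVector x, IntegerVector y, int A, int B) {
  int n = x.size();
  std::vector<int> joint(A * B, 0), nx(A, 0), ny(B, 0);
  for (int i = 0; i < n; ++i) {
    joint[x[i] * B + y[i]]++;
    nx[x[i]]++;
    ny[y[i]]++;
  }
  return mi_from_joint(joint, nx, ny, A, B, static_cast<double>(n));
}

// Null distribution of MI(x; pi(y)) over n_rand independent uniform
// permutations pi, drawn with R's RNG (Fisher-Yates), so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".cpp_perm_mi_null")]]
NumericVector cpp_perm_mi_null(IntegerVector x, IntegerVector y,
                               int A, int B, int n_rand) {
  int n = x.size();
  std::vector<int> nx(A, 0), ny(B, 0);
  for (int i = 0; i < n; ++i) { nx[x[i]]++; ny[y[i]]++; }
  std::vector<int> yp(y.begin(), y.end());
  std::vector<int> joint(A * B, 0);
  NumericVector out(n_rand);
  for (int r = 0; r < n_rand; ++r) {
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(yp[i], yp[j]);
    }
    count_joint(x, yp, joint, B);
    out[r] = mi_from_joint(joint, nx, ny, A, B, static_cast<double>(n));
  }
  return out;
}

// Conditional mutual information sum_g p(g) * MI(x; y | g) for discrete
// x (0..A-1), y (0..B-1) within strata g (0..G-1).
// [[Rcpp::export(name = ".cpp_cond_mi")]]
double cpp_cond_mi(IntegerVector x, IntegerVector y, IntegerVector g,
                   int A, int B, int G) {
  int n = x.size();
  double cmi = 0.0;
  std::vector<int> joint(A * B), nx(A), ny(B);
  for (int s = 0; s < G; ++s) {
    std::fill(joint.begin(), joint.end(), 0);
    std::fill(nx.begin(), nx.end(), 0);
    std::fill(ny.begin(), ny.end(), 0);
    int ng = 0;
    for (int i = 0; i < n; ++i) {
      if (g[i] != s) continue;
      joint[x[i] * B + y[i]]++;
      nx[x[i]]++;
      ny[y[i]]++;
      ng++;
    }
    if (ng == 0) continue;
    cmi += (static_cast<double>(ng) / n) *
           mi_from_joint(joint, nx, ny, A, B, static_cast<double>(ng));
  }
  return cmi;
}

// Null for the conditional test: y is permuted independently *within* each
// stratum of g, preserving the x/g structure.
// [[Rcpp::export(name = ".cpp_cond_perm_null")]]
NumericVector cpp_cond_perm_null(IntegerVector x, IntegerVector y,
                                 IntegerVector g, int A, int B, int G,
                                 int n_rand) {
  int n = x.size();
  std::vector< std::vector<int> > idx(G);
  for (int i = 0; i < n; ++i) idx[g[i]].push_back(i);
  std::vector<int> yp(y.begin(), y.end());
  NumericVector out(n_rand);
  std::vector<int> joint(A * B), nx(A), ny(B);
  for (int r = 0; r < n_rand; ++r) {
    double cmi = 0.0;
    for (int s = 0; s < G; ++s) {
      int ng = idx[s].size();
      if (ng == 0) continue;
      for (int i = ng - 1; i > 0; --i) {
        int j = static_cast<int>(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(yp[idx[s][i]], yp[idx[s][j]]);
      }
      std::fill(joint.begin(), joint.end(), 0);
      std::fill(nx.begin(), nx.end(), 0);
      std::fill(ny.begin(), ny.end(), 0);
      for (int t = 0; t < ng; ++t) {
        int i = idx[s][t];
        joint[x[i] * B + yp[i]]++;
        nx[x[i]]++;
        ny[yp[i]]++;
      }
      cmi += (static_cast<double>(ng) / n) *
             mi_from_joint(joint, nx, ny, A, B, static_cast<double>(ng));
    }
    out[r] = cmi;
  }
  return out;
}

// Fast path for binary x with m carriers: permuting y and intersecting with
// the fixed carrier set is distributionally identical to drawing m labels
// from y without replacement, so each null draw costs O(m) instead of O(n).
// [[Rcpp::export(name = ".cpp_perm_mi_null_binary")]]
NumericVector cpp_perm_mi_null_binary(IntegerVector y, int m, int B,
                                      int n_rand) {
  int n = y.size();
  std::vector<int> ny(B, 0);
  for (int i = 0; i < n; ++i) ny[y[i]]++;
  std::vector<int> pool(y.begin(), y.end());
  std::vector<int> k(B);
  std::vector<int> nx(2);
  nx[0] = n - m;
  nx[1] = m;
  std::vector<int> joint(2 * B);
  NumericVector out(n_rand);
  for (int r = 0; r < n_rand; ++r) {
    std::fill(k.begin(), k.end(), 0);
    for (int i = 0; i < m; ++i) {
      int j = i + static_cast<int>(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(pool[i], pool[j]);
      k[pool[i]]++;
    }
    for (int b = 0; b < B; ++b) {
      joint[b] = ny[b] - k[b];      // x = 0 row
      joint[B + b] = k[b];          // x = 1 row
    }
    out[r] = mi_from_joint(joint, nx, ny, 2, B, static_cast<double>(n));
  }
  return out;
}
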