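#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Counts of Chebyshev-similar template pairs at embedding lengths m and m+1.
// Templates start at i = 0..N-m-1 (N-m of them) for both lengths so the two
// counts are over the same index set; self-matches excluded (i < j only).
// Returns c(B, A) = c(phi(m), phi(m+1)).
// [[Rcpp::export]]
NumericVector sampen_pair_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;
  const double* xs = x.begin();
  double B = 0.0, A = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(xs[i + k] - xs[j + k]);
        if (d > dm) {
          dm = d;
          if (dm > r) { ok = false; break; }
        }
      }
      if (ok) {
        B += 1.0;
        double d = std::fabs(xs[i + m] - xs[j + m]);
        if (d > dm) dm = d;
        if (dm <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}

// Mean exponential membership exp(-(d/r)^nf) over distinct template pairs,
// templates mean-centered, Chebyshev distance, lengths m and m+1 over the
// same index set i = 0..N-m-1. Returns c(phi_m, phi_m1).
// [[Rcpp::export]]
NumericVector fuzzyen_phi(NumericVector x, int m, double r, double nf) {
  const int n = x.size();
  const int nt = n - m;
  const int m1 = m + 1;
  // contiguous row-major centered templates
  std::vector<double> tm((size_t)nt * m), tm1((size_t)nt * m1);
  for (int i = 0; i < nt; ++i) {
    double mu = 0.0, mu1 = 0.0;
    for (int k = 0; k < m; ++k) mu += x[i + k];
    mu /= m;
    for (int k = 0; k < m1; ++k) mu1 += x[i + k];
    mu1 /= m1;
    for (int k = 0; k < m; ++k) tm[(size_t)i * m + k] = x[i + k] - mu;
    for (int k = 0; k < m1; ++k) tm1[(size_t)i * m1 + k] = x[i + k] - mu1;
  }
  const bool quad = (nf == 2.0);
  const double inv_r = 1.0 / r;
  double sm = 0.0, sm1 = 0.0;
  long npair = 0;
  for (int i = 0; i < nt - 1; ++i) {
    const double* ti = &tm[(size_t)i * m];
    const double* ti1 = &tm1[(size_t)i * m1];
    for (int j = i + 1; j < nt; ++j) {
      const double* tj = &tm[(size_t)j * m];
      const double* tj1 = &tm1[(size_t)j * m1];
      double dm = 0.0, dm1 = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(ti[k] - tj[k]);
        if (d > dm) dm = d;
      }
      for (int k = 0; k < m1; ++k) {
        double d = std::fabs(ti1[k] - tj1[k]);
        if (d > dm1) dm1 = d;
      }
      double u = dm * inv_r, u1 = dm1 * inv_r;
      if (quad) {
        sm += std::exp(-u * u);
        sm1 += std::exp(-u1 * u1);
      } else {
        sm += std::exp(-std::pow(u, nf));
        sm1 += std::exp(-std::pow(u1, nf));
      }
      ++npair;
    }
  }
  if (npair == 0) return NumericVector::create(1.0, 1.0);
  return NumericVector::create(sm / npair, sm1 / npair);
}

// Approximate entropy: Phi^m(r) - Phi^{m+1}(r) with Phi the mean over
// templates of log of self-match-inclusive Chebyshev match fractions.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const double* xs = x.begin();
  auto phi = [&](int mm) {
    const int nt = n - mm + 1;
    std::vector<int> cnt(nt, 1);  // self-match included
    for (int i = 0; i < nt - 1; ++i) {
      for (int j = i + 1; j < nt; ++j) {
        bool ok = true;
        for (int k = 0; k < mm; ++k) {
          if (std::fabs(xs[i + k] - xs[j + k]) > r) { ok = false; break; }
        }
        if (ok) { ++cnt[i]; ++cnt[j]; }
      }
    }
    double s = 0.0;
    for (int i = 0; i < nt; ++i) s += std::log((double)cnt[i] / nt);
    return s / nt;
  };
  return phi(m) - phi(m + 1);
}

// Classical dynamic time warping distance with absolute-difference local
// cost and steps {(1,0),(0,1),(1,1)}; returns the cumulative cost C(n,m).
// [[Rcpp::export]]
double dtw_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = inf;
    for (int j = 1; j <= m; ++j) {
      double d = std::fabs(a[i - 1] - b[j - 1]);
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = d + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
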