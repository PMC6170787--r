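#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with initial conditions zi
// (a[0] assumed non-zero; coefficients are normalized here).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  double a0 = aa[0];
  for (int i = 0; i < nf; ++i) { bb[i] /= a0; aa[i] /= a0; }
  int n = x.size();
  NumericVector y(n);
  std::vector<double> z(nf, 0.0);
  for (int i = 0; i < nf - 1 && i < zi.size(); ++i) z[i] = zi[i];
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int k = 0; k < nf - 2; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    z[nf - 2] = bb[nf - 1] * xt - aa[nf - 1] * yt;
    y[t] = yt;
  }
  return y;
}

// Higuchi normalized curve lengths L(k), k = 1..kmax: for offset m (1..k),
// L_m(k) = (N-1) / (floor((N-m)/k) * k^2) * sum_i |x(m+ik) - x(m+(i-1)k)|,
// L(k) = mean over offsets. The fractal dimension is the negative slope of
// ln L(k) on ln k (fitted by the caller).
// [[Rcpp::export]]
NumericVector higuchi_lengths_cpp(NumericVector x, int kmax) {
  int n = x.size();
  NumericVector L(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double acc = 0.0;
    for (int m = 1; m <= k; ++m) {
      int nterms = (n - m) / k;  // floor
      if (nterms < 1) { acc = NA_REAL; break; }
      double s = 0.0;
      for (int i = 1; i <= nterms; ++i)
        s += std::fabs(x[m - 1 + i * k] - x[m - 1 + (i - 1) * k]);
      acc += s * (double)(n - 1) / ((double)nterms * (double)k * (double)k);
    }
    L[k - 1] = acc / k;
  }
  return L;
}

// Sample entropy template-match counts (Richman & Moorman): templates
// i = 1..N-m for both lengths; B = #pairs matching for m points, A = #pairs
// matching for m+1 points, Chebyshev distance <= r, self-matches excluded.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // number of templates of both lengths considered
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Kaspar-Schuster sequential form of the Lempel-Ziv 1976 exhaustive-history
// phrase count on a binary (0/1 integer) sequence.
// [[Rcpp::export]]
int lzc_count_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// Synchronization likelihood (Stam & van Dijk). Both series are
// delay-embedded (lag L, dimension m). For reference time i, admissible
// times j satisfy w1 < |i - j| < w2. The critical distance for each series
// is the k_i-th smallest embedded Euclidean distance with
// k_i = max(1, round(pref * N_i)); SL_i is the fraction of the x-recurrences
// that are simultaneously y-recurrences, and the result is the average of
// SL_i over reference times. Identical inputs give 1; independent inputs
// give ~pref.
// [[Rcpp::export]]
double sl_cpp(NumericVector x, NumericVector y, int lag, int dim,
              int w1, int w2, double pref) {
  int n = x.size();
  int M = n - (dim - 1) * lag;  // number of embedded vectors
  if (M < 4) stop("series too short for the requested embedding");
  auto dist2 = [&](NumericVector& v, int i, int j) {
    double d = 0.0;
    for (int k = 0; k < dim; ++k) {
      double dd = v[i + k * lag] - v[j + k * lag];
      d += dd * dd;
    }
    return d;
  };
  double acc = 0.0;
  int used = 0;
  std::vector<int> idx;
  std::vector<double> dx, dy;
  idx.reserve(2 * w2);
  for (int i = 0; i < M; ++i) {
    idx.clear();
    for (int j = std::max(0, i - w2 + 1); j < i - w1; ++j) idx.push_back(j);
    for (int j = i + w1 + 1; j < std::min(M, i + w2); ++j) idx.push_back(j);
    int N = (int)idx.size();
    int k = (int)std::lround(pref * N);
    if (k < 1 || N < 2) continue;
    dx.resize(N); dy.resize(N);
    for (int t = 0; t < N; ++t) {
      dx[t] = dist2(x, i, idx[t]);
      dy[t] = dist2(y, i, idx[t]);
    }
    std::vector<double> tmp(dx);
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    double ex = tmp[k - 1];
    tmp = dy;
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    double ey = tmp[k - 1];
    int shared = 0, nx = 0;
    for (int t = 0; t < N; ++t) {
      if (dx[t] <= ex) {
        ++nx;
        if (dy[t] <= ey) ++shared;
      }
    }
    if (nx == 0) continue;
    acc += (double)shared / (double)nx;
    ++used;
  }
  if (used == 0) stop("no reference times with enough recurrences; widen windows");
  return acc / used;
}
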