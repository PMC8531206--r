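#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Locate strict local maxima and minima. Plateaus are collapsed to the last
// sample before the direction change (adequate for noisy physiological data,
// where exact ties are rare).
static void find_extrema(const NumericVector& x,
                         std::vector<int>& imax, std::vector<int>& imin) {
  const int n = x.size();
  int prev = 0, prev_i = 0;
  for (int i = 1; i < n; ++i) {
    double d = x[i] - x[i - 1];
    int s = (d > 0) - (d < 0);
    if (s != 0) {
      if (prev > 0 && s < 0) imax.push_back(prev_i);
      if (prev < 0 && s > 0) imin.push_back(prev_i);
      prev = s;
    }
    prev_i = i;
  }
}

// Natural cubic spline through (t, y), evaluated at 0, 1, ..., n_out-1.
// Knots must be strictly increasing and bracket [0, n_out-1].
static std::vector<double> nat_spline(const std::vector<double>& t,
                                      const std::vector<double>& y,
                                      int n_out) {
  const int m = (int)t.size();
  std::vector<double> out(n_out);
  if (m == 2) {
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int i = 0; i < n_out; ++i) out[i] = y[0] + slope * (i - t[0]);
    return out;
  }
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m),
      c(m, 0.0), b(m - 1), d(m - 1);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  c[m - 1] = 0.0;
  for (int j = m - 2; j >= 0; --j) {
    c[j] = z[j] - mu[j] * c[j + 1];
    b[j] = (y[j + 1] - y[j]) / h[j] - h[j] * (c[j + 1] + 2.0 * c[j]) / 3.0;
    d[j] = (c[j + 1] - c[j]) / (3.0 * h[j]);
  }
  int seg = 0;
  for (int i = 0; i < n_out; ++i) {
    double xv = (double)i;
    while (seg < m - 2 && xv > t[seg + 1]) ++seg;
    double dx = xv - t[seg];
    out[i] = y[seg] + dx * (b[seg] + dx * (c[seg] + dx * d[seg]));
  }
  return out;
}

// Envelope through the extrema at `idx`, with up to two extrema mirrored
// across each boundary so the spline is anchored outside [0, n-1].
static std::vector<double> envelope(const NumericVector& x,
                                    const std::vector<int>& idx, int n) {
  const int m = (int)idx.size();
  std::vector<double> t, y;
  t.reserve(m + 6); y.reserve(m + 6);
  const int nm = std::min(2, m);
  for (int k = nm - 1; k >= 0; --k)
    if (idx[k] > 0) { t.push_back(-(double)idx[k]); y.push_back(x[idx[k]]); }
  for (int k = 0; k < m; ++k) { t.push_back((double)idx[k]); y.push_back(x[idx[k]]); }
  for (int k = 0; k < nm; ++k) {
    int j = m - 1 - k;
    if (idx[j] < n - 1) { t.push_back(2.0 * (n - 1) - idx[j]); y.push_back(x[idx[j]]); }
  }
  if (t.front() > 0.0) { t.insert(t.begin(), 0.0); y.insert(y.begin(), x[0]); }
  if (t.back() < (double)(n - 1)) { t.push_back((double)(n - 1)); y.push_back(x[n - 1]); }
  return nat_spline(t, y, n);
}

//' @title Mean envelope of one sifting step (internal)
//' @description Upper/lower cubic-spline envelopes through the local extrema
//'   (mirror boundary extension) and their pointwise mean. Returns ok = FALSE
//'   when the signal has too few extrema to sift, which signals termination
//'   of the decomposition rather than an error.
//' @param x numeric signal
//' @return list with ok, mean, upper, lower, n_max, n_min
//' @keywords internal
// [[Rcpp::export(name = ".env_mean_cpp")]]
List env_mean_cpp(NumericVector x) {
  const int n = x.size();
  std::vector<int> imax, imin;
  find_extrema(x, imax, imin);
  const int nmax = (int)imax.size(), nmin = (int)imin.size();
  if (nmax < 2 || nmin < 2 || nmax + nmin < 4)
    return List::create(_["ok"] = false, _["n_max"] = nmax, _["n_min"] = nmin);
  std::vector<double> up = envelope(x, imax, n);
  std::vector<double> lo = envelope(x, imin, n);
  NumericVector m(n), u(n), l(n);
  for (int i = 0; i < n; ++i) {
    u[i] = up[i]; l[i] = lo[i]; m[i] = 0.5 * (up[i] + lo[i]);
  }
  return List::create(_["ok"] = true, _["mean"] = m, _["upper"] = u,
                      _["lower"] = l, _["n_max"] = nmax, _["n_min"] = nmin);
}

//' @title Count extrema and zero crossings (internal)
//' @param x numeric signal
//' @return integer vector c(n_extrema, n_zero_crossings)
//' @keywords internal
// [[Rcpp::export(name = ".extrema_zc_cpp")]]
IntegerVector extrema_zc_cpp(NumericVector x) {
  const int n = x.size();
  std::vector<int> imax, imin;
  find_extrema(x, imax, imin);
  int zc = 0;
  double prev = 0.0;
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    if (v == 0.0) continue;
    if (prev != 0.0 && ((prev > 0) != (v > 0))) ++zc;
    prev = v;
  }
  return IntegerVector::create((int)(imax.size() + imin.size()), zc);
}
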