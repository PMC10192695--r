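// Empirical mode decomposition: cubic-spline envelope sifting.
//
// Envelopes are natural cubic splines through the local extrema, with the
// first two extrema mirror-reflected beyond each boundary to suppress
// end swings. An IMF is accepted when the Cauchy-type sifting criterion
// sum((h_prev - h)^2) / sum(h_prev^2) drops below `stop_sd`, or after
// `max_sift` passes. Decomposition stops at `max_imf` modes or when the
// residual has fewer than two maxima or two minima.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// strict local extrema with plateau handling: a run of equal values flanked
// by lower (higher) neighbours yields one extremum at the run midpoint
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& imax, std::vector<int>& imin) {
  imax.clear(); imin.clear();
  const int n = (int)x.size();
  int i = 1;
  while (i < n - 1) {
    if (x[i] == x[i - 1]) { ++i; continue; }
    int j = i;
    while (j < n - 1 && x[j + 1] == x[j]) ++j;   // plateau [i, j]
    if (j >= n - 1) break;
    const int mid = (i + j) / 2;
    if (x[i] > x[i - 1] && x[j] > x[j + 1]) imax.push_back(mid);
    if (x[i] < x[i - 1] && x[j] < x[j + 1]) imin.push_back(mid);
    i = j + 1;
  }
}

// natural cubic spline through (xs, ys), evaluated at 0..n-1
static void spline_eval(const std::vector<double>& xs,
                        const std::vector<double>& ys,
                        int n, std::vector<double>& out) {
  const int m = (int)xs.size();
  out.assign(n, 0.0);
  if (m == 1) { std::fill(out.begin(), out.end(), ys[0]); return; }
  if (m == 2) {
    const double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int t = 0; t < n; ++t) out[t] = ys[0] + slope * (t - xs[0]);
    return;
  }
  // second derivatives by tridiagonal solve (natural boundary conditions)
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), c(m);
  for (int k = 0; k < m - 1; ++k) h[k] = xs[k + 1] - xs[k];
  for (int k = 1; k < m - 1; ++k)
    alpha[k] = 3.0 * ((ys[k + 1] - ys[k]) / h[k] - (ys[k] - ys[k - 1]) / h[k - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int k = 1; k < m - 1; ++k) {
    l[k] = 2.0 * (xs[k + 1] - xs[k - 1]) - h[k - 1] * mu[k - 1];
    mu[k] = h[k] / l[k];
    z[k] = (alpha[k] - h[k - 1] * z[k - 1]) / l[k];
  }
  l[m - 1] = 1.0; z[m - 1] = 0.0; c[m - 1] = 0.0;
  for (int k = m - 2; k >= 0; --k) c[k] = z[k] - mu[k] * c[k + 1];

  int seg = 0;
  for (int t = 0; t < n; ++t) {
    const double xt = (double)t;
    while (seg < m - 2 && xs[seg + 1] < xt) ++seg;
    const double dx = xt - xs[seg];
    const double b = (ys[seg + 1] - ys[seg]) / h[seg] -
                     h[seg] * (c[seg + 1] + 2.0 * c[seg]) / 3.0;
    const double d = (c[seg + 1] - c[seg]) / (3.0 * h[seg]);
    out[t] = ys[seg] + dx * (b + dx * (c[seg] + dx * d));
  }
}

// mirror-extend up to `next` extrema beyond each boundary, then spline
static void envelope(const std::vector<double>& x,
                     const std::vector<int>& idx,
                     int n, std::vector<double>& env) {
  const int next = 2;
  std::vector<double> xs, ys;
  const int m = (int)idx.size();
  const int nl = std::min(next, m), nr = std::min(next, m);
  for (int k = nl - 1; k >= 0; --k) {   // reflect about sample 0
    double xr = -(double)idx[k];
    if (xr < -0.5 || idx[k] > 0) { xs.push_back(xr); ys.push_back(x[idx[k]]); }
  }
  for (int k = 0; k < m; ++k) { xs.push_back((double)idx[k]); ys.push_back(x[idx[k]]); }
  for (int k = 0; k < nr; ++k) {        // reflect about sample n-1
    const int src = m - 1 - k;
    double xr = 2.0 * (n - 1) - (double)idx[src];
    if (xr > (double)(n - 1) + 0.5 || idx[src] < n - 1) { xs.push_back(xr); ys.push_back(x[idx[src]]); }
  }
  // enforce strictly increasing abscissae (mirrors can coincide at ends)
  std::vector<double> xs2, ys2;
  for (size_t k = 0; k < xs.size(); ++k) {
    if (!xs2.empty() && xs[k] <= xs2.back()) continue;
    xs2.push_back(xs[k]); ys2.push_back(ys[k]);
  }
  spline_eval(xs2, ys2, n, env);
}

// zero crossings: sign changes ignoring exact zeros
static int count_zero_crossings(const std::vector<double>& x) {
  int zc = 0, prev = 0;
  for (size_t t = 0; t < x.size(); ++t) {
    const int s = x[t] > 0.0 ? 1 : (x[t] < 0.0 ? -1 : 0);
    if (s != 0) {
      if (prev != 0 && s != prev) ++zc;
      prev = s;
    }
  }
  return zc;
}

// [[Rcpp::export]]
List emd_cpp(NumericVector signal, int max_imf, double stop_sd, int max_sift) {
  const int n = signal.size();
  std::vector<double> r(signal.begin(), signal.end());
  std::vector<std::vector<double> > imfs;
  std::vector<int> imax, imin;
  std::vector<double> upper, lower, h, hnew;

  for (int mode = 0; mode < max_imf; ++mode) {
    find_extrema(r, imax, imin);
    if ((int)imax.size() < 2 || (int)imin.size() < 2) break;  // monotone-ish residual
    h = r;
    for (int s = 0; s < max_sift; ++s) {
      find_extrema(h, imax, imin);
      if ((int)imax.size() < 2 || (int)imin.size() < 2) break;
      envelope(h, imax, n, upper);
      envelope(h, imin, n, lower);
      double num = 0.0, den = 0.0;
      hnew.resize(n);
      for (int t = 0; t < n; ++t) {
        const double m = 0.5 * (upper[t] + lower[t]);
        hnew[t] = h[t] - m;
        num += m * m;
        den += h[t] * h[t];
      }
      h.swap(hnew);
      if (den <= 0.0) break;
      if (num / den < stop_sd) {
        // accept only an admissible mode: extrema and zero-crossing
        // counts must differ by at most one
        find_extrema(h, imax, imin);
        const int ne = (int)(imax.size() + imin.size());
        if (std::abs(ne - count_zero_crossings(h)) <= 1) break;
      }
    }
    imfs.push_back(h);
    for (int t = 0; t < n; ++t) r[t] -= h[t];
  }

  NumericMatrix M(n, (int)imfs.size());
  for (size_t k = 0; k < imfs.size(); ++k)
    std::copy(imfs[k].begin(), imfs[k].end(), M.begin() + k * n);
  return List::create(_["imfs"] = M, _["residual"] = NumericVector(r.begin(), r.end()));
}
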