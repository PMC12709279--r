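#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Strict local extrema of y at interior points; endpoints are never extrema.
// Plateau points (ties with a neighbour) are not counted: annual flux series
// are continuous-valued, and strictness keeps the IMF zero-crossing bookkeeping
// unambiguous.
static void find_extrema(const std::vector<double>& y,
                         std::vector<int>& maxima, std::vector<int>& minima) {
  maxima.clear();
  minima.clear();
  const int n = (int)y.size();
  for (int i = 1; i < n - 1; ++i) {
    if (y[i] > y[i - 1] && y[i] > y[i + 1]) maxima.push_back(i);
    else if (y[i] < y[i - 1] && y[i] < y[i + 1]) minima.push_back(i);
  }
}

// Natural cubic spline through knots (xs, ys), evaluated at integers 0..n-1.
// Tridiagonal system solved by the Thomas algorithm; natural end conditions
// (second derivative zero at the outer knots, which after mirroring lie
// outside the data window).
static std::vector<double> spline_eval(const std::vector<double>& xs,
                                       const std::vector<double>& ys,
                                       int n) {
  const int m = (int)xs.size();
  std::vector<double> out(n);
  if (m == 1) {
    std::fill(out.begin(), out.end(), ys[0]);
    return out;
  }
  if (m == 2) {
    const double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int t = 0; t < n; ++t) out[t] = ys[0] + slope * (t - xs[0]);
    return out;
  }
  // second derivatives M[0..m-1], M[0] = M[m-1] = 0
  std::vector<double> h(m - 1), alpha(m), l(m), mu(m), z(m), M(m);
  for (int i = 0; i < m - 1; ++i) h[i] = xs[i + 1] - xs[i];
  alpha[0] = 0.0;
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (xs[i + 1] - xs[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  // evaluate; spline coefficients per interval
  int seg = 0;
  for (int t = 0; t < n; ++t) {
    const double x = (double)t;
    while (seg < m - 2 && x > xs[seg + 1]) ++seg;
    const double dx = x - xs[seg];
    const double hi = h[seg];
    const double b = (ys[seg + 1] - ys[seg]) / hi - hi * (2.0 * M[seg] + M[seg + 1]) / 3.0;
    out[t] = ys[seg] + b * dx + M[seg] * dx * dx + (M[seg + 1] - M[seg]) / (3.0 * hi) * dx * dx * dx;
  }
  return out;
}

// Envelope through the given extrema (upper = through maxima). Boundary
// handling: an endpoint that lies beyond the nearest extremum (above it for
// the upper envelope, below for the lower) is itself treated as an envelope
// knot, so the envelope cannot undershoot the data at the series ends; the
// two nearest knots are then mirrored beyond each end to stabilize the
// spline curvature there.
static std::vector<double> envelope(const std::vector<double>& y,
                                    const std::vector<int>& idx, bool upper) {
  const int n = (int)y.size();
  const int k = (int)idx.size();
  std::vector<double> cx, cy;                     // core knots, ascending x
  cx.reserve(k + 2);
  cy.reserve(k + 2);
  const bool left_anchor = upper ? (y[0] >= y[idx[0]])
                                 : (y[0] <= y[idx[0]]);
  const bool right_anchor = upper ? (y[n - 1] >= y[idx[k - 1]])
                                  : (y[n - 1] <= y[idx[k - 1]]);
  if (left_anchor) { cx.push_back(0.0); cy.push_back(y[0]); }
  for (int j = 0; j < k; ++j) {
    cx.push_back((double)idx[j]);
    cy.push_back(y[idx[j]]);
  }
  if (right_anchor) { cx.push_back((double)(n - 1)); cy.push_back(y[n - 1]); }
  const int m = (int)cx.size();

  std::vector<double> xs, ys;
  xs.reserve(m + 4);
  ys.reserve(m + 4);
  // mirror the two nearest knots with x > 0 about t = 0 (outermost first)
  std::vector<int> lm;
  for (int j = 0; j < m && (int)lm.size() < 2; ++j)
    if (cx[j] > 0.0) lm.push_back(j);
  for (int j = (int)lm.size() - 1; j >= 0; --j) {
    xs.push_back(-cx[lm[j]]);
    ys.push_back(cy[lm[j]]);
  }
  for (int j = 0; j < m; ++j) { xs.push_back(cx[j]); ys.push_back(cy[j]); }
  // mirror the two nearest knots with x < n-1 about t = n-1 (nearest first)
  std::vector<int> rm;
  for (int j = m - 1; j >= 0 && (int)rm.size() < 2; --j)
    if (cx[j] < (double)(n - 1)) rm.push_back(j);
  for (size_t j = 0; j < rm.size(); ++j) {
    xs.push_back(2.0 * (n - 1) - cx[rm[j]]);
    ys.push_back(cy[rm[j]]);
  }
  return spline_eval(xs, ys, n);
}

// [[Rcpp::export(name = ".envelope_mean_cpp")]]
List envelope_mean_cpp(NumericVector series) {
  std::vector<double> y(series.begin(), series.end());
  std::vector<int> maxima, minima;
  find_extrema(y, maxima, minima);
  if ((int)maxima.size() < 2 || (int)minima.size() < 2)
    return List::create(_["ok"] = false,
                        _["n_maxima"] = (int)maxima.size(),
                        _["n_minima"] = (int)minima.size());
  std::vector<double> up = envelope(y, maxima, true);
  std::vector<double> lo = envelope(y, minima, false);
  NumericVector phi(y.size());
  for (size_t i = 0; i < y.size(); ++i) phi[i] = 0.5 * (up[i] + lo[i]);
  return List::create(_["ok"] = true, _["mean"] = phi,
                      _["n_maxima"] = (int)maxima.size(),
                      _["n_minima"] = (int)minima.size());
}

// zero-crossing count with runs of exact zeros collapsed to one crossing
static int count_zero_crossings(const std::vector<double>& y) {
  const int n = (int)y.size();
  int zc = 0;
  for (int i = 1; i < n; ++i) {
    if ((y[i - 1] < 0.0 && y[i] > 0.0) || (y[i - 1] > 0.0 && y[i] < 0.0)) ++zc;
    else if (y[i] == 0.0 && y[i - 1] != 0.0) {
      int j = i + 1;
      while (j < n && y[j] == 0.0) ++j;
      if (j < n && ((y[i - 1] > 0.0) != (y[j] > 0.0))) ++zc;
      i = j - 1;
    }
  }
  return zc;
}

// One sifting pass bundle: iterate h_k = h_{k-1} - envelope_mean(h_{k-1})
// until the Cauchy-type SD = sum (h_k - h_{k-1})^2 / h_{k-1}^2 (zero-
// denominator terms skipped) drops below sd_threshold AND the candidate
// satisfies the defining IMF property (extrema and zero-crossing counts
// differ by at most one), the candidate runs out of extrema, or max_iters
// is hit.
// [[Rcpp::export(name = ".sift_imf_cpp")]]
List sift_imf_cpp(NumericVector series, double sd_threshold, int max_iters) {
  const int n = series.size();
  std::vector<double> h(series.begin(), series.end());
  std::vector<int> maxima, minima;
  find_extrema(h, maxima, minima);
  if ((int)maxima.size() < 2 || (int)minima.size() < 2)
    return List::create(_["ok"] = false);
  int iters = 0;
  for (int it = 0; it < max_iters; ++it) {
    find_extrema(h, maxima, minima);
    if ((int)maxima.size() < 2 || (int)minima.size() < 2) break;
    std::vector<double> up = envelope(h, maxima, true);
    std::vector<double> lo = envelope(h, minima, false);
    double sd = 0.0;
    std::vector<double> hnew(n);
    for (int t = 0; t < n; ++t) {
      const double phi = 0.5 * (up[t] + lo[t]);
      hnew[t] = h[t] - phi;
      const double denom = h[t] * h[t];
      if (denom > 0.0) sd += (hnew[t] - h[t]) * (hnew[t] - h[t]) / denom;
    }
    h.swap(hnew);
    ++iters;
    if (sd < sd_threshold) {
      find_extrema(h, maxima, minima);
      const int n_ext = (int)(maxima.size() + minima.size());
      if (std::abs(n_ext - count_zero_crossings(h)) <= 1) break;
    }
  }
  NumericVector imf(n), rem(n);
  for (int t = 0; t < n; ++t) {
    imf[t] = h[t];
    rem[t] = series[t] - h[t];
  }
  return List::create(_["ok"] = true, _["imf"] = imf, _["remainder"] = rem,
                      _["iterations"] = iters);
}

// Full EMD: extract IMFs from successive residuals until the residual has
// fewer than two maxima or two minima, or max_imfs components were taken.
// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector series, double sd_threshold, int max_sift_iters,
             int max_imfs) {
  const int n = series.size();
  std::vector<double> resid(series.begin(), series.end());
  std::vector<std::vector<double> > imfs;
  std::vector<int> maxima, minima;
  while ((int)imfs.size() < max_imfs) {
    find_extrema(resid, maxima, minima);
    if ((int)maxima.size() < 2 || (int)minima.size() < 2) break;
    NumericVector cur(resid.begin(), resid.end());
    List s = sift_imf_cpp(cur, sd_threshold, max_sift_iters);
    if (!as<bool>(s["ok"])) break;
    NumericVector imf = s["imf"];
    std::vector<double> comp(imf.begin(), imf.end());
    bool allzero = true;
    for (int t = 0; t < n; ++t) {
      if (comp[t] != 0.0) { allzero = false; }
      resid[t] -= comp[t];
    }
    if (allzero) break;
    imfs.push_back(comp);
  }
  NumericMatrix out((int)imfs.size(), n);
  for (size_t i = 0; i < imfs.size(); ++i)
    for (int t = 0; t < n; ++t) out((int)i, t) = imfs[i][t];
  return List::create(_["imfs"] = out,
                      _["residual"] = NumericVector(resid.begin(), resid.end()));
}

// Extrema / zero-crossing counts, used for the IMF structural property.
// [[Rcpp::export(name = ".imf_counts_cpp")]]
IntegerVector imf_counts_cpp(NumericVector series) {
  std::vector<double> y(series.begin(), series.end());
  std::vector<int> maxima, minima;
  find_extrema(y, maxima, minima);
  return IntegerVector::create((int)(maxima.size() + minima.size()),
                               count_zero_crossings(y));
}
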