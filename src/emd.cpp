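#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Extrema detection.
//
// Strict three-point local extrema; runs of equal values (plateaus) are
// compressed first so a plateau contributes its midpoint index exactly once.
// Endpoint runs never qualify (interior extrema only).
// ---------------------------------------------------------------------------

static void find_extrema_core(const std::vector<double>& x,
                              std::vector<int>& maxima,
                              std::vector<int>& minima) {
  const int n = (int)x.size();
  maxima.clear();
  minima.clear();
  if (n < 3) return;

  // compress equal-value runs: value, start index, end index (inclusive)
  std::vector<double> rv;
  std::vector<int> rs, re;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[j + 1] == x[i]) ++j;
    rv.push_back(x[i]);
    rs.push_back(i);
    re.push_back(j);
    i = j + 1;
  }
  const int m = (int)rv.size();
  for (int k = 1; k + 1 < m; ++k) {
    const int mid = (rs[k] + re[k]) / 2;
    if (rv[k] > rv[k - 1] && rv[k] > rv[k + 1]) maxima.push_back(mid);
    else if (rv[k] < rv[k - 1] && rv[k] < rv[k + 1]) minima.push_back(mid);
  }
}

// [[Rcpp::export]]
List find_extrema_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::vector<int> ma, mi;
  find_extrema_core(xs, ma, mi);
  IntegerVector maxima(ma.size()), minima(mi.size());
  for (size_t k = 0; k < ma.size(); ++k) maxima[k] = ma[k] + 1;  // 1-based
  for (size_t k = 0; k < mi.size(); ++k) minima[k] = mi[k] + 1;
  return List::create(_["maxima"] = maxima, _["minima"] = minima);
}

// ---------------------------------------------------------------------------
// Natural cubic spline through knots (t, y), evaluated on the integer grid
// 0..n-1. Second-derivative formulation, natural boundary (M_0 = M_last = 0),
// Thomas tridiagonal solve. Knots must be strictly increasing.
// ---------------------------------------------------------------------------

static std::vector<double> natural_spline_grid(const std::vector<double>& t,
                                               const std::vector<double>& y,
                                               int n) {
  const int m = (int)t.size();
  std::vector<double> out(n, 0.0);
  if (m == 2) {  // straight line
    const double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int k = 0; k < n; ++k) out[k] = y[0] + slope * (k - t[0]);
    return out;
  }
  std::vector<double> h(m - 1);
  for (int k = 0; k < m - 1; ++k) h[k] = t[k + 1] - t[k];

  // tridiagonal system for interior second derivatives M_1..M_{m-2}
  const int p = m - 2;
  std::vector<double> a(p), b(p), c(p), d(p), M(m, 0.0);
  for (int k = 0; k < p; ++k) {
    a[k] = h[k];
    b[k] = 2.0 * (h[k] + h[k + 1]);
    c[k] = h[k + 1];
    d[k] = 6.0 * ((y[k + 2] - y[k + 1]) / h[k + 1] - (y[k + 1] - y[k]) / h[k]);
  }
  for (int k = 1; k < p; ++k) {  // forward elimination
    const double w = a[k] / b[k - 1];
    b[k] -= w * c[k - 1];
    d[k] -= w * d[k - 1];
  }
  if (p > 0) {
    M[p] = d[p - 1] / b[p - 1];
    for (int k = p - 2; k >= 0; --k) M[k + 1] = (d[k] - c[k] * M[k + 2]) / b[k];
  }

  // evaluate; extrapolate with the end cubics if the grid exceeds the knots
  int seg = 0;
  for (int k = 0; k < n; ++k) {
    const double tv = (double)k;
    while (seg < m - 2 && tv > t[seg + 1]) ++seg;
    const double hk = h[seg];
    const double A = (t[seg + 1] - tv) / hk;
    const double B = (tv - t[seg]) / hk;
    out[k] = A * y[seg] + B * y[seg + 1] +
      ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) * hk * hk / 6.0;
  }
  return out;
}

// Build spline envelope through extrema with the two nearest extrema mirrored
// about each end of the support (anti edge-swing boundary condition).
static std::vector<double> envelope(const std::vector<double>& x,
                                    const std::vector<int>& idx, int n) {
  const int m = (int)idx.size();
  std::vector<double> t, y;
  t.reserve(m + 4);
  y.reserve(m + 4);
  // left mirror about t = 0: farther point first so knots stay increasing
  const int lm = std::min(2, m);
  for (int k = lm - 1; k >= 0; --k) {
    t.push_back(-(double)idx[k]);
    y.push_back(x[idx[k]]);
  }
  for (int k = 0; k < m; ++k) {
    t.push_back((double)idx[k]);
    y.push_back(x[idx[k]]);
  }
  // right mirror about t = n-1
  for (int k = 0; k < lm; ++k) {
    const int src = m - 1 - k;
    t.push_back(2.0 * (n - 1) - (double)idx[src]);
    y.push_back(x[idx[src]]);
  }
  return natural_spline_grid(t, y, n);
}

static bool envelope_mean_core(const std::vector<double>& x,
                               std::vector<double>& mean_env) {
  const int n = (int)x.size();
  std::vector<int> ma, mi;
  find_extrema_core(x, ma, mi);
  if ((int)ma.size() < 2 || (int)mi.size() < 2) return false;
  std::vector<double> up = envelope(x, ma, n);
  std::vector<double> lo = envelope(x, mi, n);
  mean_env.resize(n);
  for (int k = 0; k < n; ++k) mean_env[k] = 0.5 * (up[k] + lo[k]);
  return true;
}

// [[Rcpp::export]]
NumericVector envelope_mean_cpp(NumericVector x, IntegerVector maxima,
                                IntegerVector minima) {
  const int n = x.size();
  std::vector<double> xs(x.begin(), x.end());
  std::vector<int> ma(maxima.size()), mi(minima.size());
  for (int k = 0; k < maxima.size(); ++k) ma[k] = maxima[k] - 1;
  for (int k = 0; k < minima.size(); ++k) mi[k] = minima[k] - 1;
  if ((int)ma.size() < 2 || (int)mi.size() < 2)
    stop("monotone residual reached: need at least 2 maxima and 2 minima");
  std::vector<double> up = envelope(xs, ma, n);
  std::vector<double> lo = envelope(xs, mi, n);
  NumericVector out(n);
  for (int k = 0; k < n; ++k) out[k] = 0.5 * (up[k] + lo[k]);
  return out;
}

// ---------------------------------------------------------------------------
// Sifting. h_{i,0} = x, h_{i,j} = h_{i,j-1} - m(h_{i,j-1}); the Cauchy-type
// stoppage criterion D_j = sum |h_{j-1} - h_j|^2 / sum |h_{j-1}|^2 ends the
// loop when D_j < threshold (or at max_sift). This is the method's operative
// stop rule; the ideal-IMF zero-crossing/extrema parity then holds exactly
// for clean oscillations and approximately (within a few percent of the
// extrema count) for noisy ones — enforcing parity inside the loop was tried
// and rejected: the extra sifting drains the leading mode and pushes the
// tremor band down the mode ladder.
// ---------------------------------------------------------------------------

static bool sift_core(const std::vector<double>& x, double threshold,
                      int max_sift, std::vector<double>& imf, int& n_sifts) {
  const int n = (int)x.size();
  std::vector<double> h(x), m;
  n_sifts = 0;
  for (int j = 1; j <= max_sift; ++j) {
    if (!envelope_mean_core(h, m)) {
      if (j == 1) return false;  // x itself has too few extrema
      break;                     // sifted to (near) monotone: accept h
    }
    double num = 0.0, den = 0.0;
    for (int k = 0; k < n; ++k) {
      num += m[k] * m[k];  // (h_prev - h_curr) = m
      den += h[k] * h[k];
    }
    if (den == 0.0) return false;
    for (int k = 0; k < n; ++k) h[k] -= m[k];
    n_sifts = j;
    if (num / den < threshold) break;
  }
  imf = h;
  return true;
}

// [[Rcpp::export]]
List sift_one_cpp(NumericVector x, double threshold, int max_sift) {
  std::vector<double> xs(x.begin(), x.end()), imf;
  int n_sifts = 0;
  if (!sift_core(xs, threshold, max_sift, imf, n_sifts))
    stop("monotone residual reached: insufficient extrema to sift");
  return List::create(_["imf"] = NumericVector(imf.begin(), imf.end()),
                      _["n_sifts"] = n_sifts);
}

// [[Rcpp::export]]
List emd_cpp(NumericVector x, double threshold, int max_sift, int max_imfs) {
  const int n = x.size();
  std::vector<double> r(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  std::vector<int> sift_counts;
  for (int i = 0; i < max_imfs; ++i) {
    std::vector<int> ma, mi;
    find_extrema_core(r, ma, mi);
    if ((int)ma.size() < 2 || (int)mi.size() < 2) break;  // monotone residual
    std::vector<double> imf;
    int ns = 0;
    if (!sift_core(r, threshold, max_sift, imf, ns)) break;
    imfs.push_back(imf);
    sift_counts.push_back(ns);
    for (int k = 0; k < n; ++k) r[k] -= imf[k];
  }
  const int K = (int)imfs.size();
  NumericMatrix im(n, K);
  for (int i = 0; i < K; ++i)
    for (int k = 0; k < n; ++k) im(k, i) = imfs[i][k];
  return List::create(_["imfs"] = im,
                      _["residual"] = NumericVector(r.begin(), r.end()),
                      _["n_sifts"] = IntegerVector(sift_counts.begin(),
                                                   sift_counts.end()));
}

// ---------------------------------------------------------------------------
// Direct-form II transposed IIR filter with initial conditions, for the
// Butterworth benchmark module. Coefficients normalized so a[0] = 1.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x,
                             NumericVector zi) {
  const int n = x.size();
  const int ord = std::max(a.size(), b.size()) - 1;
  std::vector<double> bb(ord + 1, 0.0), aa(ord + 1, 0.0), z(ord, 0.0);
  for (int k = 0; k < b.size(); ++k) bb[k] = b[k];
  for (int k = 0; k < a.size(); ++k) aa[k] = a[k];
  for (int k = 0; k < std::min((int)zi.size(), ord); ++k) z[k] = zi[k];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (ord > 0 ? z[0] : 0.0);
    for (int k = 0; k < ord - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (ord > 0) z[ord - 1] = bb[ord] * xi - aa[ord] * yi;
    y[i] = yi;
  }
  return y;
}
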