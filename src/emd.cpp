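#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- extrema ------------------------------------------------------------
// Interior extrema with plateau runs collapsed to their midpoint (rounded
// down). Strict comparisons against the neighbouring runs guarantee that
// maxima and minima alternate.
static void extrema_scan(const double* x, int n,
                         std::vector<int>& mx, std::vector<int>& mn) {
  mx.clear(); mn.clear();
  if (n < 3) return;
  std::vector<int> rs, re;
  std::vector<double> rv;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[j + 1] == x[i]) ++j;
    rs.push_back(i); re.push_back(j); rv.push_back(x[i]);
    i = j + 1;
  }
  int K = (int) rs.size();
  for (int k = 1; k + 1 < K; ++k) {
    int mid = (rs[k] + re[k]) / 2;
    if (rv[k] > rv[k - 1] && rv[k] > rv[k + 1]) mx.push_back(mid);
    else if (rv[k] < rv[k - 1] && rv[k] < rv[k + 1]) mn.push_back(mid);
  }
}

// [[Rcpp::export]]
List cpp_find_extrema(NumericVector x) {
  std::vector<int> mx, mn;
  extrema_scan(x.begin(), x.size(), mx, mn);
  return List::create(_["maxima"] = wrap(mx), _["minima"] = wrap(mn));
}

// ---- natural cubic spline ----------------------------------------------
// Knots (t, v) strictly increasing in t; evaluated at 0..n-1. Fewer than 4
// knots fall back to piecewise-linear interpolation (with end-segment
// extrapolation); a single knot gives a constant.
static void spline_eval(const std::vector<double>& t,
                        const std::vector<double>& v,
                        int n, std::vector<double>& out) {
  int m = (int) t.size();
  out.assign(n, 0.0);
  if (m == 0) return;
  if (m == 1) { std::fill(out.begin(), out.end(), v[0]); return; }
  if (m < 4) {                       // linear
    for (int i = 0; i < n; ++i) {
      double xi = (double) i;
      int k = 0;
      while (k + 2 < m && t[k + 1] < xi) ++k;
      double w = (xi - t[k]) / (t[k + 1] - t[k]);
      out[i] = v[k] + w * (v[k + 1] - v[k]);
    }
    return;
  }
  // second derivatives: natural boundary (y'' = 0 at both ends)
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), c(m);
  for (int k = 0; k < m - 1; ++k) h[k] = t[k + 1] - t[k];
  for (int k = 1; k < m - 1; ++k)
    alpha[k] = 3.0 * ((v[k + 1] - v[k]) / h[k] - (v[k] - v[k - 1]) / h[k - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int k = 1; k < m - 1; ++k) {
    l[k] = 2.0 * (t[k + 1] - t[k - 1]) - h[k - 1] * mu[k - 1];
    mu[k] = h[k] / l[k];
    z[k] = (alpha[k] - h[k - 1] * z[k - 1]) / l[k];
  }
  l[m - 1] = 1.0; z[m - 1] = 0.0; c[m - 1] = 0.0;
  for (int k = m - 2; k >= 0; --k) c[k] = z[k] - mu[k] * c[k + 1];
  int k = 0;
  for (int i = 0; i < n; ++i) {
    double xi = (double) i;
    while (k + 2 < m && t[k + 1] < xi) ++k;
    double hk = h[k];
    double A = (t[k + 1] - xi) / hk, B = (xi - t[k]) / hk;
    out[i] = A * v[k] + B * v[k + 1] +
      ((A * A * A - A) * c[k] + (B * B * B - B) * c[k + 1]) * (hk * hk) / 6.0;
  }
}

// Mirror up to the two nearest extrema of each kind about both endpoints so
// the envelope splines span the full epoch without end swings.
static void mirror_extend(const std::vector<int>& idx, const double* x, int n,
                          std::vector<double>& t, std::vector<double>& v) {
  t.clear(); v.clear();
  int m = (int) idx.size();
  if (m == 0) return;
  int nl = std::min(2, m), nr = std::min(2, m);
  for (int k = nl - 1; k >= 0; --k) {          // left mirror, descending t
    t.push_back(-(double) idx[k]); v.push_back(x[idx[k]]);
  }
  std::reverse(t.begin(), t.end()); std::reverse(v.begin(), v.end());
  for (int k = 0; k < m; ++k) { t.push_back((double) idx[k]); v.push_back(x[idx[k]]); }
  for (int k = 0; k < nr; ++k) {
    t.push_back(2.0 * (n - 1) - (double) idx[m - 1 - k]);
    v.push_back(x[idx[m - 1 - k]]);
  }
  // drop any duplicated abscissae from the mirroring (e.g. extremum at 0)
  std::vector<double> tt, vv;
  for (size_t k = 0; k < t.size(); ++k) {
    if (tt.empty() || t[k] > tt.back() + 1e-9) { tt.push_back(t[k]); vv.push_back(v[k]); }
  }
  t.swap(tt); v.swap(vv);
}

// envelopes; returns false when there are fewer than 2 maxima or 2 minima
static bool envelopes(const double* x, int n,
                      std::vector<double>& up, std::vector<double>& lo,
                      std::vector<double>& mean) {
  std::vector<int> mx, mn;
  extrema_scan(x, n, mx, mn);
  if ((int) mx.size() < 2 || (int) mn.size() < 2) return false;
  std::vector<double> t, v;
  mirror_extend(mx, x, n, t, v);
  spline_eval(t, v, n, up);
  mirror_extend(mn, x, n, t, v);
  spline_eval(t, v, n, lo);
  mean.resize(n);
  for (int i = 0; i < n; ++i) mean[i] = 0.5 * (up[i] + lo[i]);
  return true;
}

// [[Rcpp::export]]
List cpp_envelopes(NumericVector x) {
  std::vector<double> up, lo, mean;
  bool ok = envelopes(x.begin(), x.size(), up, lo, mean);
  if (!ok) return List::create(_["ok"] = false);
  return List::create(_["ok"] = true, _["upper"] = wrap(up),
                      _["lower"] = wrap(lo), _["mean"] = wrap(mean));
}

static int zero_crossings(const double* x, int n) {
  // sign convention sgn(x >= 0) = +1, matching the ZCR feature
  int c = 0;
  for (int i = 1; i < n; ++i) {
    int s1 = (x[i] >= 0) ? 1 : -1, s0 = (x[i - 1] >= 0) ? 1 : -1;
    if (s1 != s0) ++c;
  }
  return c;
}

// one IMF by repeated sifting; SD (Cauchy) stop or max_sift
static bool extract_imf_core(const double* x, int n, double sd_threshold,
                             int max_sift, std::vector<double>& imf,
                             int& sift_count, bool& imf_ok) {
  imf.assign(x, x + n);
  std::vector<double> up, lo, mean;
  sift_count = 0;
  for (int it = 0; it < max_sift; ++it) {
    if (!envelopes(imf.data(), n, up, lo, mean)) {
      if (it == 0) return false;      // monotone input: no envelopes at all
      break;                          // sifted to (near-)monotone: accept
    }
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      num += mean[i] * mean[i];
      den += imf[i] * imf[i];
      imf[i] -= mean[i];
    }
    ++sift_count;
    double sd = (den > 0.0) ? num / den : 0.0;
    if (sd < sd_threshold) break;
  }
  std::vector<int> mx, mn;
  extrema_scan(imf.data(), n, mx, mn);
  int next = (int) (mx.size() + mn.size());
  int nzc = zero_crossings(imf.data(), n);
  imf_ok = std::abs(next - nzc) <= 1;
  return true;
}

// [[Rcpp::export]]
List cpp_extract_imf(NumericVector x, double sd_threshold, int max_sift) {
  std::vector<double> imf;
  int count = 0; bool ok = false;
  bool sifted = extract_imf_core(x.begin(), x.size(), sd_threshold, max_sift,
                                 imf, count, ok);
  return List::create(_["monotone"] = !sifted, _["imf"] = wrap(imf),
                      _["sift_count"] = count, _["imf_ok"] = ok);
}

// [[Rcpp::export]]
List cpp_emd(NumericVector x, int n_imfs, double sd_threshold, int max_sift) {
  int n = x.size();
  NumericMatrix imfs(n_imfs, n);
  IntegerVector counts(n_imfs);
  LogicalVector placeholder(n_imfs), condition_ok(n_imfs);
  std::vector<double> r(x.begin(), x.end()), imf;
  int k = 0;
  for (; k < n_imfs; ++k) {
    int count = 0; bool ok = false;
    if (!extract_imf_core(r.data(), n, sd_threshold, max_sift, imf, count, ok))
      break;                          // residual is monotone: stop early
    for (int i = 0; i < n; ++i) {
      imfs(k, i) = imf[i];
      r[i] -= imf[i];
    }
    counts[k] = count;
    placeholder[k] = false;
    condition_ok[k] = ok;
  }
  for (; k < n_imfs; ++k) {           // zero-padded slots keep width fixed
    for (int i = 0; i < n; ++i) imfs(k, i) = 0.0;
    counts[k] = 0; placeholder[k] = true; condition_ok[k] = NA_LOGICAL;
  }
  return List::create(_["imfs"] = imfs, _["residual"] = wrap(r),
                      _["sift_counts"] = counts,
                      _["placeholder"] = placeholder,
                      _["condition_ok"] = condition_ok);
}

// ---- approximate entropy ------------------------------------------------
// Two-term form with self-matches included (Heaviside(0) = 1): the average
// of log C_i^e over the N-e+1 length-e windows minus the average of
// log C_i^(e+1) over the N-e length-(e+1) windows, each C_i normalised by
// its own window count.
static double phi_m(const double* x, int N, int m, double r, bool chebyshev) {
  int M = N - m + 1;
  double acc = 0.0;
  for (int i = 0; i < M; ++i) {
    int cnt = 0;
    for (int j = 0; j < M; ++j) {
      if (chebyshev) {
        double d = 0.0;
        for (int k = 0; k < m; ++k) {
          double a = std::fabs(x[i + k] - x[j + k]);
          if (a > d) d = a;
          if (d > r) break;
        }
        if (d <= r) ++cnt;
      } else {
        double s = 0.0;
        for (int k = 0; k < m; ++k) {
          double a = x[i + k] - x[j + k];
          s += a * a;
        }
        if (std::sqrt(s) <= r) ++cnt;
      }
    }
    acc += std::log((double) cnt / (double) M);
  }
  return acc / (double) M;
}

// [[Rcpp::export]]
double cpp_apen(NumericVector x, int e, double r, bool chebyshev) {
  int N = x.size();
  return phi_m(x.begin(), N, e, r, chebyshev) -
         phi_m(x.begin(), N, e + 1, r, chebyshev);
}

// ---- cascaded biquad filtering ------------------------------------------
// one forward pass of the SOS cascade (direct form II transposed)
// [[Rcpp::export]]
NumericVector cpp_sos_filter(NumericVector x, NumericMatrix sos,
                             double gain, double baseline) {
  int n = x.size(), ns = sos.nrow();
  std::vector<double> y(x.begin(), x.end());
  double c = baseline;                 // reference level entering section s
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a0 = sos(s, 3), a1 = sos(s, 4), a2 = sos(s, 5);
    b0 /= a0; b1 /= a0; b2 /= a0; a1 /= a0; a2 /= a0;
    // steady-state initial conditions for a constant input at the
    // signal's baseline level: a DC offset then causes no startup
    // transient from the near-unit-circle low-cut poles, while a
    // zero-baseline oscillation starts from rest
    double h1 = (b0 + b1 + b2) / (1.0 + a1 + a2);
    double y0 = h1 * c;
    double z1 = y0 - b0 * c;
    double z2 = b2 * c - a2 * y0;
    c = y0;
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  NumericVector out(y.begin(), y.end());
  for (int i = 0; i < n; ++i) out[i] *= gain;
  return out;
}
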